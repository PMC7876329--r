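# Independent oracles used across the suite. These deliberately share no
# code with the implementation: plain-R brute force, written from the
# operation definitions.

# per-pixel kernel-sum density oracle (square truncation window, matching
# the documented kernel contract)
oracle_density_map <- function(points, shape, sigma = 6, trunc = 4,
                               legacy = FALSE) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(0, H, W)
  norm <- if (legacy) 1 / (2 * pi * sigma) else 1 / (2 * pi * sigma^2)
  rad <- trunc * sigma
  for (r in 0:(H - 1)) {
    for (cc in 0:(W - 1)) {
      v <- 0
      for (i in seq_len(nrow(points))) {
        dr <- r - points[i, 1]; dc <- cc - points[i, 2]
        if (abs(dr) <= rad && abs(dc) <= rad) {
          v <- v + norm * exp(-(dr^2 + dc^2) / (2 * sigma^2))
        }
      }
      out[r + 1, cc + 1] <- v
    }
  }
  out
}

# brute-force enumerate-sort-suppress peak oracle: threshold at gamma, take
# plateau-deduplicated 8-neighbourhood local maxima (positive value only),
# sort by descending value then ascending (row, col), greedily suppress
# candidates within Euclidean distance < delta of an accepted peak.
oracle_peaks <- function(den, gamma, delta) {
  H <- nrow(den); W <- ncol(den)
  z <- den
  z[z < gamma] <- 0
  # neighbourhood maximum by shifting (out-of-image treated as -Inf)
  nb <- matrix(-Inf, H, W)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(-Inf, H, W)
      rs <- max(1, 1 + dr):min(H, H + dr)
      cs <- max(1, 1 + dc):min(W, W + dc)
      sh[rs - dr, cs - dc] <- z[rs, cs]
      nb <- pmax(nb, sh)
    }
  }
  cand <- z > 0 & z >= gamma & z >= nb
  # plateau dedup by BFS over equal-valued candidate neighbours (only
  # needed where a candidate actually ties with a candidate neighbour)
  seen <- matrix(FALSE, H, W)
  reps <- NULL
  for (cc in 1:W) {
    for (r in 1:H) {
      if (!cand[r, cc] || seen[r, cc]) next
      v <- z[r, cc]
      comp <- matrix(c(r, cc), 1, 2)
      seen[r, cc] <- TRUE
      queue <- list(c(r, cc))
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) {
          for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            rr <- p[1] + dr; c2 <- p[2] + dc
            if (rr < 1 || rr > H || c2 < 1 || c2 > W) next
            if (!cand[rr, c2] || seen[rr, c2] || z[rr, c2] != v) next
            seen[rr, c2] <- TRUE
            comp <- rbind(comp, c(rr, c2))
            queue <- c(queue, list(c(rr, c2)))
          }
        }
      }
      top <- comp[order(comp[, 1], comp[, 2])[1], ]
      reps <- rbind(reps, c(top[1] - 1, top[2] - 1, v))
    }
  }
  if (is.null(reps)) {
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  }
  ord <- order(-reps[, 3], reps[, 1], reps[, 2])
  reps <- reps[ord, , drop = FALSE]
  acc <- NULL
  for (i in seq_len(nrow(reps))) {
    if (is.null(acc)) {
      acc <- reps[i, , drop = FALSE]
      next
    }
    d2 <- (acc[, 1] - reps[i, 1])^2 + (acc[, 2] - reps[i, 2])^2
    if (all(d2 >= delta^2)) acc <- rbind(acc, reps[i, ])
  }
  data.frame(row = as.integer(acc[, 1]), col = as.integer(acc[, 2]),
             value = acc[, 3])
}

# nearest-neighbour rotation of an (H, W) indicator image about its center,
# same inverse-map convention stated by augment_sample's contract
oracle_rotate_nn <- function(img, angle) {
  H <- nrow(img); W <- ncol(img)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  out <- matrix(0, H, W)
  for (r in 0:(H - 1)) {
    for (cc in 0:(W - 1)) {
      sr <- cos(angle) * (r - ctr[1]) + sin(angle) * (cc - ctr[2]) + ctr[1]
      sc <- -sin(angle) * (r - ctr[1]) + cos(angle) * (cc - ctr[2]) + ctr[2]
      ri <- round(sr); ci <- round(sc)
      if (ri >= 0 && ri < H && ci >= 0 && ci < W) {
        out[r + 1, cc + 1] <- img[ri + 1, ci + 1]
      }
    }
  }
  out
}

# scatter n points into [margin, H-margin) x [margin, W-margin) with
# pairwise separation >= min_sep (simple dart throwing)
scatter_points <- function(n, shape, margin, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(pts) < n && guard < 20000) {
    guard <- guard + 1
    p <- c(runif(1, margin, shape[1] - margin),
           runif(1, margin, shape[2] - margin))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

# small smooth random density fields for peak-oracle sweeps: a handful of
# random Gaussian bumps of varying amplitude plus optional noise/quantizing
random_density_field <- function(shape = c(64, 64), n_bumps = 12,
                                 quantize = FALSE, noise = 0) {
  pts <- cbind(runif(n_bumps, 0, shape[1] - 1e-9),
               runif(n_bumps, 0, shape[2] - 1e-9))
  amp <- runif(n_bumps, 0.2, 3)
  den <- matrix(0, shape[1], shape[2])
  for (i in seq_len(n_bumps)) {
    den <- den + amp[i] * gaussian_density_map(
      pts[i, , drop = FALSE], shape, kernel_config(sigma = 3))
  }
  if (noise > 0) den <- den + matrix(abs(rnorm(prod(shape), 0, noise)),
                                     shape[1], shape[2])
  if (quantize) den <- round(den, 2)
  den
}

# deterministic tiny sample sets for trainer tests
tiny_field_samples <- function(n, size = 64L, seed = 11L, offset = 0L,
                               spacing = 14) {
  spec <- field_spec(image_height = size, image_width = size,
                     bed_width = 24L, road_width = 12L,
                     plant_spacing = spacing,
                     flowering_fraction = c(0.2, 1), seed = seed)
  generate_samples(spec, n, offset = offset)
}
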