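#' Synthetic field specification
#'
#' Parameters of the synthetic field-image generator. The generator lays
#' vegetation beds out as vertical stripes separated by bare access roads,
#' places a plant lattice inside the beds (never on roads), marks a seeded
#' Bernoulli subset of plants as flowering, and renders each flowering
#' plant as a small reddish blob with a radial falloff to the green
#' rosette-textured background - the minimal stimulus with the "red
#' center" appearance that makes a flowering plant countable from above.
#'
#' @param image_height,image_width image size in pixels.
#' @param bed_width,road_width widths of the vegetation bed and bare road
#'   stripes (pixels); the pattern starts with a bed at column 0.
#' @param plant_spacing lattice spacing between plants (pixels).
#' @param flowering_fraction probability that a lattice site flowers;
#'   either a scalar in \[0, 1\] or a range `c(lo, hi)` from which a
#'   per-field fraction is drawn (lets a dataset span empty to saturated
#'   patches, emulating beds where flower induction partly failed).
#' @param blob_radius_range `c(min, max)` inflorescence blob radius
#'   (pixels), drawn uniformly per plant.
#' @param blob_color,background_color RGB triples in \[0, 1\].
#' @param texture_noise_sd per-pixel Gaussian noise SD (intensity units in
#'   \[0, 1\]) emulating rosette texture.
#' @param jitter_sd Gaussian positional jitter SD (pixels) applied to each
#'   lattice site, clamped so plants stay inside their bed.
#' @param illumination_gradient if `TRUE`, a low-frequency linear
#'   brightness ramp (random orientation, +-15%) is applied, emulating
#'   lighting and shadowing differences across a mosaic.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(image_height = 256L, image_width = 256L,
                       bed_width = 40L, road_width = 24L,
                       plant_spacing = 16L, flowering_fraction = 0.9,
                       blob_radius_range = c(3, 5),
                       blob_color = c(0.85, 0.25, 0.25),
                       background_color = c(0.20, 0.45, 0.18),
                       texture_noise_sd = 0.03, jitter_sd = 1.5,
                       illumination_gradient = FALSE, seed = 1L) {
  if (image_height < 1 || image_width < 1)
    stop("image dimensions must be positive")
  if (bed_width < 1 || road_width < 0)
    stop("bed width must be positive and road width nonnegative")
  if (plant_spacing < 1) stop("plant_spacing must be >= 1")
  if (length(flowering_fraction) > 2L ||
      any(flowering_fraction < 0 | flowering_fraction > 1))
    stop("flowering_fraction must lie in [0, 1]")
  if (length(blob_radius_range) != 2L || blob_radius_range[1] < 1 ||
      blob_radius_range[1] > blob_radius_range[2])
    stop("blob_radius_range must be c(min, max) with 1 <= min <= max")
  if (texture_noise_sd < 0 || jitter_sd < 0)
    stop("noise and jitter SDs must be nonnegative")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    bed_width = as.integer(bed_width), road_width = as.integer(road_width),
    plant_spacing = as.numeric(plant_spacing),
    flowering_fraction = as.numeric(flowering_fraction),
    blob_radius_range = as.numeric(blob_radius_range),
    blob_color = as.numeric(blob_color),
    background_color = as.numeric(background_color),
    texture_noise_sd = as.numeric(texture_noise_sd),
    jitter_sd = as.numeric(jitter_sd),
    illumination_gradient = isTRUE(illumination_gradient),
    seed = as.integer(seed)
  ), class = "field_spec")
}

# lattice site positions (row, col) and the bed column interval of each site
.field_lattice <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  period <- spec$bed_width + spec$road_width
  bed_starts <- seq(0L, W - 1L, by = period)
  rows_n <- max(1L, floor(H / spec$plant_spacing))
  row_centers <- (seq_len(rows_n) - 0.5) * H / rows_n
  out <- NULL
  for (bs in bed_starts) {
    be <- min(bs + spec$bed_width, W)          # bed may be clipped at edge
    bw <- be - bs
    if (bw < 1) next
    ncol_bed <- max(1L, floor(bw / spec$plant_spacing))
    col_centers <- bs + (seq_len(ncol_bed) - 0.5) * bw / ncol_bed
    grid <- expand.grid(row = row_centers, col = col_centers)
    grid$bed_lo <- bs
    grid$bed_hi <- be
    out <- rbind(out, grid)
  }
  out[order(out$row, out$col), , drop = FALSE]
}

#' Generate one synthetic field image with ground truth
#'
#' @param spec a [field_spec()].
#' @param image_id identifier attached to the returned annotation set.
#' @return list with `image` (H x W x 3 array in \[0, 1\], quantized to the
#'   8-bit grid so PNG round-trips are exact) and `annotations` (a
#'   [point_set()] with one point at the center of every rendered
#'   inflorescence blob).
#' @export
generate_field <- function(spec, image_id = "field") {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, .generate_field_impl(spec, image_id))
}

.generate_field_impl <- function(spec, image_id) {
  H <- spec$image_height; W <- spec$image_width
  lattice <- .field_lattice(spec)
  n <- nrow(lattice)
  frac <- spec$flowering_fraction
  if (length(frac) == 2L) frac <- runif(1L, frac[1], frac[2])
  flowering <- rbinom(n, 1L, frac) == 1L
  # positional jitter, clamped to the bed so roads stay plant-free
  jr <- rnorm(n, 0, spec$jitter_sd)
  jc <- rnorm(n, 0, spec$jitter_sd)
  rows <- pmin(pmax(lattice$row + jr, 0), H - 1e-3)
  cols <- pmin(pmax(lattice$col + jc, lattice$bed_lo + 0.5),
               lattice$bed_hi - 0.5)
  radii <- runif(n, spec$blob_radius_range[1], spec$blob_radius_range[2])

  img <- array(rep(spec$background_color, each = H * W), dim = c(H, W, 3L))
  for (i in which(flowering)) {
    img <- .render_blob(img, rows[i], cols[i], radii[i], spec$blob_color)
  }
  img <- img + array(rnorm(H * W * 3L, 0, spec$texture_noise_sd),
                     dim = c(H, W, 3L))
  if (spec$illumination_gradient) {
    theta <- runif(1L, 0, 2 * pi)
    ramp <- outer(seq_len(H) - (H + 1) / 2, seq_len(W) - (W + 1) / 2,
                  function(r, c) r * sin(theta) + c * cos(theta))
    ramp <- ramp / max(abs(ramp), 1)
    img <- img * (1 + 0.15 * array(ramp, dim = c(H, W, 3L)))
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  pts <- cbind(rows[flowering], cols[flowering])
  list(image = img, annotations = point_set(image_id, pts))
}

# alpha-blend a radial linear falloff blob centered at (zr, zc)
.render_blob <- function(img, zr, zc, radius, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r0 <- max(0L, floor(zr - radius)); r1 <- min(H - 1L, ceiling(zr + radius))
  c0 <- max(0L, floor(zc - radius)); c1 <- min(W - 1L, ceiling(zc + radius))
  if (r1 < r0 || c1 < c0) return(img)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - zr)^2, (cc - zc)^2, `+`))
  wgt <- pmax(0, 1 - d / radius)
  for (ch in 1:3) {
    sub <- img[rr + 1L, cc + 1L, ch]
    img[rr + 1L, cc + 1L, ch] <- sub + wgt * (color[ch] - sub)
  }
  img
}

#' Generate an in-memory sample list
#'
#' Draws `n` independent fields from `spec`, one per seed in
#' `spec$seed + offset + 1:n`. Used by the trainer and the test-suite;
#' [generate_dataset()] is the file-writing counterpart.
#'
#' @param spec a [field_spec()] (its `image_height`/`image_width` give the
#'   patch size).
#' @param n number of patches.
#' @param offset seed stream offset, letting callers draw disjoint streams
#'   (e.g. an out-of-domain test split).
#' @param prefix image_id prefix.
#' @return list of samples `list(id, image, points)`.
#' @export
generate_samples <- function(spec, n, offset = 0L, prefix = "patch") {
  lapply(seq_len(n), function(i) {
    si <- spec
    si$seed <- spec$seed + offset + i
    id <- sprintf("%s_%05d", prefix, offset + i)
    fld <- generate_field(si, image_id = id)
    list(id = id, image = fld$image, points = fld$annotations$points)
  })
}

# split sizes that sum to n exactly, largest-remainder on cumulative sums
.split_sizes <- function(n, fractions) {
  cs <- round(cumsum(fractions) * n)
  diff(c(0L, cs))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_patches` synthetic patches as 8-bit RGB PNGs with per-patch
#' annotation CSVs and a manifest assigning each patch to exactly one of
#' train/val/test. Test patches are drawn from a disjoint seed stream so
#' the test split is out-of-domain with respect to the generator draws used
#' for train/val (mirroring evaluation on a field the model never saw).
#'
#' @param spec a [field_spec()]; patch size is taken from its image
#'   dimensions unless `patch_size` is given.
#' @param n_patches total number of patches.
#' @param split_fractions `c(train, val, test)` fractions summing to 1.
#' @param dir output directory (created).
#' @param patch_size optional square patch size overriding the spec's
#'   dimensions.
#' @return the manifest data.frame (`image_id,split,path,annotation_path`),
#'   also written to `dir/manifest.csv`.
#' @export
generate_dataset <- function(spec, n_patches, split_fractions = c(0.8, 0.1, 0.1),
                             dir, patch_size = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  if (n_patches < 1) stop("n_patches must be >= 1")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  if (!is.null(patch_size)) {
    spec$image_height <- as.integer(patch_size)
    spec$image_width <- as.integer(patch_size)
  }
  sizes <- .split_sizes(n_patches, split_fractions)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  trainval <- generate_samples(spec, sizes[1] + sizes[2], offset = 0L)
  # distinct seed stream for the held-out split
  test <- generate_samples(spec, sizes[3], offset = 100000L)
  samples <- c(trainval, test)
  split <- rep(c("train", "val", "test"), times = sizes)
  manifest <- data.frame(
    image_id = vapply(samples, `[[`, "", "id"),
    split = split,
    path = file.path("images", paste0(vapply(samples, `[[`, "", "id"), ".png")),
    annotation_path = file.path(
      "annotations", paste0(vapply(samples, `[[`, "", "id"), ".csv")),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    write_png(s$image, file.path(dir, manifest$path[i]))
    write_annotations(point_set(s$id, s$points),
                      file.path(dir, manifest$annotation_path[i]))
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Load manifest samples into memory
#'
#' @param manifest manifest data.frame or path to a manifest CSV.
#' @param dir dataset root that manifest paths are relative to.
#' @param split optional split filter (`"train"`, `"val"`, `"test"`).
#' @return list of samples `list(id, image, points)` as produced by
#'   [generate_samples()].
#' @export
load_samples <- function(manifest, dir = ".", split = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir) || identical(dir, ".")) dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_png(file.path(dir, manifest$path[i]))
    id <- manifest$image_id[i]
    reg <- stats::setNames(list(dim(img)[1:2]), id)
    ann <- read_annotations(file.path(dir, manifest$annotation_path[i]), reg)
    list(id = id, image = img, points = ann[[id]]$points)
  })
}
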