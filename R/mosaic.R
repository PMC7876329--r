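#' Plan non-overlapping tiling of a large mosaic
#'
#' Computes a tiling layout for field-scale inference: the mosaic is
#' reflect-padded at the bottom/right edges up to the next multiple of
#' `tile_size`, then covered by non-overlapping row-major tiles. The tile
#' size must be divisible by `2^model_depth` so every tile passes the
#' network's pooling constraint.
#'
#' @param mosaic_shape `c(H, W)` in pixels.
#' @param tile_size tile side in pixels (default 256).
#' @param model_depth number of pooling stages of the model that will
#'   consume the tiles.
#' @return object of class `mosaic_layout`: mosaic/padded shapes, pad
#'   amounts, tile offsets (0-based, in the padded frame) and the depth it
#'   was planned for.
#' @export
plan_tiling <- function(mosaic_shape, tile_size = 256L, model_depth = 3L) {
  tile_size <- as.integer(tile_size)
  if (tile_size %% 2L^model_depth != 0L) {
    stop(sprintf("tile_size %d not divisible by 2^depth = %d", tile_size,
                 2L^model_depth))
  }
  H <- as.integer(mosaic_shape[1]); W <- as.integer(mosaic_shape[2])
  ph <- ceiling(H / tile_size) * tile_size
  pw <- ceiling(W / tile_size) * tile_size
  offs <- expand.grid(col_offset = seq(0L, pw - tile_size, by = tile_size),
                      row_offset = seq(0L, ph - tile_size, by = tile_size))
  offs <- offs[, c("row_offset", "col_offset")]
  offs <- offs[order(offs$row_offset, offs$col_offset), ]
  rownames(offs) <- NULL
  structure(list(
    mosaic_shape = c(H, W), tile_size = tile_size,
    padded_shape = c(ph, pw), pad = c(bottom = ph - H, right = pw - W),
    tiles = offs, model_depth = as.integer(model_depth)
  ), class = "mosaic_layout")
}

# reflect-pad an H x W x C array (or matrix) at bottom/right
.pad_reflect <- function(x, bottom, right) {
  d <- dim(x)
  ri <- c(seq_len(d[1]), if (bottom > 0) d[1] - seq_len(bottom))
  ci <- c(seq_len(d[2]), if (right > 0) d[2] - seq_len(right))
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Tiled inference over a field mosaic
#'
#' Runs the density regressor tile by tile over an arbitrarily large RGB
#' mosaic and stitches the per-tile predictions into one field-scale
#' density map. Tiles do not overlap and padding regions are cropped away
#' before stitching, so the stitched integral equals the sum of the
#' cropped tile integrals exactly - counting mass is conserved. Only one
#' tile batch is held in memory at a time.
#'
#' @param model trained `fc_unet`.
#' @param mosaic H x W x 3 numeric array (values \[0, 1\] or 8-bit).
#' @param layout a [plan_tiling()] layout for this mosaic; defaults to
#'   tile 256 planned from the mosaic's own shape.
#' @param batch_size tiles per forward pass.
#' @return H x W numeric density matrix.
#' @export
infer_mosaic <- function(model, mosaic, layout = NULL, batch_size = 8L) {
  stopifnot(inherits(model, "fc_unet"))
  mosaic <- normalize_rgb(mosaic)
  d <- dim(mosaic)
  if (is.null(layout)) {
    layout <- plan_tiling(d[1:2], 256L, model$spec$depth)
  }
  stopifnot(inherits(layout, "mosaic_layout"))
  if (!identical(layout$mosaic_shape, as.integer(d[1:2])))
    stop("layout was planned for a different mosaic shape")
  if (layout$model_depth != model$spec$depth)
    stop(sprintf("layout planned for depth %d but model has depth %d",
                 layout$model_depth, model$spec$depth))
  padded <- .pad_reflect(mosaic, layout$pad["bottom"], layout$pad["right"])
  ts <- layout$tile_size
  den <- matrix(0, layout$padded_shape[1], layout$padded_shape[2])
  tiles <- layout$tiles
  ptr <- .model_ptr(model)
  for (chunk in split(seq_len(nrow(tiles)),
                      ceiling(seq_len(nrow(tiles)) / batch_size))) {
    x <- array(0, dim = c(ts, ts, 3L, length(chunk)))
    for (j in seq_along(chunk)) {
      r0 <- tiles$row_offset[chunk[j]]; c0 <- tiles$col_offset[chunk[j]]
      x[, , , j] <- padded[r0 + seq_len(ts), c0 + seq_len(ts), ]
    }
    p <- .cpp_unet_forward(ptr, x, FALSE, 0.1, FALSE) / .target_scale(model)
    for (j in seq_along(chunk)) {
      r0 <- tiles$row_offset[chunk[j]]; c0 <- tiles$col_offset[chunk[j]]
      den[r0 + seq_len(ts), c0 + seq_len(ts)] <- p[, , j]
    }
  }
  den[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Render a density overlay
#'
#' Maps a density field to the familiar scouting overlay: transparent
#' where there is (near) no flowering, and a yellow-to-red ramp from low
#' to high density elsewhere. The color scale is fixed per field at the
#' 99th percentile of positive density (robust to hot pixels), so blocks
#' within one field are directly comparable.
#'
#' @param density numeric density matrix.
#' @param transparency_floor densities strictly below this are fully
#'   transparent.
#' @param base_image optional H x W x 3 RGB mosaic to alpha-composite the
#'   overlay onto (returns RGB instead of RGBA).
#' @param scale_max optional fixed top of the color scale, overriding the
#'   percentile rule (use to share one scale across fields).
#' @return H x W x 4 RGBA array in \[0, 1\], or H x W x 3 if composited.
#' @export
render_overlay <- function(density, transparency_floor = 1e-3,
                           base_image = NULL, scale_max = NULL) {
  stopifnot(is.matrix(density), transparency_floor >= 0)
  pos <- density[density > 0]
  if (is.null(scale_max)) {
    scale_max <- if (length(pos) > 0) stats::quantile(pos, 0.99, names = FALSE)
                 else 1
  }
  if (scale_max <= 0) scale_max <- 1
  t_ <- pmin(density / scale_max, 1)
  H <- nrow(density); W <- ncol(density)
  rgba <- array(0, dim = c(H, W, 4L))
  rgba[, , 1] <- 1            # red channel full on: yellow (1,1,0) -> red (1,0,0)
  rgba[, , 2] <- 1 - t_
  rgba[, , 4] <- ifelse(density < transparency_floor, 0, 0.7)
  if (is.null(base_image)) return(rgba)
  base_image <- normalize_rgb(base_image)
  out <- base_image
  a <- rgba[, , 4]
  for (ch in 1:3) out[, , ch] <- (1 - a) * base_image[, , ch] + a * rgba[, , ch]
  out
}

# even-odd rule point-in-polygon mask over pixel centers; poly is an n x 2
# matrix of (row, col) vertices, 0-based pixel coordinates
.polygon_mask <- function(shape, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  pr <- poly[, 1]; pc <- poly[, 2]
  if (abs(sum(pr * c(pc[-1], pc[1])) - sum(pc * c(pr[-1], pr[1]))) < 1e-12)
    stop("degenerate polygon: zero area")
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  cols <- 0:(W - 1)
  nv <- nrow(poly)
  for (r in 0:(H - 1)) {
    crossing <- rep(0L, W)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      r1 <- pr[i]; r2 <- pr[j]
      if ((r1 <= r) == (r2 <= r)) next  # edge does not span this row
      cx <- pc[i] + (r - r1) / (r2 - r1) * (pc[j] - pc[i])
      crossing <- crossing + (cols < cx)
    }
    mask[r + 1L, ] <- crossing %% 2L == 1L
  }
  mask
}

#' Per-block counts from a field density map
#'
#' Integrates the density over each management block polygon and ranks
#' blocks from lowest to highest mean density, surfacing the candidates
#' for failed flower induction that warrant ground inspection.
#'
#' @param density field-scale density matrix.
#' @param block_polygons named list of polygons, each an n x 2 matrix of
#'   0-based (row, col) vertices inside the mosaic.
#' @return data.frame `block_id, count, mean_density, rank`, sorted by
#'   ascending mean density (rank 1 = weakest flowering).
#' @export
block_report <- function(density, block_polygons) {
  stopifnot(is.matrix(density), length(block_polygons) > 0)
  ids <- names(block_polygons)
  if (is.null(ids)) ids <- paste0("block_", seq_along(block_polygons))
  rows <- lapply(seq_along(block_polygons), function(i) {
    poly <- as.matrix(block_polygons[[i]])
    if (any(poly[, 1] < 0 | poly[, 1] > nrow(density) |
              poly[, 2] < 0 | poly[, 2] > ncol(density)))
      stop(sprintf("polygon '%s' extends outside the mosaic", ids[i]))
    mask <- .polygon_mask(dim(density), poly)
    npx <- sum(mask)
    data.frame(block_id = ids[i],
               count = integrate_count(density, mask),
               mean_density = if (npx > 0) sum(density[mask]) / npx else 0,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$mean_density, df$block_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
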