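#' Gaussian kernel configuration for density targets
#'
#' @param sigma kernel standard deviation in pixels. The default of 6 px is
#'   the bandwidth at which one blurred point roughly covers one plant at
#'   the imagery's scale; larger values smear neighbouring plants together,
#'   smaller ones make the regression target needle-like and hard to fit.
#' @param truncation_radius kernel support half-width in multiples of
#'   `sigma` (Chebyshev window); at the default 4 the discarded tail is
#'   below 0.01% of the mass of each point.
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(sigma = 6, truncation_radius = 4) {
  if (sigma <= 0) stop("sigma must be positive")
  if (truncation_radius < 3) stop("truncation_radius must be >= 3")
  structure(list(sigma = sigma, truncation_radius = truncation_radius),
            class = "kernel_config")
}

#' Build a ground-truth density map from point annotations
#'
#' Superimposes one normalized isotropic 2-D Gaussian per annotated point:
#'
#' \deqn{D(x) = \sum_{n=1}^{N} \frac{1}{2\pi\sigma^2}
#'       \exp\!\left(-\frac{\lVert x - z_n\rVert^2}{2\sigma^2}\right)}
#'
#' so each point contributes unit mass and integrating the map over a
#' region yields the expected object count in that region. Kernels are
#' truncated at `truncation_radius * sigma` (square window); points near
#' the image border keep only their in-image mass - the map integrates
#' what is visible, with no edge renormalization.
#'
#' @param annotations a [point_set()] or a two-column (row, col) matrix.
#' @param shape `c(H, W)` output size in pixels.
#' @param kernel a [kernel_config()].
#' @param legacy_prefactor if `TRUE`, uses a \eqn{1/(2\pi\sigma)}
#'   prefactor instead of the normalized \eqn{1/(2\pi\sigma^2)}. With it,
#'   per-point mass is \eqn{\sigma} rather than 1 and counting by
#'   integration over-counts by that factor; provided only to reproduce
#'   the unnormalized convention some descriptions print.
#' @return H x W numeric matrix; sums to (approximately) the number of
#'   interior points.
#' @export
gaussian_density_map <- function(annotations, shape,
                                 kernel = kernel_config(),
                                 legacy_prefactor = FALSE) {
  pts <- if (inherits(annotations, "point_set")) annotations$points
         else as.matrix(annotations)
  if (length(pts) == 0L) pts <- matrix(numeric(0), 0L, 2L)
  if (any(shape < 1)) stop("shape must be positive")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  .check_bounds(pts, c(H, W), where = "density target")
  den <- matrix(0, H, W)
  if (nrow(pts) == 0L) return(den)
  sigma <- kernel$sigma
  rad <- kernel$truncation_radius * sigma
  norm <- if (legacy_prefactor) 1 / (2 * pi * sigma) else 1 / (2 * pi * sigma^2)
  for (i in seq_len(nrow(pts))) {
    zr <- pts[i, 1]; zc <- pts[i, 2]
    r0 <- max(0L, ceiling(zr - rad)); r1 <- min(H - 1L, floor(zr + rad))
    c0 <- max(0L, ceiling(zc - rad)); c1 <- min(W - 1L, floor(zc + rad))
    if (r1 < r0 || c1 < c0) next
    vr <- exp(-((r0:r1) - zr)^2 / (2 * sigma^2))
    vc <- exp(-((c0:c1) - zc)^2 / (2 * sigma^2))
    den[(r0:r1) + 1L, (c0:c1) + 1L] <-
      den[(r0:r1) + 1L, (c0:c1) + 1L] + norm * outer(vr, vc)
  }
  den
}

#' Random rotate-and-crop augmentation
#'
#' Training-time augmentation: rotates the image by a random angle about
#' its center (bilinear resampling), applies the same rigid rotation to the
#' point annotations, then crops a random `crop_size` window lying fully
#' inside the rotated image's valid region. Points outside the crop are
#' dropped; returned coordinates are crop-relative. Density targets should
#' be regenerated from the returned points (exact mass preservation) rather
#' than resampling a rotated raster.
#'
#' When `crop_size` equals the image size no fully-valid rotated crop
#' exists except at right angles, so the fallback policy `rigid = TRUE`
#' (also selectable explicitly) draws one of the 8 exact square symmetries
#' (right-angle rotations and flips) instead - no interpolation, no
#' invalid region.
#'
#' @param image H x W x 3 numeric array.
#' @param annotations [point_set()] or (row, col) matrix.
#' @param crop_size side of the square crop in pixels.
#' @param angle rotation angle in radians (counter-clockwise in (row, col)
#'   space); `NULL` draws uniformly from \[0, 2pi).
#' @param rigid force the exact right-angle policy.
#' @return list with `image` (crop_size x crop_size x 3) and `points`
#'   (crop-relative (row, col) matrix).
#' @export
augment_sample <- function(image, annotations, crop_size, angle = NULL,
                           rigid = FALSE) {
  pts <- if (inherits(annotations, "point_set")) annotations$points
         else if (is.null(annotations)) matrix(numeric(0), 0L, 2L)
         else as.matrix(annotations)
  if (length(pts) == 0L) pts <- matrix(numeric(0), 0L, 2L)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (crop_size > H || crop_size > W)
    stop(sprintf("crop_size %d exceeds image size %d x %d", crop_size, H, W))
  if (rigid || (is.null(angle) && crop_size == min(H, W))) {
    return(.augment_rigid(image, pts, crop_size))
  }
  if (is.null(angle)) angle <- runif(1L, 0, 2 * pi)
  rot <- .cpp_rotate_image(image, angle, TRUE, 0)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  # forward point transform (inverse of the sampling map used on pixels)
  rp <- pts
  if (nrow(pts) > 0L) {
    dr <- pts[, 1] - ctr[1]; dc <- pts[, 2] - ctr[2]
    rp <- cbind(cos(angle) * dr - sin(angle) * dc + ctr[1],
                sin(angle) * dr + cos(angle) * dc + ctr[2])
  }
  off <- .sample_valid_crop(H, W, crop_size, angle, ctr)
  crop <- rot[off[1] + seq_len(crop_size), off[2] + seq_len(crop_size), ,
              drop = FALSE]
  keep <- rp[, 1] >= off[1] & rp[, 1] < off[1] + crop_size &
    rp[, 2] >= off[2] & rp[, 2] < off[2] + crop_size
  pts_out <- rp[keep, , drop = FALSE]
  pts_out[, 1] <- pts_out[, 1] - off[1]
  pts_out[, 2] <- pts_out[, 2] - off[2]
  list(image = crop, points = pts_out)
}

# a crop is valid when the pre-images of its four corners fall inside the
# original image; the valid offset set is convex, so corner checks suffice.
# rejection-sample offsets, falling back to the centered crop (always valid
# for crop <= side/sqrt(2), and at worst minimally invalid corners else).
.sample_valid_crop <- function(H, W, s, angle, ctr) {
  inside <- function(r, c) {
    dr <- r - ctr[1]; dc <- c - ctr[2]
    sr <- cos(angle) * dr + sin(angle) * dc + ctr[1]
    sc <- -sin(angle) * dr + cos(angle) * dc + ctr[2]
    sr >= 0 & sr <= H - 1 & sc >= 0 & sc <= W - 1
  }
  for (i in seq_len(200L)) {
    off <- c(runif(1L, 0, H - s), runif(1L, 0, W - s))
    corners_r <- off[1] + c(0, 0, s - 1, s - 1)
    corners_c <- off[2] + c(0, s - 1, 0, s - 1)
    if (all(inside(corners_r, corners_c))) return(floor(off))
  }
  floor(c((H - s) / 2, (W - s) / 2))
}

.augment_rigid <- function(image, pts, crop_size) {
  H <- dim(image)[1]; W <- dim(image)[2]
  k <- sample.int(4L, 1L) - 1L          # number of 90-degree rotations
  flip <- sample.int(2L, 1L) == 2L
  img <- image
  p <- pts
  for (i in seq_len(k)) {
    # 90 degrees counter-clockwise in (row, col): (r, c) -> (C-1-c, r)
    Wc <- dim(img)[2]
    img <- aperm(img[, Wc:1, , drop = FALSE], c(2L, 1L, 3L))
    if (nrow(p) > 0L) p <- cbind(Wc - 1 - p[, 2], p[, 1])
  }
  if (flip) {
    Hc <- dim(img)[1]
    img <- img[Hc:1, , , drop = FALSE]
    if (nrow(p) > 0L) p <- cbind(Hc - 1 - p[, 1], p[, 2])
  }
  Hc <- dim(img)[1]; Wc <- dim(img)[2]
  off <- c(if (Hc > crop_size) sample.int(Hc - crop_size, 1L) else 0L,
           if (Wc > crop_size) sample.int(Wc - crop_size, 1L) else 0L)
  crop <- img[off[1] + seq_len(crop_size), off[2] + seq_len(crop_size), ,
              drop = FALSE]
  if (nrow(p) > 0L) {
    keep <- p[, 1] >= off[1] & p[, 1] < off[1] + crop_size &
      p[, 2] >= off[2] & p[, 2] < off[2] + crop_size
    p <- p[keep, , drop = FALSE]
    p[, 1] <- p[, 1] - off[1]
    p[, 2] <- p[, 2] - off[2]
  }
  list(image = crop, points = p)
}

#' Split an image or density map into non-overlapping tiles
#'
#' Row-major exact partition into `tile_size` x `tile_size` tiles, each
#' carrying its 0-based `(row_offset, col_offset)`. Dimensions must be
#' divisible by `tile_size`; for arbitrary sizes use [plan_tiling()], which
#' pads first.
#'
#' @param x matrix or H x W x C array.
#' @param tile_size tile side in pixels.
#' @return list of `list(data, row_offset, col_offset)`.
#' @export
split_into_tiles <- function(x, tile_size) {
  d <- dim(x)
  if (d[1] %% tile_size != 0L || d[2] %% tile_size != 0L) {
    stop(sprintf(
      "dimensions %d x %d not divisible by tile_size %d; use plan_tiling() to pad",
      d[1], d[2], tile_size))
  }
  tiles <- list()
  for (r0 in seq(0L, d[1] - tile_size, by = tile_size)) {
    for (c0 in seq(0L, d[2] - tile_size, by = tile_size)) {
      data <- if (length(d) == 2L) {
        x[r0 + seq_len(tile_size), c0 + seq_len(tile_size), drop = FALSE]
      } else {
        x[r0 + seq_len(tile_size), c0 + seq_len(tile_size), , drop = FALSE]
      }
      tiles[[length(tiles) + 1L]] <-
        list(data = data, row_offset = r0, col_offset = c0)
    }
  }
  tiles
}
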