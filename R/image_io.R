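#' Read and write PNG images
#'
#' Minimal 8-bit PNG support (grayscale, RGB, RGBA; no interlacing) backed
#' by zlib. Values are exchanged as numeric arrays in \[0, 1\]; writing
#' quantizes to 8 bits, so `read_png(write_png(x))` returns `x` exactly
#' when `x` is already on the 8-bit grid (as all generator output is).
#'
#' @param img H x W x C numeric array (C in 1, 3, 4) with values in
#'   \[0, 1\], or an H x W matrix for grayscale.
#' @param path file path.
#' @return `read_png` returns an H x W x C numeric array in \[0, 1\];
#'   `write_png` returns `path` invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  if (length(d) != 3L) stop("img must be an H x W x C array")
  v <- pmin(pmax(img, 0), 1)
  q <- as.integer(round(v * 255))
  # interleave channels row-major as PNG expects
  px <- aperm(array(q, d), c(3L, 2L, 1L))
  bytes <- .cpp_png_encode(as.raw(px), d[1], d[2], d[3])
  writeBin(bytes, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  dec <- .cpp_png_decode(readBin(path, "raw", file.info(path)$size))
  v <- as.integer(dec$pixels) / 255
  arr <- array(v, dim = c(dec$channels, dec$width, dec$height))
  aperm(arr, c(3L, 2L, 1L))
}

#' Read and write density rasters as single-band float32 TIFF
#'
#' Density maps are persisted as uncompressed 32-bit float, single-band,
#' little-endian TIFF. When a georeference is supplied the GeoTIFF
#' `ModelPixelScale` and `ModelTiepoint` tags are written so GIS tools can
#' place the raster; no CRS database is embedded (the CRS travels with the
#' workflow, not the file). Writing is deterministic: identical input
#' produces byte-identical files.
#'
#' @param density numeric matrix (H x W).
#' @param path file path.
#' @param pixel_scale optional `c(sx, sy)` ground units per pixel.
#' @param tiepoint optional `c(x, y)` world position of pixel (0, 0).
#' @return `read_density_tiff` returns the density matrix with attributes
#'   `pixel_scale`/`tiepoint` when present; `write_density_tiff` returns
#'   `path` invisibly.
#' @export
write_density_tiff <- function(density, path, pixel_scale = NULL,
                               tiepoint = NULL) {
  stopifnot(is.matrix(density))
  h <- nrow(density); w <- ncol(density)
  con <- file(path, "wb")
  on.exit(close(con))
  geo <- !is.null(pixel_scale) || !is.null(tiepoint)
  ntags <- 10L + if (geo) 2L else 0L
  # layout: header(8) + IFD + tag payloads + pixel strip
  ifd_off <- 8L
  ifd_size <- 2L + ntags * 12L + 4L
  payload_off <- ifd_off + ifd_size
  # payloads: bits-per-sample fits inline; doubles for geo tags
  geo_scale_off <- payload_off
  n_scale <- 3L
  geo_tie_off <- geo_scale_off + if (geo) 8L * n_scale else 0L
  n_tie <- 6L
  data_off <- geo_tie_off + if (geo) 8L * n_tie else 0L

  writeChar("II", con, eos = NULL)   # little-endian
  writeBin(42L, con, size = 2L)      # magic
  writeBin(ifd_off, con, size = 4L)  # first IFD offset
  writeBin(ntags, con, size = 2L)
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2L)
    writeBin(as.integer(type), con, size = 2L)
    writeBin(as.integer(count), con, size = 4L)
    writeBin(as.integer(value), con, size = 4L)
  }
  tag(256L, 4L, 1L, w)              # ImageWidth
  tag(257L, 4L, 1L, h)              # ImageLength
  tag(258L, 3L, 1L, 32L)            # BitsPerSample
  tag(259L, 3L, 1L, 1L)             # Compression = none
  tag(262L, 3L, 1L, 1L)             # Photometric = BlackIsZero
  tag(273L, 4L, 1L, data_off)       # StripOffsets
  tag(277L, 3L, 1L, 1L)             # SamplesPerPixel
  tag(278L, 4L, 1L, h)              # RowsPerStrip
  tag(279L, 4L, 1L, 4L * h * w)     # StripByteCounts
  tag(339L, 3L, 1L, 3L)             # SampleFormat = IEEE float
  if (geo) {
    tag(33550L, 12L, n_scale, geo_scale_off)  # ModelPixelScale
    tag(33922L, 12L, n_tie, geo_tie_off)      # ModelTiepoint
  }
  writeBin(0L, con, size = 4L)      # next IFD = none
  if (geo) {
    ps <- if (is.null(pixel_scale)) c(1, 1) else pixel_scale
    tp <- if (is.null(tiepoint)) c(0, 0) else tiepoint
    writeBin(as.double(c(ps[1], ps[2], 0)), con, size = 8L)
    writeBin(as.double(c(0, 0, 0, tp[1], tp[2], 0)), con, size = 8L)
  }
  # pixel data row-major
  writeBin(as.double(t(density)), con, size = 4L)
  invisible(path)
}

#' @rdname write_density_tiff
#' @export
read_density_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(bytes[1:2]) != "II") stop("not a little-endian TIFF: ", path)
  u16 <- function(off) sum(as.integer(bytes[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(bytes[off + 1:4]) * 256^(0:3))
  ifd <- u32(4L)
  ntags <- u16(ifd)
  tags <- list()
  for (i in seq_len(ntags)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tags[[as.character(u16(off))]] <-
      list(type = u16(off + 2L), count = u32(off + 4L),
           value = u32(off + 8L))
  }
  need <- c("256", "257", "273", "279")
  if (!all(need %in% names(tags))) stop("unsupported TIFF layout: ", path)
  if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1L)
    stop("compressed TIFF not supported")
  if (!is.null(tags[["339"]]) && tags[["339"]]$value != 3L)
    stop("expected IEEE float sample format")
  w <- tags[["256"]]$value; h <- tags[["257"]]$value
  data_off <- tags[["273"]]$value
  vals <- readBin(bytes[(data_off + 1L):(data_off + 4L * h * w)],
                  "double", n = h * w, size = 4L)
  density <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  rdbl <- function(off, n) readBin(bytes[(off + 1L):(off + 8L * n)],
                                   "double", n = n, size = 8L)
  if (!is.null(tags[["33550"]])) {
    s <- rdbl(tags[["33550"]]$value, 3L)
    attr(density, "pixel_scale") <- s[1:2]
  }
  if (!is.null(tags[["33922"]])) {
    tp <- rdbl(tags[["33922"]]$value, 6L)
    attr(density, "tiepoint") <- tp[4:5]
  }
  density
}
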