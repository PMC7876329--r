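#' Point annotation set
#'
#' A set of point labels (one per counted object) for a single image.
#' Coordinates are continuous, 0-based, `(row, col)`, pixel-center
#' convention; a point is in bounds for an H x W image when it lies in
#' `[0, H) x [0, W)`.
#'
#' @param image_id character scalar identifying the image.
#' @param points a numeric matrix / data.frame with two columns (row, col),
#'   or `NULL` for an empty set.
#' @return an object of class `point_set`: a list with `image_id`, a
#'   two-column `points` matrix and the derived `count`.
#' @export
point_set <- function(image_id, points = NULL) {
  if (is.null(points)) points <- matrix(numeric(0), 0L, 2L)
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 2L)
  if (ncol(points) != 2L) stop("points must have two columns (row, col)")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  colnames(points) <- c("row", "col")
  rownames(points) <- NULL
  structure(list(image_id = as.character(image_id), points = points,
                 count = nrow(points)),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> image '%s': %d points\n", x$image_id, x$count))
  invisible(x)
}

# bounds check against an image shape; `where` labels error messages
.check_bounds <- function(points, shape, where = "annotation") {
  if (nrow(points) == 0L) return(invisible(TRUE))
  bad <- which(points[, 1] < 0 | points[, 1] >= shape[1] |
                 points[, 2] < 0 | points[, 2] >= shape[2])
  if (length(bad) > 0L) {
    p <- points[bad[1], ]
    stop(sprintf(
      "%s point (%g, %g) outside image bounds [0, %d) x [0, %d)",
      where, p[1], p[2], shape[1], shape[2]))
  }
  invisible(TRUE)
}

.registry_shape <- function(image_registry, id) {
  if (is.data.frame(image_registry)) {
    i <- match(id, image_registry$image_id)
    if (is.na(i)) return(NULL)
    return(c(image_registry$height[i], image_registry$width[i]))
  }
  image_registry[[id]]
}

#' Read point annotations
#'
#' Reads the package's annotation interchange formats: CSV with header
#' `image_id,row,col` or GeoJSON `Point` features (property `image_id`,
#' pixel coordinates either directly or through an affine georeference).
#' Every point is validated against its image's bounds, exact duplicate
#' `(image_id, row, col)` records are rejected, and images registered with
#' zero points come back as empty sets.
#'
#' @param path file to read.
#' @param image_registry image dimensions to validate against: a named list
#'   of `c(height, width)` or a data.frame with columns `image_id`,
#'   `height`, `width`. All `image_id`s in the file must be registered.
#' @param affine optional affine georeference (see [write_annotations()])
#'   used to convert GeoJSON world coordinates back to pixels.
#' @return named list of [point_set()] objects, one per registered image
#'   (empty sets for images without points).
#' @export
read_annotations <- function(path, image_registry, affine = NULL) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    df <- .read_annotations_geojson(path, affine)
  } else {
    df <- .read_annotations_csv(path)
  }
  ids <- if (is.data.frame(image_registry)) image_registry$image_id
         else names(image_registry)
  unknown <- setdiff(unique(df$image_id), ids)
  if (length(unknown) > 0L) {
    stop("annotation references unknown image_id: ",
         paste(unknown, collapse = ", "))
  }
  key <- paste(df$image_id, df$row, df$col, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate annotation (%s, %g, %g) at line %d",
                 d$image_id, d$row, d$col, d$line))
  }
  out <- list()
  for (id in ids) {
    sub <- df[df$image_id == id, , drop = FALSE]
    shape <- .registry_shape(image_registry, id)
    if (nrow(sub) > 0L) {
      oob <- which(sub$row < 0 | sub$row >= shape[1] |
                     sub$col < 0 | sub$col >= shape[2])
      if (length(oob) > 0L) {
        stop(sprintf(
          "point (%g, %g) out of bounds [0, %d) x [0, %d) for image '%s' (line %d)",
          sub$row[oob[1]], sub$col[oob[1]], shape[1], shape[2], id,
          sub$line[oob[1]]))
      }
    }
    out[[id]] <- point_set(id, cbind(sub$row, sub$col))
  }
  out
}

.read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have header image_id,row,col (got: ",
         paste(names(df), collapse = ","), ")")
  }
  df <- df[, need]
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (nrow(df) > 0L) {
    for (cn in c("row", "col")) {
      v <- df[[cn]]
      if (!is.numeric(v) || any(!is.finite(v))) {
        bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
        stop(sprintf("malformed %s value at line %d of %s", cn,
                     df$line[bad], path))
      }
    }
  }
  df
}

.read_annotations_geojson <- function(path, affine = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  n <- length(gj$features)
  df <- data.frame(image_id = character(n), row = numeric(n),
                   col = numeric(n), line = seq_len(n))
  for (i in seq_len(n)) {
    f <- gj$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
      stop(sprintf("feature %d is not a Point", i))
    xy <- unlist(f$geometry$coordinates)
    if (length(xy) < 2 || any(!is.finite(xy)))
      stop(sprintf("malformed coordinates in feature %d", i))
    if (!is.null(f$properties$pixel_row) && is.null(affine)) {
      rc <- c(f$properties$pixel_row, f$properties$pixel_col)
    } else if (!is.null(affine)) {
      rc <- .affine_inverse(affine, xy[1], xy[2])
    } else {
      # non-georeferenced: coordinates are (x = col, y = row)
      rc <- c(xy[2], xy[1])
    }
    df$image_id[i] <- f$properties$image_id
    df$row[i] <- rc[1]
    df$col[i] <- rc[2]
  }
  df
}

#' Write point annotations
#'
#' Writes a mapping of [point_set()]s in a deterministic order (by
#' `image_id`, then row, then col) so repeated writes are byte-identical.
#' The CSV dialect is the package-wide interchange format
#' (`image_id,row,col`); GeoJSON writes `Point` features carrying the pixel
#' coordinates as properties and, when an affine georeference is supplied,
#' world coordinates in the geometry.
#'
#' @param mapping a named list of [point_set()]s (or a single `point_set`).
#' @param path output file.
#' @param dialect `"csv"` or `"geojson"`.
#' @param affine optional georeference for the GeoJSON dialect: numeric
#'   vector `c(x0, dx_col, dx_row, y0, dy_col, dy_row)` so that
#'   `x = x0 + dx_col*col + dx_row*row`, `y = y0 + dy_col*col + dy_row*row`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(mapping, path, dialect = c("csv", "geojson"),
                              affine = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(mapping, "point_set")) {
    mapping <- stats::setNames(list(mapping), mapping$image_id)
  }
  rows <- do.call(rbind, lapply(mapping, function(ps) {
    if (ps$count == 0L) return(NULL)
    data.frame(image_id = ps$image_id, row = ps$points[, 1],
               col = ps$points[, 2], stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(image_id = character(0), row = numeric(0),
                       col = numeric(0))
  }
  rows <- rows[order(rows$image_id, rows$row, rows$col), , drop = FALSE]
  if (dialect == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows$row[i]; cc <- rows$col[i]
      coords <- if (is.null(affine)) c(cc, r) else .affine_forward(affine, r, cc)
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = coords),
           properties = list(image_id = rows$image_id[i],
                             pixel_row = r, pixel_col = cc))
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = feats), path,
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# affine c(x0, dx_col, dx_row, y0, dy_col, dy_row): pixel (row, col) -> (x, y)
.affine_forward <- function(a, row, col) {
  c(a[1] + a[2] * col + a[3] * row, a[4] + a[5] * col + a[6] * row)
}

.affine_inverse <- function(a, x, y) {
  m <- matrix(c(a[3], a[6], a[2], a[5]), 2L, 2L)  # cols: d/drow, d/dcol
  rc <- solve(m, c(x - a[1], y - a[4]))
  c(rc[1], rc[2])
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with columns `image_id,split,path,annotation_path`
#' assigning each patch to exactly one of the train/val/test splits.
#' Extra provenance columns (e.g. `round`, `source` added by
#' [ingest_corrections()]) survive a round-trip.
#'
#' @param path manifest CSV path.
#' @param manifest a data.frame with at least the four manifest columns.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "split", "path", "annotation_path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  df
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
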