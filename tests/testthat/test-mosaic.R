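test_that("plan_tiling pads to tile multiples and covers exactly", {
  lay <- plan_tiling(c(512L, 512L), 256L, 3L)
  expect_equal(nrow(lay$tiles), 4L)
  expect_equal(unname(lay$pad), c(0L, 0L))

  lay2 <- plan_tiling(c(300L, 300L), 256L, 3L)
  expect_equal(lay2$padded_shape, c(512L, 512L))
  expect_equal(unname(lay2$pad), c(212L, 212L))
  expect_equal(nrow(lay2$tiles), 4L)

  # every padded pixel covered exactly once
  cover <- matrix(0L, lay2$padded_shape[1], lay2$padded_shape[2])
  for (i in seq_len(nrow(lay2$tiles))) {
    r0 <- lay2$tiles$row_offset[i]; c0 <- lay2$tiles$col_offset[i]
    cover[r0 + 1:256, c0 + 1:256] <- cover[r0 + 1:256, c0 + 1:256] + 1L
  }
  expect_true(all(cover == 1L))

  expect_error(plan_tiling(c(100L, 100L), 100L, 3L), "not divisible")
})

test_that("single-tile mosaics reproduce predict_density bit-identically", {
  m <- build_model(model_spec(depth = 3L, base_channels = 2L), seed = 60L)
  set.seed(60)
  mosaic <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  lay <- plan_tiling(c(32L, 32L), 32L, 3L)
  expect_identical(infer_mosaic(m, mosaic, lay),
                   predict_density(m, mosaic))
})

test_that("stitching conserves mass exactly and streams tile by tile", {
  m <- build_model(model_spec(depth = 3L, base_channels = 2L), seed = 61L)
  set.seed(61)
  mosaic <- array(runif(80 * 112 * 3), dim = c(80, 112, 3))
  lay <- plan_tiling(c(80L, 112L), 32L, 3L)
  den <- infer_mosaic(m, mosaic, lay, batch_size = 3L)
  expect_identical(dim(den), c(80L, 112L))
  # mass equals the sum of cropped per-tile integrals
  padded <- floracount:::.pad_reflect(normalize_rgb(mosaic),
                                      lay$pad["bottom"], lay$pad["right"])
  tile_sum <- 0
  for (i in seq_len(nrow(lay$tiles))) {
    r0 <- lay$tiles$row_offset[i]; c0 <- lay$tiles$col_offset[i]
    p <- predict_density(m, padded[r0 + 1:32, c0 + 1:32, ])
    rkeep <- seq_len(max(0, min(32, 80 - r0)))
    ckeep <- seq_len(max(0, min(32, 112 - c0)))
    tile_sum <- tile_sum + sum(p[rkeep, ckeep])
  }
  expect_equal(integrate_count(den), tile_sum, tolerance = 1e-12)
})

test_that("mismatched layouts are refused", {
  m <- build_model(model_spec(depth = 3L, base_channels = 2L), seed = 62L)
  mosaic <- array(0.5, dim = c(64, 64, 3))
  expect_error(infer_mosaic(m, mosaic, plan_tiling(c(32L, 32L), 32L, 3L)),
               "different mosaic shape")
  expect_error(infer_mosaic(m, mosaic, plan_tiling(c(64L, 64L), 32L, 4L)),
               "depth")
})

test_that("a constant mosaic predicts near-constant density away from
          tile borders", {
  m <- build_model(model_spec(depth = 2L, base_channels = 2L), seed = 63L)
  mosaic <- array(0.4, dim = c(64, 64, 3))
  den <- infer_mosaic(m, mosaic, plan_tiling(c(64L, 64L), 32L, 2L))
  # interior of each tile: identical values tile-to-tile
  expect_equal(den[10:20, 10:20], den[42:52, 10:20], tolerance = 1e-6)
  interior_sd <- stats::sd(den[12:22, 12:22])
  expect_lt(interior_sd, 1e-6 + 0.05 * (mean(den) + 1e-9))
})

test_that("overlay is transparent at zero, monotone to red, and
          deterministic through the raster round-trip", {
  expect_true(all(render_overlay(matrix(0, 8, 8))[, , 4] == 0))
  den <- matrix(seq(0, 0.6, length.out = 64), 8, 8)
  ov <- render_overlay(den, transparency_floor = 1e-3)
  redfrac <- ov[, , 1] / (ov[, , 1] + ov[, , 2] + ov[, , 3])
  o <- order(den)
  expect_true(all(diff(redfrac[o]) >= -1e-12))
  expect_true(all(ov[, , 4][den < 1e-3] == 0))
  expect_true(all(ov[, , 4][den >= 1e-3] > 0))

  p <- withr::local_tempfile(fileext = ".tif")
  write_density_tiff(den, p)
  back <- read_density_tiff(p)
  ov1 <- render_overlay(structure(back, pixel_scale = NULL,
                                  tiepoint = NULL))
  ov2 <- render_overlay(structure(read_density_tiff(p), pixel_scale = NULL,
                                  tiepoint = NULL))
  expect_identical(ov1, ov2)
})

test_that("block_report integrates per polygon, additively, and ranks the
          weak bed lowest", {
  den <- matrix(0, 60, 60)
  den[11:50, 6:15] <- 0.010   # strong bed
  den[11:50, 26:35] <- 0.009  # strong bed
  den[11:50, 46:55] <- 0.002  # weak bed
  # polygons in 0-based (row, col) coords around each bed
  poly <- function(c0, c1) rbind(c(10, c0), c(10, c1), c(50, c1), c(50, c0))
  blocks <- list(bed_a = poly(5, 15), bed_b = poly(25, 35),
                 bed_c = poly(45, 55))
  rep <- block_report(den, blocks)
  expect_equal(rep$block_id[1], "bed_c")
  expect_equal(rep$rank, 1:3)
  expect_equal(sum(rep$count), integrate_count(den), tolerance = 1e-9)

  one <- block_report(den, list(all = rbind(c(0, 0), c(0, 60), c(60, 60),
                                            c(60, 0))))
  expect_equal(one$count, integrate_count(den))

  expect_error(block_report(den, list(bad = rbind(c(0, 0), c(1, 1)))),
               "degenerate")
  expect_error(block_report(den, list(out = rbind(c(-5, 0), c(0, 70),
                                                  c(70, 70)))),
               "outside")
})
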