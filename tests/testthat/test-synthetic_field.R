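test_that("spec validation rejects out-of-range parameters", {
  expect_error(field_spec(image_height = 0), "positive")
  expect_error(field_spec(flowering_fraction = 1.2), "\\[0, 1\\]")
  expect_error(field_spec(blob_radius_range = c(5, 3)), "min <= max")
  expect_error(field_spec(plant_spacing = 0), "plant_spacing")
})

test_that("flowering_fraction = 0 yields no blobs and no annotations", {
  spec <- field_spec(image_height = 96L, image_width = 96L,
                     flowering_fraction = 0, seed = 3L)
  fld <- generate_field(spec)
  expect_equal(fld$annotations$count, 0L)
  expect_identical(dim(fld$image), c(96L, 96L, 3L))
  # no blob: red channel stays near the background everywhere
  expect_lt(max(fld$image[, , 1]),
            spec$background_color[1] + 6 * spec$texture_noise_sd)
})

test_that("generation is bit-identical under a fixed spec + seed", {
  spec <- field_spec(image_height = 80L, image_width = 120L, seed = 17L,
                     illumination_gradient = TRUE)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations$points, b$annotations$points)
})

test_that("every lattice site flowers when fraction = 1, jitter = 0, and blobs
          are countable by connected components", {
  spec <- field_spec(image_height = 160L, image_width = 160L,
                     bed_width = 40L, road_width = 24L, plant_spacing = 16L,
                     flowering_fraction = 1, jitter_sd = 0,
                     texture_noise_sd = 0, seed = 5L)
  fld <- generate_field(spec)
  lattice <- floracount:::.field_lattice(spec)
  expect_equal(fld$annotations$count, nrow(lattice))
  expect_true(all(abs(fld$annotations$points[, 1] - lattice$row) < 1e-9))
  # oracle: count blobs by 4-connected component labelling of the redness
  # excess (red minus green channel)
  red <- fld$image[, , 1] - fld$image[, , 2] > 0.15
  lab <- matrix(0L, nrow(red), ncol(red))
  nlab <- 0L
  for (r in seq_len(nrow(red))) {
    for (cc in seq_len(ncol(red))) {
      if (!red[r, cc] || lab[r, cc] > 0L) next
      nlab <- nlab + 1L
      queue <- list(c(r, cc))
      lab[r, cc] <- nlab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- p[1] + d[1]; c2 <- p[2] + d[2]
          if (rr < 1 || rr > nrow(red) || c2 < 1 || c2 > ncol(red)) next
          if (red[rr, c2] && lab[rr, c2] == 0L) {
            lab[rr, c2] <- nlab
            queue <- c(queue, list(c(rr, c2)))
          }
        }
      }
    }
  }
  expect_equal(nlab, fld$annotations$count)
  # each annotation sits inside its blob (a red pixel within blob radius)
  for (i in seq_len(fld$annotations$count)) {
    p <- round(fld$annotations$points[i, ]) + 1
    expect_true(red[p[1], p[2]])
  }
})

test_that("no annotation ever falls inside a road stripe", {
  for (seed in c(1L, 2L, 3L)) {
    spec <- field_spec(image_height = 128L, image_width = 200L,
                       bed_width = 30L, road_width = 20L, jitter_sd = 6,
                       flowering_fraction = 1, seed = seed)
    fld <- generate_field(spec)
    cols <- fld$annotations$points[, 2]
    period <- spec$bed_width + spec$road_width
    within_bed <- (cols %% period) < spec$bed_width
    expect_true(all(within_bed))
    expect_true(all(cols >= 0 & cols < spec$image_width))
  }
})

test_that("generate_dataset partitions patches exactly and reproducibly", {
  spec <- field_spec(image_height = 32L, image_width = 32L, seed = 9L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man <- generate_dataset(spec, 10L, c(0.8, 0.1, 0.1), dir1)
  expect_equal(as.vector(table(factor(man$split,
                                      c("train", "val", "test")))),
               c(8L, 1L, 1L))
  expect_equal(anyDuplicated(man$image_id), 0L)
  expect_true(all(file.exists(file.path(dir1, man$path))))
  expect_true(all(file.exists(file.path(dir1, man$annotation_path))))
  man2 <- generate_dataset(spec, 10L, c(0.8, 0.1, 0.1), dir2)
  expect_identical(man, man2)
  # regenerated files are byte-identical
  f1 <- file.path(dir1, man$path[1])
  f2 <- file.path(dir2, man$path[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generate_dataset validates split fractions", {
  spec <- field_spec(image_height = 32L, image_width = 32L)
  expect_error(generate_dataset(spec, 10L, c(0.8, 0.1, 0.2), tempdir()),
               "sum to 1")
})

test_that("dataset round-trips through PNG + CSV loading", {
  spec <- field_spec(image_height = 48L, image_width = 48L, seed = 21L)
  dir <- withr::local_tempdir()
  man <- generate_dataset(spec, 4L, c(0.5, 0.25, 0.25), dir)
  loaded <- load_samples(man, dir, "train")
  fresh <- generate_samples(spec, 2L)
  expect_equal(length(loaded), 2L)
  expect_equal(loaded[[1]]$image, fresh[[1]]$image)
  p0 <- fresh[[1]]$points
  p0 <- p0[order(p0[, 1], p0[, 2]), , drop = FALSE]
  expect_equal(loaded[[1]]$points, p0, ignore_attr = TRUE)
})
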