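# density maps with a controllable (t_c, t_d): `npk` spikes of height 0.2
# (each a clean peak) plus sub-threshold mass to set the integral
make_map <- function(t_c, npk, size = 32L) {
  den <- matrix(0, size, size)
  if (npk > 0) {
    pos <- cbind(4 + 6 * (seq_len(npk) - 1) %% 5, 4 + 6 * (seq_len(npk) - 1) %/% 5)
    den[pos + 1] <- 0.2
  }
  rest <- t_c - sum(den)
  stopifnot(rest >= 0)
  den[size, size] <- 0  # keep corner free
  den <- den + (rest / (size * size - npk)) *
    (1 * (den == 0)) * 0.999999
  den
}

test_that("rank_samples orders by descending CountDiff with id tie-break", {
  # diffs: a = 5, b = 12, c = 3
  maps <- list(a = make_map(7, 2), b = make_map(13, 1), c = make_map(6, 3))
  cfg <- peak_config(gamma = 0.05, delta = 4)
  pr <- rank_samples(maps, cfg)
  expect_equal(pr$sample_id, c("b", "a", "c"))
  expect_equal(pr$count_diff, pr$t_c - pr$t_d)

  ties <- list(z = make_map(5, 1), a = make_map(5, 1), m = make_map(5, 1))
  pr2 <- rank_samples(ties, cfg)
  expect_equal(pr2$sample_id, c("a", "m", "z"))

  expect_error(rank_samples(list()), "empty")
})

test_that("ranking equals a brute-force recomputation", {
  set.seed(30)
  maps <- lapply(1:6, function(i) random_density_field(c(32, 32), n_bumps = i))
  names(maps) <- sprintf("s%02d", sample(1:6))
  cfg <- peak_config(gamma = 0.02, delta = 4)
  pr <- rank_samples(maps, cfg)
  brute <- vapply(names(maps), function(id) {
    sum(maps[[id]]) - nrow(oracle_peaks(maps[[id]], 0.02, 4))
  }, 1)
  ord <- names(sort(-brute))  # names(sort()) breaks ties by name
  expect_equal(pr$sample_id, ord)
  expect_equal(pr$count_diff[match(names(maps), pr$sample_id)],
               unname(brute))
})

test_that("ingest_corrections appends to train only and regenerates targets", {
  dir <- withr::local_tempdir()
  spec <- field_spec(image_height = 32L, image_width = 32L, seed = 31L)
  man <- generate_dataset(spec, 6L, c(0.5, 0.25, 0.25), dir)
  val_before <- man[man$split == "val", ]

  # corrected points for 10 new pool samples (images written first)
  corr <- list()
  set.seed(31)
  for (i in 1:10) {
    id <- sprintf("pool_%03d", i)
    img <- generate_field(field_spec(image_height = 32L, image_width = 32L,
                                     seed = 500L + i), id)$image
    write_png(img, file.path(dir, "images", paste0(id, ".png")))
    corr[[id]] <- point_set(id, scatter_points(3, c(32, 32), 2, 2))
  }
  kernel <- kernel_config(sigma = 2)
  man2 <- ingest_corrections(corr, man, dir, kernel, round = 1L)
  expect_equal(nrow(man2), nrow(man) + 10L)
  expect_equal(sum(man2$split == "train"), sum(man$split == "train") + 10L)
  expect_equal(man2[man2$split == "val", names(val_before)],
               val_before, ignore_attr = TRUE)
  expect_true(all(man2$source[man2$split == "train" &
                                !is.na(man2$source)] == "oracle"))
  # regenerated target integrates to the corrected count
  tgt <- read_density_tiff(file.path(dir, "targets", "pool_001.tif"))
  expect_equal(integrate_count(tgt), corr$pool_001$count, tolerance = 0.1)
  # round-trip of the corrected annotations
  back <- read_annotations(file.path(dir, "annotations", "pool_001.csv"),
                           list(pool_001 = c(32L, 32L)))
  expect_equal(back$pool_001$count, 3L)

  # split contamination is refused
  vid <- val_before$image_id[1]
  bad <- stats::setNames(list(point_set(vid, rbind(c(1, 1)))), vid)
  expect_error(ingest_corrections(bad, man2, dir, kernel), "contamination")
})

test_that("incremental_experiment honours levels, exhaustion and top-k
          selection on a miniature pool", {
  pool <- tiny_field_samples(8, size = 32L, seed = 40L)
  va <- tiny_field_samples(2, size = 32L, seed = 40L, offset = 200L)
  te <- tiny_field_samples(2, size = 32L, seed = 40L, offset = 400L)
  cfg <- training_config(batch_size = 4L, max_epochs = 2L,
                         early_stop_patience = 2L, crop_size = 32L,
                         sigma = 4, seed = 50L)
  spec <- model_spec(depth = 2L, base_channels = 2L)
  pcfg <- peak_config(gamma = 0.01, delta = 4)
  res <- incremental_experiment(pool, va, te, c(3L, 5L, 8L), spec, cfg,
                                pcfg)
  expect_equal(res$ledger$training_size, c(3L, 5L, 8L))
  all_sel <- unlist(res$selections)
  expect_equal(anyDuplicated(all_sel), 0L)
  expect_setequal(all_sel, vapply(pool, `[[`, "", "id"))  # exhaustion
  # round-2 additions are exactly the top-k CountDiff of the remaining
  # pool under the round-1 model, recomputed independently
  rem <- setdiff(vapply(pool, `[[`, "", "id"), res$selections[[1]])
  m1 <- res$round_models[[1]]
  kappa <- floracount:::.target_scale(m1)
  diffs <- vapply(rem, function(id) {
    den <- predict_density(m1, pool[[match(id, vapply(pool, `[[`, "",
                                                      "id"))]]$image)
    sum(den) - nrow(oracle_peaks(den * kappa, pcfg$gamma, pcfg$delta))
  }, 1)
  want <- names(sort(-diffs))[1:2]
  # same tie rule as rank_samples: descending diff, ascending id
  expect_equal(sort(res$selections[[2]]), sort(want))
  expect_error(
    incremental_experiment(pool, va, te, c(3L, 20L), spec, cfg, pcfg),
    "exceeds pool")
  expect_error(
    incremental_experiment(pool, va, te, c(5L, 5L), spec, cfg, pcfg),
    "strictly increasing")
})
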