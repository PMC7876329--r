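test_that("mse_loss matches its definition", {
  a <- matrix(runif(16), 4, 4)
  expect_equal(mse_loss(a, a), 0)
  t2 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(mse_loss(matrix(0, 2, 2), t2), 0.25)
  set.seed(20)
  p <- matrix(rnorm(35), 5, 7)
  q <- matrix(rnorm(35), 5, 7)
  brute <- 0
  for (i in 1:5) for (j in 1:7) brute <- brute + (p[i, j] - q[i, j])^2
  expect_equal(mse_loss(p, q), brute / 35)
  expect_error(mse_loss(p, matrix(0, 2, 2)), "shapes differ")
})

test_that("training_config validates its fields", {
  expect_error(training_config(learning_rate = 0), "positive")
  expect_error(training_config(beta2 = 1), "betas")
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_error(training_config(early_stop_patience = 0), "patience")
})

test_that("early stopping halts after `patience` non-improving epochs and
          returns the best-epoch weights", {
  vals <- c(0.5, 0.6, 0.7, 0.8)  # strictly increasing from epoch 1
  i <- 0
  testthat::local_mocked_bindings(
    .val_loss = function(...) {
      i <<- i + 1
      vals[i]
    },
    .package = "floracount"
  )
  tr <- tiny_field_samples(4, size = 32L)
  va <- tiny_field_samples(2, size = 32L, offset = 100L)
  cfg <- training_config(batch_size = 4L, max_epochs = 10L,
                         early_stop_patience = 1L, crop_size = 32L,
                         sigma = 3, seed = 1L)
  m <- build_model(model_spec(depth = 2L, base_channels = 2L), seed = 1L,
                   sigma = 3)
  fit <- train_model(m, tr, va, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(fit$stop_reason, "early_stop")
})

test_that("returned weights achieve the minimum recorded validation loss", {
  tr <- tiny_field_samples(6, size = 32L, seed = 3L)
  va <- tiny_field_samples(3, size = 32L, seed = 3L, offset = 100L)
  cfg <- training_config(batch_size = 6L, max_epochs = 6L,
                         early_stop_patience = 6L, crop_size = 32L,
                         sigma = 3, seed = 2L)
  m <- build_model(model_spec(depth = 2L, base_channels = 2L), seed = 2L,
                   sigma = 3)
  fit <- train_model(m, tr, va, cfg)
  kernel <- kernel_config(sigma = 3)
  targets <- lapply(va, function(s) {
    gaussian_density_map(s$points, dim(s$image)[1:2], kernel)
  })
  preds <- floracount:::.predict_set(fit$model, va)
  re_val <- mean(mapply(function(p, t) mean((p - t)^2), preds, targets))
  expect_equal(re_val, min(fit$history$val_mse), tolerance = 1e-10)
  expect_equal(fit$history$val_mse[fit$best_epoch],
               min(fit$history$val_mse))
})

test_that("training is reproducible under a fixed seed", {
  tr <- tiny_field_samples(4, size = 32L, seed = 5L)
  va <- tiny_field_samples(2, size = 32L, seed = 5L, offset = 100L)
  cfg <- training_config(batch_size = 4L, max_epochs = 3L,
                         early_stop_patience = 3L, crop_size = 32L,
                         sigma = 3, seed = 9L)
  fit1 <- train_model(build_model(model_spec(2L, 2L), seed = 9L, sigma = 3),
                      tr, va, cfg)
  fit2 <- train_model(build_model(model_spec(2L, 2L), seed = 9L, sigma = 3),
                      tr, va, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$weights$head$W, fit2$model$weights$head$W)
})

test_that("a short training run beats the all-zero predictor", {
  tr <- tiny_field_samples(20, size = 64L, seed = 8L)
  va <- tiny_field_samples(4, size = 64L, seed = 8L, offset = 100L)
  cfg <- training_config(batch_size = 20L, max_epochs = 30L,
                         early_stop_patience = 30L, crop_size = 64L,
                         sigma = 6, seed = 4L)
  m <- build_model(model_spec(depth = 3L, base_channels = 8L), seed = 4L)
  fit <- train_model(m, tr, va, cfg)
  # oracle: the all-zero predictor's loss is the mean of target^2
  kernel <- kernel_config(sigma = 6)
  zero_loss <- mean(vapply(tr, function(s) {
    mean(gaussian_density_map(s$points, dim(s$image)[1:2], kernel)^2)
  }, 1))
  expect_lt(tail(fit$history$train_mse, 1), zero_loss)
  expect_lt(min(fit$history$val_mse), mean(vapply(va, function(s) {
    mean(gaussian_density_map(s$points, dim(s$image)[1:2], kernel)^2)
  }, 1)))
})

test_that("evaluate_model reproduces its documented arithmetic", {
  # mock predictions with known integrals: actual (100, 50),
  # predicted (90, 55) -> MAE 7.5, MAPD 10%
  sz <- 10L
  eval_set <- list(
    list(id = "a", image = array(0, dim = c(sz, sz, 3)),
         points = cbind(runif(100, 0, sz - 1e-6), runif(100, 0, sz - 1e-6))),
    list(id = "b", image = array(0, dim = c(sz, sz, 3)),
         points = cbind(runif(50, 0, sz - 1e-6), runif(50, 0, sz - 1e-6)))
  )
  fake <- list(a = matrix(90 / sz^2, sz, sz), b = matrix(55 / sz^2, sz, sz))
  testthat::local_mocked_bindings(
    .predict_set = function(model, samples, ...) fake[
      vapply(samples, `[[`, "", "id")],
    .package = "floracount"
  )
  m <- build_model(model_spec(1L, 1L), seed = 1L)
  got <- evaluate_model(m, eval_set)
  expect_equal(got$mae, 7.5)
  expect_equal(got$mapd, mean(c(10 / 100, 5 / 50)) * 100)

  # a perfect predictor on interior-point samples scores ~zero everywhere
  set.seed(12)
  smp <- lapply(1:3, function(i) {
    list(id = paste0("s", i), image = array(0, dim = c(64, 64, 3)),
         points = scatter_points(4 + i, c(64, 64), margin = 26, min_sep = 3))
  })
  kernel <- kernel_config(sigma = 6)
  perfect <- lapply(smp, function(s) {
    gaussian_density_map(s$points, dim(s$image)[1:2], kernel)
  })
  names(perfect) <- vapply(smp, `[[`, "", "id")
  testthat::local_mocked_bindings(
    .predict_set = function(model, samples, ...) perfect[
      vapply(samples, `[[`, "", "id")],
    .package = "floracount"
  )
  got2 <- evaluate_model(m, smp)
  expect_equal(got2$pixel_mse, 0)
  expect_lt(got2$mae, 1e-3)
  expect_lt(got2$mapd, 0.1)
})

test_that("empty-count patches are excluded from MAPD but kept in MAE", {
  sz <- 8L
  eval_set <- list(
    list(id = "zero", image = array(0, dim = c(sz, sz, 3)),
         points = matrix(numeric(0), 0, 2)),
    list(id = "ten", image = array(0, dim = c(sz, sz, 3)),
         points = cbind(runif(10, 0, 7.9), runif(10, 0, 7.9)))
  )
  fake <- list(zero = matrix(2 / sz^2, sz, sz),
               ten = matrix(11 / sz^2, sz, sz))
  testthat::local_mocked_bindings(
    .predict_set = function(model, samples, ...) fake[
      vapply(samples, `[[`, "", "id")],
    .package = "floracount"
  )
  m <- build_model(model_spec(1L, 1L), seed = 1L)
  got <- evaluate_model(m, eval_set)
  expect_equal(got$mae, mean(c(2, 1)))
  expect_equal(got$mapd, 10)
})

test_that("degenerate inputs error early", {
  m <- build_model(model_spec(2L, 2L), seed = 1L)
  cfg <- training_config(crop_size = 32L)
  expect_error(train_model(m, list(), list(), cfg), "non-empty")
  tr <- tiny_field_samples(2, size = 16L)
  expect_error(train_model(m, tr, tr, cfg), "crop_size larger")
})
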