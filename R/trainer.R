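#' Training configuration
#'
#' Defaults follow the density-regression training recipe this package
#' implements: Adam with learning rate 1e-3, beta1 = 0.9, beta2 = 0.99 and
#' weight decay 1e-5; batches of 20 randomly rotated-and-cropped patches;
#' up to 1000 epochs halted by early stopping when validation loss has not
#' improved for 30 consecutive epochs.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty added to weight gradients.
#' @param batch_size patches per optimization step.
#' @param max_epochs hard epoch cap.
#' @param early_stop_patience epochs without validation improvement before
#'   halting.
#' @param sigma Gaussian kernel bandwidth (px) for density targets.
#' @param crop_size augmentation crop side (px); when it equals the patch
#'   size the exact right-angle augmentation policy is used (see
#'   [augment_sample()]).
#' @param seed seed controlling initialization order, shuffling and
#'   augmentation draws; fixed seed makes a training run reproducible.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.99,
                            weight_decay = 1e-5, batch_size = 20L,
                            max_epochs = 1000L, early_stop_patience = 30L,
                            sigma = 6, crop_size = 256L, seed = 1L) {
  if (learning_rate <= 0 || weight_decay < 0) stop("rates must be positive")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("Adam betas must lie in (0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (early_stop_patience < 1) stop("early_stop_patience must be >= 1")
  structure(list(
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    sigma = sigma, crop_size = as.integer(crop_size), seed = as.integer(seed)
  ), class = "training_config")
}

#' Pixel mean squared error between density maps
#'
#' The training loss: the mean over all pixels of the squared difference
#' between predicted and target density.
#'
#' @param predicted,target numeric matrices (or arrays) of identical shape.
#' @return scalar MSE.
#' @export
mse_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)))
    stop("predicted and target shapes differ")
  mean((predicted - target)^2)
}

# predict density maps for a list of samples in evaluation mode, batching
# same-shape patches together
.predict_set <- function(model, samples, batch_size = 20L) {
  ptr <- .model_ptr(model)
  out <- vector("list", length(samples))
  if (length(samples) == 0L) return(out)
  shapes <- vapply(samples, function(s) dim(s$image)[1:2], integer(2L))
  for (grp in split(seq_along(samples),
                    paste(shapes[1, ], shapes[2, ]))) {
    H <- shapes[1, grp[1]]; W <- shapes[2, grp[1]]
    for (chunk in split(grp, ceiling(seq_along(grp) / batch_size))) {
      x <- array(0, dim = c(H, W, 3L, length(chunk)))
      for (j in seq_along(chunk)) {
        x[, , , j] <- normalize_rgb(samples[[chunk[j]]]$image)
      }
      p <- .cpp_unet_forward(ptr, x, FALSE, 0.1, FALSE) / .target_scale(model)
      for (j in seq_along(chunk)) out[[chunk[j]]] <- matrix(p[, , j], H, W)
    }
  }
  names(out) <- vapply(samples, `[[`, "", "id")
  out
}

# targets for a fixed (unaugmented) sample list
.set_targets <- function(samples, kernel) {
  lapply(samples, function(s) {
    gaussian_density_map(s$points, dim(s$image)[1:2], kernel)
  })
}

#' Train the density regressor
#'
#' Minimizes pixel MSE between predicted and target density maps with
#' Adam. Each epoch visits every training patch once with a fresh random
#' augmentation ([augment_sample()]); targets are regenerated from the
#' augmented points each time. Validation patches are evaluated
#' unaugmented after every epoch; the weights with the lowest validation
#' loss are returned, and training halts after `early_stop_patience`
#' epochs without improvement (or at `max_epochs`). Fully reproducible
#' under a fixed `config$seed`.
#'
#' @param model an `fc_unet` from [build_model()] (its weights are the
#'   starting point).
#' @param train_set,val_set sample lists (`list(id, image, points)` per
#'   sample, as from [generate_samples()] or [load_samples()]).
#' @param config a [training_config()].
#' @param quiet suppress per-epoch progress lines.
#' @return list with `model` (best weights), `history` (data.frame
#'   `epoch,train_mse,val_mse`), `best_epoch` and `stop_reason`.
#' @export
train_model <- function(model, train_set, val_set, config = training_config(),
                        quiet = TRUE) {
  stopifnot(inherits(model, "fc_unet"), inherits(config, "training_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("training and validation sets must be non-empty")
  dims <- vapply(train_set, function(s) dim(s$image)[1:2], integer(2L))
  if (any(dims[1, ] < config$crop_size) || any(dims[2, ] < config$crop_size))
    stop("crop_size larger than a training patch")
  kernel <- kernel_config(sigma = config$sigma)
  with_seed(config$seed,
            .train_loop(model, train_set, val_set, config, kernel, quiet))
}

.train_loop <- function(model, train_set, val_set, config, kernel, quiet) {
  ptr <- .model_ptr(model, fresh = TRUE)
  kappa <- .target_scale(model)
  cs <- config$crop_size
  val_targets <- .set_targets(val_set, kernel)
  best_val <- Inf
  best_weights <- NULL
  best_epoch <- 0L
  bad <- 0L
  stop_reason <- "max_epochs"
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train_set))
    tot <- 0; seen <- 0L
    for (chunk in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      B <- length(chunk)
      x <- array(0, dim = c(cs, cs, 3L, B))
      tg <- array(0, dim = c(cs, cs, B))
      for (j in seq_len(B)) {
        s <- train_set[[chunk[j]]]
        aug <- augment_sample(normalize_rgb(s$image), s$points, cs)
        x[, , , j] <- aug$image
        tg[, , j] <- kappa *
          gaussian_density_map(aug$points, c(cs, cs), kernel)
      }
      p <- .cpp_unet_forward(ptr, x, TRUE, 0.1, TRUE)
      loss <- mean((p - tg)^2)
      if (!is.finite(loss)) {
        stop(sprintf(
          "non-finite training loss at epoch %d (lr too high or degenerate input)",
          epoch))
      }
      .cpp_unet_zero_grad(ptr)
      .cpp_unet_backward(ptr, 2 * (p - tg) / length(tg))
      .cpp_unet_step(ptr, config$learning_rate, config$beta1, config$beta2,
                     1e-8, config$weight_decay)
      tot <- tot + loss * B
      seen <- seen + B
    }
    train_mse <- tot / seen / kappa^2   # report in raw density units
    model$weights <- .cpp_unet_get_weights(ptr)
    val_mse <- .val_loss(model, val_set, val_targets, config$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                val_mse = val_mse)
    if (!quiet) {
      message(sprintf("epoch %3d  train %.3e  val %.3e", epoch, train_mse,
                      val_mse))
    }
    if (val_mse < best_val) {
      best_val <- val_mse
      best_weights <- model$weights
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$early_stop_patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  model$weights <- best_weights
  model$config$sigma <- config$sigma
  model$env$ptr <- NULL
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
       best_epoch = best_epoch, stop_reason = stop_reason)
}

.val_loss <- function(model, val_set, val_targets, batch_size) {
  preds <- .predict_set(model, val_set, batch_size)
  losses <- mapply(function(p, t) mean((p - t)^2), preds, val_targets)
  npix <- vapply(val_targets, length, 1L)
  sum(losses * npix) / sum(npix)
}

#' Evaluate counting performance
#'
#' Predicts a density map per patch (inference mode, no augmentation),
#' integrates it for the predicted count, and compares with the annotated
#' count. MAE is the mean absolute count error over all patches; MAPD is
#' the mean of `|predicted - actual| / actual * 100` over patches with at
#' least one annotated object (the percent deviation is undefined at
#' zero, so empty patches contribute to MAE only). Pixel MSE is computed
#' against density targets built with the model's training `sigma`.
#'
#' @param model a trained `fc_unet`.
#' @param eval_set sample list with annotations.
#' @param batch_size forward-pass batch size.
#' @return list of class `count_metrics`: `mae`, `mapd`, `pixel_mse`, and
#'   `per_patch` (data.frame `id,actual,predicted`).
#' @export
evaluate_model <- function(model, eval_set, batch_size = 20L) {
  if (length(eval_set) == 0L) stop("eval_set is empty")
  kernel <- kernel_config(sigma = model$config$sigma)
  preds <- .predict_set(model, eval_set, batch_size)
  targets <- .set_targets(eval_set, kernel)
  actual <- vapply(eval_set, function(s) nrow(s$points), 1L)
  predicted <- vapply(preds, integrate_count, 1)
  npix <- vapply(targets, length, 1L)
  pixel_mse <- sum(mapply(function(p, t) mean((p - t)^2), preds, targets) *
                     npix) / sum(npix)
  err <- abs(predicted - actual)
  mapd <- if (any(actual > 0)) {
    mean(err[actual > 0] / actual[actual > 0]) * 100
  } else {
    NA_real_
  }
  structure(list(
    mae = mean(err), mapd = mapd, pixel_mse = pixel_mse,
    per_patch = data.frame(id = vapply(eval_set, `[[`, "", "id"),
                           actual = actual, predicted = predicted)
  ), class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("<count_metrics> MAE %.2f | MAPD %s | pixel MSE %.3e | n = %d\n",
              x$mae,
              if (is.na(x$mapd)) "NA" else sprintf("%.2f%%", x$mapd),
              x$pixel_mse, nrow(x$per_patch)))
  invisible(x)
}
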