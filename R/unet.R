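#' Model architecture specification
#'
#' Describes the encoder-decoder density regressor: a U-net style fully
#' convolutional network taking a 3-channel RGB patch and producing a single
#' nonnegative density channel of the same spatial size. Each encoder stage
#' is two (3x3 conv, batch norm, ReLU) blocks followed by 2x2 stride-2 max
#' pooling; the decoder mirrors it with 2x2 transposed-convolution
#' upsampling and skip concatenation; the head is a 1x1 convolution with a
#' final ReLU so densities are nonnegative by construction.
#'
#' @param depth number of pooling stages (input sides must be divisible by
#'   `2^depth`).
#' @param base_channels channel width of the first encoder stage; widths
#'   double at each deeper stage.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(depth = 4L, base_channels = 64L) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  stopifnot(length(depth) == 1L, length(base_channels) == 1L)
  if (is.na(depth) || depth < 1L) stop("depth must be >= 1")
  if (is.na(base_channels) || base_channels < 1L)
    stop("base_channels must be >= 1")
  structure(
    list(depth = depth, base_channels = base_channels,
         input_channels = 3L, output_channels = 1L),
    class = "model_spec"
  )
}

# channel plan mirroring the C++ layer layout: blocks 0..(4*depth+1) in
# forward order (encoder, bottleneck, decoder), ups indexed by the encoder
# stage they decode back to
.unet_layout <- function(spec) {
  d <- spec$depth
  b <- spec$base_channels
  blocks <- vector("list", 4L * d + 2L)
  ci <- 3L
  for (s in seq_len(d)) {
    co <- b * 2L^(s - 1L)
    blocks[[2L * s - 1L]] <- c(cin = ci, cout = co)
    blocks[[2L * s]] <- c(cin = co, cout = co)
    ci <- co
  }
  cb <- b * 2L^d
  blocks[[2L * d + 1L]] <- c(cin = ci, cout = cb)
  blocks[[2L * d + 2L]] <- c(cin = cb, cout = cb)
  ups <- vector("list", d)
  for (s in (d - 1L):0L) {
    co <- b * 2L^s
    ups[[s + 1L]] <- c(cin = 2L * co, cout = co)
    bi <- 2L * d + 2L + 2L * (d - 1L - s) + 1L
    blocks[[bi]] <- c(cin = 2L * co, cout = co)
    blocks[[bi + 1L]] <- c(cin = co, cout = co)
  }
  list(blocks = blocks, ups = ups, head_cin = b)
}

.init_weights <- function(spec) {
  lay <- .unet_layout(spec)
  w <- list()
  for (i in seq_along(lay$blocks)) {
    cin <- lay$blocks[[i]][["cin"]]
    cout <- lay$blocks[[i]][["cout"]]
    fan_in <- 9 * cin
    w[[paste0("block", i - 1L)]] <- list(
      W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
      gamma = matrix(1, cout, 1L),
      beta = matrix(0, cout, 1L),
      run_mean = numeric(cout),
      run_var = rep(1, cout)
    )
  }
  for (s in seq_along(lay$ups)) {
    cin <- lay$ups[[s]][["cin"]]
    cout <- lay$ups[[s]][["cout"]]
    fan_in <- 4 * cin
    w[[paste0("up", s - 1L)]] <- list(
      W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
      b = matrix(0, cout, 1L)
    )
  }
  # density targets live at the 1e-3 scale while unit-gain features are O(1);
  # a downscaled head makes the network start near the all-zero predictor so
  # training spends its epochs shaping the density, not shrinking the output.
  # the small positive bias keeps the final ReLU from starting saturated at
  # zero (an all-zero output has zero gradient everywhere).
  w[["head"]] <- list(
    W = matrix(rnorm(lay$head_cin, sd = 0.02 * sqrt(2 / lay$head_cin)),
               1L, lay$head_cin),
    b = matrix(1e-3, 1L, 1L)
  )
  w[["adam_t"]] <- 0L
  w
}

#' Build a density regression model
#'
#' Instantiates the network described by a [model_spec()] with seeded
#' He-normal weight initialization. The returned model carries its weights
#' in plain R matrices (the checkpoint currency) plus a handle to a native
#' compute state that is rebuilt on demand, so models can be saved, loaded
#' and copied like ordinary R objects.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @param sigma Gaussian kernel bandwidth (pixels) the model is trained
#'   against; recorded so inference consumers know the target convention.
#' @return an object of class `fc_unet`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L, sigma = 6) {
  stopifnot(inherits(spec, "model_spec"))
  weights <- with_seed(seed, .init_weights(spec))
  model <- list(
    spec = spec,
    weights = weights,
    config = list(normalization = "rgb01", sigma = sigma,
                  gamma = 0.05, delta = 4, target_scale = 100),
    env = new.env(parent = emptyenv())
  )
  model$env$ptr <- NULL
  class(model) <- "fc_unet"
  model
}

# materialize (or refresh) the native network from the stored weights
.model_ptr <- function(model, fresh = FALSE) {
  env <- model$env
  if (fresh || is.null(env$ptr)) {
    env$ptr <- .cpp_unet_create(model$spec$depth, model$spec$base_channels)
    .cpp_unet_set_weights(env$ptr, model$weights)
  }
  env$ptr
}

# pull weights (incl. batch-norm running stats and Adam step) out of the
# native state back into the R model
.model_sync <- function(model) {
  if (!is.null(model$env$ptr)) {
    model$weights <- .cpp_unet_get_weights(model$env$ptr)
  }
  model
}

#' @export
print.fc_unet <- function(x, ...) {
  np <- sum(vapply(x$weights, function(b) {
    if (is.list(b)) sum(vapply(b, length, 1L)) else 0L
  }, 1))
  cat(sprintf(
    "<fc_unet> depth=%d base_channels=%d (%s parameters), sigma=%g\n",
    x$spec$depth, x$spec$base_channels, format(np, big.mark = ","),
    x$config$sigma))
  invisible(x)
}

#' Predict a density map for one RGB patch
#'
#' Runs the network in inference mode (batch-norm uses running statistics).
#' The network is fully convolutional: any patch whose sides are divisible
#' by `2^depth` is accepted, and the output has the input's spatial shape.
#'
#' @param model an `fc_unet` from [build_model()] or [train_model()].
#' @param patch an H x W x 3 numeric array with values in \[0, 1\] (the
#'   training normalization), or an H x W x 3 integer array in \[0, 255\]
#'   which is rescaled.
#' @return an H x W numeric matrix of predicted density (nonnegative).
#' @export
predict_density <- function(model, patch) {
  stopifnot(inherits(model, "fc_unet"))
  patch <- normalize_rgb(patch)
  dm <- dim(patch)
  div <- 2L^model$spec$depth
  if (dm[1] %% div != 0L || dm[2] %% div != 0L) {
    stop(sprintf(
      "patch sides must be divisible by 2^depth = %d (got %d x %d)",
      div, dm[1], dm[2]))
  }
  x <- array(patch, dim = c(dm[1], dm[2], 3L, 1L))
  out <- .cpp_unet_forward(.model_ptr(model), x, FALSE, 0.1, FALSE)
  matrix(out, dm[1], dm[2]) / .target_scale(model)
}

# the network regresses density multiplied by this factor: raw densities
# live at the 1e-3 scale, which sits badly with unit-gain batch-norm
# features and Adam's fixed step size (one step can cross the whole target
# range and strand the final ReLU in its dead zone). Training on scaled
# targets and dividing at inference is loss-equivalent and leaves every
# user-facing quantity in true density units.
.target_scale <- function(model) {
  s <- model$config$target_scale
  if (is.null(s)) 1 else s
}

# batched forward used by the trainer; x is (H, W, 3, B)
.predict_batch <- function(ptr, x, training, keep) {
  .cpp_unet_forward(ptr, x, training, 0.1, keep)
}

#' Normalize an RGB image array to \[0, 1\]
#'
#' @param img H x W x 3 numeric array, either already in \[0, 1\] or 8-bit
#'   values in \[0, 255\].
#' @return numeric array in \[0, 1\].
#' @export
normalize_rgb <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected an H x W x 3 image array")
  if (max(img) > 1 + 1e-9) img <- img / 255
  img
}

#' Save / load a trained model
#'
#' The checkpoint is the package's native serialized weight list plus a
#' JSON sidecar recording the architecture and the training-time
#' conventions (input normalization, kernel sigma, peak gamma/delta), so a
#' checkpoint is interpretable without loading it.
#'
#' @param model an `fc_unet`.
#' @param path checkpoint path (an `.rds` file); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `fc_unet`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fc_unet"))
  model <- .model_sync(model)
  saveRDS(list(spec = unclass(model$spec), weights = model$weights,
               config = model$config), path)
  sidecar <- list(
    class = "fc_unet",
    spec = unclass(model$spec),
    config = model$config
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  spec <- do.call(model_spec, obj$spec[c("depth", "base_channels")])
  model <- build_model(spec, seed = 0L)
  model$weights <- obj$weights
  model$config <- obj$config
  model$env$ptr <- NULL
  model
}
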