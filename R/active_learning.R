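#' Rank samples for annotation by CountDiff
#'
#' For each unlabeled sample the integrated count \eqn{\hat T_c} and the
#' discrete peak count \eqn{\hat T_d} are computed from its predicted
#' density map, and `CountDiff` \eqn{= \hat T_c - \hat T_d} measures how
#' much predicted mass failed to resolve into clean peaks - the samples
#' the current model understands worst. Samples are returned in
#' descending CountDiff order (ties: ascending `sample_id`), ready for
#' top-k selection.
#'
#' @param pool_predictions named list of predicted density matrices
#'   (names are sample ids) in raw density units, e.g. from
#'   [predict_density()] over a pool of patches.
#' @param config a [peak_config()].
#' @param density_scale scale on which `config$gamma` is defined (see
#'   [peak_count_deficit()]); `t_c` is always computed from the raw map.
#' @return data.frame `sample_id, t_c, t_d, count_diff`, ordered.
#' @export
rank_samples <- function(pool_predictions, config = peak_config(),
                         density_scale = 1) {
  if (length(pool_predictions) == 0L) stop("empty prediction pool")
  ids <- names(pool_predictions)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("pool_predictions must be a named list (names = sample ids)")
  rec <- lapply(ids, function(id) {
    pc <- peak_count_deficit(pool_predictions[[id]], config, density_scale,
                             warn = FALSE)
    data.frame(sample_id = id, t_c = pc$t_c, t_d = pc$t_d,
               count_diff = pc$t_c - pc$t_d, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rec)
  df <- df[order(-df$count_diff, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Ingest oracle-corrected annotations into a dataset
#'
#' File-level half of the annotation loop: for each corrected sample the
#' corrected points are written in the annotation CSV dialect, a density
#' target is regenerated with the same Gaussian kernel used for the
#' original training data, and the sample is appended to the *training*
#' split of the manifest with provenance columns (`round`, `source =
#' "oracle"`). The validation and test splits are never touched; a
#' corrected sample whose id already belongs to either is a split
#' contamination error.
#'
#' @param corrections named list of [point_set()]s (names = sample ids).
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param dir dataset root; annotation CSVs go to `annotations/`, density
#'   targets to `targets/`, and images are expected at `images/<id>.png`.
#' @param kernel [kernel_config()] used to regenerate targets.
#' @param round active-learning round recorded in the provenance column.
#' @return the updated manifest data.frame (also rewritten to
#'   `dir/manifest.csv` when it exists there).
#' @export
ingest_corrections <- function(corrections, manifest, dir,
                               kernel = kernel_config(), round = 1L) {
  stopifnot(is.data.frame(manifest))
  ids <- names(corrections)
  held <- manifest$image_id[manifest$split %in% c("val", "test")]
  clash <- intersect(ids, held)
  if (length(clash) > 0L) {
    stop("split contamination: corrected sample(s) in val/test: ",
         paste(clash, collapse = ", "))
  }
  if (!"round" %in% names(manifest)) manifest$round <- NA_integer_
  if (!"source" %in% names(manifest)) manifest$source <- NA_character_
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "targets"), showWarnings = FALSE)
  for (id in ids) {
    ps <- corrections[[id]]
    stopifnot(inherits(ps, "point_set"))
    ann_path <- file.path("annotations", paste0(id, ".csv"))
    write_annotations(ps, file.path(dir, ann_path))
    img_path <- file.path("images", paste0(id, ".png"))
    shape <- dim(read_png(file.path(dir, img_path)))[1:2]
    target <- gaussian_density_map(ps, shape, kernel)
    write_density_tiff(target, file.path(dir, "targets",
                                         paste0(id, ".tif")))
    manifest <- rbind(manifest, data.frame(
      image_id = id, split = "train", path = img_path,
      annotation_path = ann_path, round = as.integer(round),
      source = "oracle", stringsAsFactors = FALSE))
  }
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) write_manifest(manifest, mpath)
  manifest
}

#' Incremental data-quantity experiment
#'
#' Emulates the active-learning loop at dataset scale: train on an initial
#' random subset of the pool, then repeatedly (1) run inference on the
#' not-yet-selected pool, (2) rank it by CountDiff, (3) add the top
#' samples up to the next level, and (4) retrain from fresh initialization,
#' recording validation and test metrics per round. Test data is used only
#' to record performance, never for selection.
#'
#' @param pool full labeled training pool (sample list); labels are used
#'   only once a sample has been selected, emulating the oracle.
#' @param val_set,test_set fixed validation / held-out test sample lists.
#' @param levels strictly increasing training-set sizes, e.g.
#'   `c(50, 100, 250, 500, 650)`; the last level may equal the pool size.
#' @param spec [model_spec()] for each round's fresh model.
#' @param config [training_config()]; `config$seed` drives the initial
#'   subset draw and each round's training.
#' @param peak_cfg [peak_config()] for CountDiff.
#' @param strategy `"countdiff"` (active) or `"random"` (passive baseline).
#' @param quiet suppress progress output.
#' @return list with `ledger` (data.frame `round, training_size, val_mse,
#'   test_mae, test_mse`), `selections` (ids added per round),
#'   `priorities` (the per-round ranking tables, for audit),
#'   `round_models` (each round's trained model, so selections can be
#'   re-derived) and `model` (the final round's model).
#' @export
incremental_experiment <- function(pool, val_set, test_set, levels,
                                   spec = model_spec(depth = 3L,
                                                     base_channels = 8L),
                                   config = training_config(),
                                   peak_cfg = peak_config(),
                                   strategy = c("countdiff", "random"),
                                   quiet = TRUE) {
  strategy <- match.arg(strategy)
  levels <- as.integer(levels)
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (max(levels) > length(pool))
    stop(sprintf("level %d exceeds pool size %d", max(levels), length(pool)))
  pool_ids <- vapply(pool, `[[`, "", "id")
  if (anyDuplicated(pool_ids)) stop("duplicate sample ids in pool")

  selected <- with_seed(config$seed,
                        sample(pool_ids, levels[1]))
  selections <- list(selected)
  priorities <- list(NULL)
  round_models <- vector("list", length(levels))
  ledger <- vector("list", length(levels))
  model <- NULL
  for (r in seq_along(levels)) {
    if (r > 1L) {
      remaining <- setdiff(pool_ids, selected)
      k <- levels[r] - levels[r - 1L]
      if (strategy == "countdiff") {
        preds <- .predict_set(model, pool[match(remaining, pool_ids)],
                              config$batch_size)
        pr <- rank_samples(preds, peak_cfg, .target_scale(model))
        add <- pr$sample_id[seq_len(k)]
        priorities[[r]] <- pr
      } else {
        add <- with_seed(config$seed + r, sample(remaining, k))
        priorities[[r]] <- NULL
      }
      selections[[r]] <- add
      selected <- c(selected, add)
    }
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    fresh <- build_model(spec, seed = cfg$seed, sigma = config$sigma)
    fit <- train_model(fresh, pool[match(selected, pool_ids)], val_set, cfg,
                       quiet = quiet)
    model <- fit$model
    round_models[[r]] <- model
    test_metrics <- evaluate_model(model, test_set, config$batch_size)
    ledger[[r]] <- data.frame(
      round = r, training_size = length(selected),
      val_mse = min(fit$history$val_mse),
      test_mae = test_metrics$mae, test_mse = test_metrics$pixel_mse)
    if (!quiet) {
      message(sprintf("round %d (n=%d): val %.3e, test MAE %.2f", r,
                      length(selected), min(fit$history$val_mse),
                      test_metrics$mae))
    }
  }
  list(ledger = do.call(rbind, ledger), selections = selections,
       priorities = priorities, round_models = round_models, model = model)
}
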