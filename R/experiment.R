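#' Run the full leave-one-subject-out experiment
#'
#' Orchestrates the whole pipeline on a set of labeled circuits: channel
#' subsetting, transition removal, five-pass windowing, feature extraction,
#' three-window context stacking, then per fold - class balancing and
#' scaler fitting on the training split only, network training, and
#' evaluation of all three splits. Nothing from the held-out subject
#' touches the scaler, the balancing draw or the weights.
#'
#' @param circuits Circuit tibble ([read_circuits()] / [generate_dataset()]).
#' @param seg_cfg A [segmentation_config()].
#' @param ann_cfg An [ann_config()].
#' @param channels Channel subset (see [gait_channels()]).
#' @param val_per_subject,test_per_subject,train_cap Fold construction, see
#'   [make_loso_folds()].
#' @param n_per_class Optional per-class cap on training rows after
#'   balancing (see [balance_classes()]); `NULL` keeps the rarest-class
#'   count.
#' @param balance_all Balance validation/test splits too (default `FALSE`:
#'   evaluation splits stay unbalanced so their metrics reflect the raw
#'   label distribution).
#' @param median_mode Feature median convention, see [extract_features()].
#' @param seed Master seed; per-fold seeds for balancing and weight
#'   initialisation are derived from it.
#' @param folds Optional subset of fold numbers to run (default: all).
#' @param verbose Print per-fold progress.
#' @return A `gait_eval` object; see [tidy.gait_eval()], [glance.gait_eval()]
#'   and [autoplot.gait_eval()]. Components: `metrics` (per fold x split
#'   accuracy and macro F1), `f1` (per fold x split x class), `confusion`
#'   (nested list of matrices), `folds` (the fold table), `timing`, and the
#'   fitted models' traces.
#' @export
run_experiment <- function(circuits,
                           seg_cfg = segmentation_config(),
                           ann_cfg = ann_config(),
                           channels = "all",
                           val_per_subject = 2L, test_per_subject = 4L,
                           train_cap = 8L,
                           n_per_class = NULL, balance_all = FALSE,
                           median_mode = "sorted",
                           seed = 1L, folds = NULL, verbose = FALSE) {
  chans <- channel_names(channels)
  keep <- c("subject_id", "circuit_id", "sample_idx", chans, "label")
  circuits <- circuits[, keep]

  t0 <- proc.time()[["elapsed"]]
  feats <- build_feature_table(circuits, seg_cfg, median_mode)
  stacked <- stack_context(feats, seg_cfg$context)
  rm(feats)
  gc(FALSE)
  pre_elapsed <- proc.time()[["elapsed"]] - t0
  n_rows <- nrow(stacked)

  fold_tbl <- make_loso_folds(circuits, val_per_subject, test_per_subject,
                              train_cap, seed)
  run_folds <- if (is.null(folds)) unique(fold_tbl$fold) else folds
  row_key <- paste(stacked$subject_id, stacked$circuit_id, sep = "\r")

  metrics <- list(); f1s <- list(); confs <- list(); traces <- list()
  inf_times <- numeric()
  for (f in run_folds) {
    ft <- fold_tbl[fold_tbl$fold == f, ]
    idx <- function(split) {
      sel <- ft[ft$split == split, ]
      which(row_key %in% paste(sel$subject_id, sel$circuit_id, sep = "\r"))
    }
    train_idx <- idx("train")
    train <- stacked[train_idx[balance_indices(
      stacked$activity[train_idx], seed = seed + 1000L * f, n_per_class)], ]
    cfg_f <- ann_cfg
    cfg_f$seed <- ann_cfg$seed + f
    fit <- gait_ann(train, cfg_f)
    traces[[as.character(f)]] <- fit$trace

    confs[[as.character(f)]] <- list()
    for (split in c("train", "val", "test")) {
      if (split == "train") {
        rows <- NULL
        truth <- train$activity
      } else {
        rows <- idx(split)
        if (balance_all) {
          rows <- rows[balance_indices(stacked$activity[rows],
                                       seed = seed + 1000L * f +
                                         match(split, c("val", "test")))]
        }
        truth <- stacked$activity[rows]
      }
      t1 <- proc.time()[["elapsed"]]
      pred <- if (is.null(rows)) {
        predict(fit, train)
      } else {
        predict_rows(fit, stacked$features, rows)
      }
      dt <- proc.time()[["elapsed"]] - t1
      if (split == "test") inf_times <- c(inf_times, dt / length(pred))
      cm <- confusion_matrix(truth, pred)
      confs[[as.character(f)]][[split]] <- cm
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        fold = f, split = split, n = length(pred),
        accuracy = accuracy(cm), macro_f1 = macro_f1(cm))
      fc <- f1_per_class(cm)
      fc$fold <- f; fc$split <- split
      f1s[[length(f1s) + 1L]] <- fc
      rm(pred, truth)
    }
    gc(FALSE)
    if (verbose) {
      m <- dplyr::bind_rows(utils::tail(metrics, 3))
      message(sprintf("fold %d: train %.3f / val %.3f / test %.3f",
                      f, m$accuracy[m$split == "train"],
                      m$accuracy[m$split == "val"],
                      m$accuracy[m$split == "test"]))
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  timing <- tibble::tibble(
    stage = c("preprocess", "inference"),
    mean_us_per_row = c(pre_elapsed / n_rows, mean(inf_times)) * 1e6,
    sd_us_per_row = c(NA_real_,
                      if (length(inf_times) > 1) stats::sd(inf_times) * 1e6 else 0),
    n_rows = c(n_rows, NA_integer_))
  structure(list(metrics = metrics, f1 = dplyr::bind_rows(f1s),
                 confusion = confs, folds = fold_tbl, timing = timing,
                 traces = traces, channels = channels, seed = seed,
                 seg_cfg = seg_cfg, ann_cfg = ann_cfg,
                 n_stacked_rows = n_rows),
            class = "gait_eval")
}

# chunked prediction straight off the shared feature matrix: large
# evaluation splits are never materialised as whole-split copies
predict_rows <- function(fit, X, rows, chunk = 20000L) {
  out <- integer(length(rows))
  for (s in seq(1L, length(rows), by = chunk)) {
    e <- min(s + chunk - 1L, length(rows))
    Xc <- scale_mat(X[rows[s:e], , drop = FALSE], fit$scaler)
    out[s:e] <- max.col(ann_forward(fit$params, Xc), ties.method = "first")
  }
  factor(fit$levels[out], levels = fit$levels)
}

#' @export
print.gait_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<gait_eval> %d folds, channels = %s\n  mean accuracy: train %.4f / val %.4f / test %.4f\n",
    g$n_folds, x$channels, g$mean_train_accuracy, g$mean_val_accuracy,
    g$mean_test_accuracy))
  invisible(x)
}

#' Per-row pipeline timing
#'
#' Measures wall-clock preprocessing (windowing + feature extraction +
#' stacking, per produced row, timed per circuit) and single-row inference
#' (scaling + forward pass, timed row by row) for a fitted model. Timings
#' are informational; they depend entirely on the host.
#'
#' @param object A fitted `gait_ann`.
#' @param circuits Circuits to preprocess and classify.
#' @param seg_cfg A [segmentation_config()].
#' @param n_rows Number of single-row inference timings (default 1000).
#' @return A tibble: `stage`, `mean_us_per_row`, `sd_us_per_row`, `n`.
#' @export
time_pipeline <- function(object, circuits, seg_cfg = segmentation_config(),
                          n_rows = 1000L) {
  pre <- numeric()
  rows <- list()
  for (grp in split_circuits(circuits)) {
    t0 <- proc.time()[["elapsed"]]
    st <- stack_context(build_feature_table(grp, seg_cfg), seg_cfg$context)
    dt <- proc.time()[["elapsed"]] - t0
    if (nrow(st) > 0) {
      pre <- c(pre, dt / nrow(st) * 1e6)
      rows[[length(rows) + 1L]] <- st
    }
  }
  st <- dplyr::bind_rows(rows)
  n <- min(n_rows, nrow(st))
  X <- design_matrix(st)[seq_len(n), , drop = FALSE]
  inf <- vapply(seq_len(n), function(i) {
    xi <- X[i, , drop = FALSE]
    t0 <- Sys.time()
    ann_forward(object$params, scale_mat(xi, object$scaler))
    as.numeric(Sys.time() - t0) * 1e6
  }, numeric(1))
  tibble::tibble(
    stage = c("preprocess", "inference"),
    mean_us_per_row = c(mean(pre), mean(inf)),
    sd_us_per_row = c(if (length(pre) > 1) stats::sd(pre) else 0,
                      if (length(inf) > 1) stats::sd(inf) else 0),
    n = c(length(pre), n))
}
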