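#' Stack consecutive windows into temporal-context rows
#'
#' Concatenates the feature vectors of k consecutive windows (default 3)
#' into one classifier input, the temporal analogue of shifting the feature
#' table one window down per copy and binding the copies column-wise. Rows
#' are consecutive only within one (circuit, run, pass) group, so the
#' constituents are one window length apart in time and share a single
#' activity; the first k - 1 windows of every group produce no output. The
#' stacked row takes the label and provenance of its latest window.
#'
#' @param features Feature table from [build_feature_table()].
#' @param k Context depth (number of windows; default from the table's
#'   segmentation, usually 3).
#' @return A tibble shaped like the input, whose `features` matrix column
#'   has `k * ncol` columns: the oldest window's block first (column prefix
#'   `lag2.` for k = 3), the current window's block (`lag0.`) last.
#' @export
stack_context <- function(features, k = 3L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  key <- paste(features$subject_id, features$circuit_id, features$run_id,
               features$pass, sep = "\r")
  r <- rle(key)
  pos <- sequence(r$lengths)          # position within contiguous group
  sel <- which(pos >= k)
  X <- features$features
  p <- ncol(X)
  # fill one preallocated matrix per lag block (large inputs: avoid holding
  # k extra full-width copies at once)
  Xs <- matrix(NA_real_, length(sel), k * p)
  nm <- character(k * p)
  for (j in seq_len(k)) {
    lag <- k - j
    cols <- (j - 1L) * p + seq_len(p)
    Xs[, cols] <- X[sel - lag, , drop = FALSE]
    nm[cols] <- paste0("lag", lag, ".", colnames(X))
  }
  colnames(Xs) <- nm
  out <- features[sel, setdiff(names(features), "features")]
  out$features <- Xs
  out
}

#' Column-wise standardisation fitted on training rows
#'
#' `fit_scaler()` computes per-column mean and scale (population standard
#' deviation) on the training design matrix; `apply_scaler()` centres and
#' scales any matrix with those statistics. Zero-variance columns get scale
#' 1, so they pass through centred only. The scaler must be fitted on
#' training rows alone and reused unchanged on validation/test rows.
#'
#' @param x A numeric matrix, or a stacked/feature tibble with a `features`
#'   matrix column.
#' @return `fit_scaler()`: a `gait_scaler` (list with `mean` and `scale`);
#'   `apply_scaler()`: `x` with standardised values (same type as input).
#' @export
fit_scaler <- function(x) {
  X <- design_matrix(x)
  if (nrow(X) == 0) {
    rlang::abort("cannot fit a scaler on zero rows",
                 class = "gaitrec_config_error")
  }
  m <- colMeans(X)
  v <- colMeans(X * X) - m * m
  v[v < 0] <- 0  # numerical guard
  s <- sqrt(v)
  s[s < 1e-12] <- 1
  structure(list(mean = m, scale = s), class = "gait_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `gait_scaler` from `fit_scaler()`.
#' @export
apply_scaler <- function(x, scaler) {
  X <- design_matrix(x)
  if (ncol(X) != length(scaler$mean)) {
    rlang::abort(sprintf("scaler was fitted on %d columns, data has %d",
                         length(scaler$mean), ncol(X)),
                 class = "gaitrec_shape_error")
  }
  Xs <- scale_mat(X, scaler)
  if (is.matrix(x)) return(Xs)
  x$features <- Xs
  x
}

scale_mat <- function(X, scaler) {
  Xs <- sweep(X, 2, scaler$mean, "-")
  sweep(Xs, 2, scaler$scale, "/")
}

design_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && "features" %in% names(x)) return(x$features)
  rlang::abort("expected a matrix or a tibble with a `features` column",
               class = "gaitrec_shape_error")
}

#' Balance classes by downsampling
#'
#' Reduces every activity to the size of the rarest one by uniform random
#' sampling without replacement; gait windows are highly repetitive, so the
#' discarded majority-class rows are largely redundant. Relative row order
#' is preserved among survivors. An optional per-class cap downsamples
#' further, trading training-set size for speed.
#'
#' Balancing belongs on the training split only (evaluation splits stay
#' unbalanced so reported accuracy reflects the raw label distribution);
#' [run_experiment()] has a `balance_all` switch to balance every split
#' instead.
#'
#' @param stacked Stacked tibble from [stack_context()] (any tibble with an
#'   `activity` factor column works).
#' @param seed Integer seed for the sampling.
#' @param n_per_class Optional cap; the per-class count becomes
#'   `min(rarest class, n_per_class)`.
#' @return The downsampled tibble.
#' @export
balance_classes <- function(stacked, seed = 1L, n_per_class = NULL) {
  stacked[balance_indices(stacked$activity, seed, n_per_class), ]
}

# row positions kept by the balancing draw; shared by balance_classes and
# run_experiment (which balances by index to avoid copying large splits)
balance_indices <- function(y, seed = 1L, n_per_class = NULL) {
  counts <- table(y)  # over all 7 levels
  if (any(counts == 0)) {
    rlang::abort(sprintf("cannot balance: class(es) with zero rows: %s",
                         paste(names(counts)[counts == 0], collapse = ", ")),
                 class = "gaitrec_config_error")
  }
  target <- min(counts)
  if (!is.null(n_per_class)) target <- min(target, as.integer(n_per_class))
  withr::with_seed(seed, {
    idx <- lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      if (length(rows) > target) sort(sample(rows, target)) else rows
    })
    sort(unlist(idx))
  })
}
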