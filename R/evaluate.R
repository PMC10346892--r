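#' Leave-one-subject-out fold construction
#'
#' Builds one fold per subject: that subject's circuits are the (unseen)
#' test set; every other ("seen") subject contributes `val_per_subject`
#' randomly drawn circuits to validation and up to `train_cap` of the rest
#' to training. With the default 8 subjects x 10 circuits this yields the
#' benchmark 56 train / 14 validation / 4 test circuits per fold.
#'
#' @param circuits Circuit tibble (only `subject_id` / `circuit_id` are
#'   used, so a stacked or feature tibble works too).
#' @param val_per_subject Validation circuits per seen subject (default 2).
#' @param test_per_subject Test circuits drawn from the held-out subject
#'   (default 4).
#' @param train_cap Maximum training circuits per seen subject (default 8).
#' @param seed Seed for the circuit draws.
#' @return A tibble: `fold`, `test_subject`, `split` (`"train"`, `"val"`,
#'   `"test"`), `subject_id`, `circuit_id`.
#' @export
make_loso_folds <- function(circuits, val_per_subject = 2L,
                            test_per_subject = 4L, train_cap = 8L,
                            seed = 1L) {
  tab <- dplyr::distinct(circuits[, c("subject_id", "circuit_id")])
  subjects <- sort(unique(tab$subject_id))
  if (length(subjects) < 2) {
    rlang::abort("leave-one-subject-out needs at least 2 subjects",
                 class = "gaitrec_config_error")
  }
  by_subj <- split(tab$circuit_id, tab$subject_id)
  for (s in subjects) {
    if (length(by_subj[[s]]) < max(val_per_subject + 1L, test_per_subject)) {
      rlang::abort(sprintf(
        "subject %s has %d circuits; needs >= %d for validation draw and >= %d for testing",
        s, length(by_subj[[s]]), val_per_subject + 1L, test_per_subject),
        class = "gaitrec_config_error")
    }
  }
  withr::with_seed(seed, {
    purrr::imap_dfr(subjects, function(ts, fold) {
      rows <- list()
      for (s in subjects) {
        ids <- sort(by_subj[[s]])
        if (s == ts) {
          test <- sort(sample(ids, test_per_subject))
          rows[[s]] <- tibble::tibble(split = "test", subject_id = s,
                                      circuit_id = test)
        } else {
          val <- sort(sample(ids, val_per_subject))
          rest <- setdiff(ids, val)
          train <- if (length(rest) > train_cap) {
            sort(sample(rest, train_cap))
          } else rest
          rows[[s]] <- dplyr::bind_rows(
            tibble::tibble(split = "train", subject_id = s, circuit_id = train),
            tibble::tibble(split = "val", subject_id = s, circuit_id = val))
        }
      }
      out <- dplyr::bind_rows(rows)
      out$fold <- fold
      out$test_subject <- ts
      out[, c("fold", "test_subject", "split", "subject_id", "circuit_id")]
    })
  })
}

#' Confusion matrix over the seven activities
#'
#' @param truth,estimate Activity labels (factors or names/codes), equal
#'   length.
#' @param levels Class levels fixing row/column order.
#' @return Integer matrix `[K x K]`, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, estimate, levels = activity_levels()) {
  if (length(truth) != length(estimate)) {
    rlang::abort("truth and estimate differ in length",
                 class = "gaitrec_shape_error")
  }
  t_f <- factor(as.character(truth), levels = levels)
  e_f <- factor(as.character(estimate), levels = levels)
  cm <- table(truth = t_f, predicted = e_f)
  matrix(as.integer(cm), nrow = length(levels),
         dimnames = list(truth = levels, predicted = levels))
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return `sum(diag(cm)) / sum(cm)`.
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Per-class F1 scores (one-vs-rest)
#'
#' For class k: `TP = cm[k, k]`, `FP = colsum - TP`, `FN = rowsum - TP`, and
#' `F1 = TP / (TP + (FP + FN) / 2)`. A class with `TP = FP = FN = 0` (absent
#' from both truth and predictions) scores 0 and is flagged `degenerate`,
#' which keeps macro averages conservative.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return A tibble: `activity`, `tp`, `fp`, `fn`, `f1`, `degenerate`.
#' @export
#' @examples
#' cm <- matrix(c(9, 1, 1, 9), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' f1_per_class(cm)
f1_per_class <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- tp + (fp + fn) / 2
  degenerate <- denom == 0
  f1 <- ifelse(degenerate, 0, tp / denom)
  tibble::tibble(activity = rownames(cm), tp = as.numeric(tp),
                 fp = as.numeric(fp), fn = as.numeric(fn),
                 f1 = as.numeric(f1), degenerate = degenerate)
}

#' @rdname f1_per_class
#' @return `macro_f1()`: the unweighted mean of the per-class F1 scores.
#' @export
macro_f1 <- function(cm) mean(f1_per_class(cm)$f1)
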