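#' Serialize a stacked dataset to a two-file text container
#'
#' Writes `<prefix>_X.csv` (the design matrix, one header row of feature
#' names) and `<prefix>_meta.csv` (per-row provenance: subject, circuit,
#' run, pass, window index, activity). `read_stacked()` restores the
#' tibble with its `features` matrix column.
#'
#' @param stacked Stacked tibble from [stack_context()] (a feature table
#'   from [build_feature_table()] works too).
#' @param prefix Path prefix for the two files.
#' @return `prefix`, invisibly; `read_stacked()` returns the tibble.
#' @export
write_stacked <- function(stacked, prefix) {
  X <- design_matrix(stacked)
  readr::write_csv(tibble::as_tibble(X), paste0(prefix, "_X.csv"),
                   progress = FALSE)
  meta <- stacked[, setdiff(names(stacked), "features")]
  meta$activity <- as.character(meta$activity)
  readr::write_csv(meta, paste0(prefix, "_meta.csv"), progress = FALSE)
  invisible(prefix)
}

#' @rdname write_stacked
#' @export
read_stacked <- function(prefix) {
  X <- as.matrix(readr::read_csv(paste0(prefix, "_X.csv"),
                                 col_types = readr::cols(.default = "d"),
                                 progress = FALSE))
  meta <- readr::read_csv(paste0(prefix, "_meta.csv"),
                          col_types = readr::cols(
                            subject_id = "c", circuit_id = "c",
                            run_id = "i", pass = "i", window_index = "i",
                            activity = "c"), progress = FALSE)
  if (nrow(meta) != nrow(X)) {
    rlang::abort("matrix and metadata files disagree on row count",
                 class = "gaitrec_io_error")
  }
  meta$activity <- activity_factor(meta$activity)
  meta$features <- X
  meta
}

#' Serialize scaler statistics as key-value text
#'
#' @param scaler A `gait_scaler` from [fit_scaler()].
#' @param path File path (CSV: `column`, `mean`, `scale`).
#' @export
write_scaler <- function(scaler, path) {
  readr::write_csv(tibble::tibble(
    column = names(scaler$mean) %||% seq_along(scaler$mean),
    mean = unname(scaler$mean), scale = unname(scaler$scale)),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  df <- readr::read_csv(path, col_types = "cdd", progress = FALSE)
  structure(list(mean = stats::setNames(df$mean, df$column),
                 scale = stats::setNames(df$scale, df$column)),
            class = "gait_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
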