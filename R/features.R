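#' Nine time-domain features of one window
#'
#' For a window `x` of W samples the features are, in order: `mean`
#' (arithmetic mean), `median`, `sd` (population standard deviation,
#' dividing by W), `min`, `max` (the extreme values, not their positions),
#' `initial` (first sample), `final` (last sample), `mav` (mean absolute
#' deviation from the window mean) and `wl` (waveform length, the sum of
#' absolute first differences).
#'
#' The `median` is the ceil(W/2)-th order statistic of the sorted window
#' (for W = 25, the 13th-smallest value); `median_mode = "center"` instead
#' returns the raw sample at the window's center position (the
#' strict-formula reading, x at offset 12 for W = 25).
#'
#' @param x Numeric vector, one window of one channel (length >= 2).
#' @param median_mode `"sorted"` (default) or `"center"`.
#' @return Named numeric vector of the 9 features.
#' @export
#' @examples
#' extract_features(0:24)
extract_features <- function(x, median_mode = c("sorted", "center")) {
  median_mode <- rlang::arg_match(median_mode)
  w <- length(x)
  if (w < 2) {
    rlang::abort("window must hold at least 2 samples",
                 class = "gaitrec_window_error")
  }
  mu <- mean(x)
  med_i <- (w + 1L) %/% 2L  # ceil(w/2), 1-based
  med <- if (median_mode == "sorted") sort(x, partial = med_i)[med_i] else x[med_i]
  c(mean = mu,
    median = med,
    sd = sqrt(sum((x - mu)^2) / w),
    min = min(x),
    max = max(x),
    initial = x[1],
    final = x[w],
    mav = sum(abs(x - mu)) / w,
    wl = sum(abs(diff(x))))
}

feature_names <- function() {
  c("mean", "median", "sd", "min", "max", "initial", "final", "mav", "wl")
}

#' Build the per-window feature table for a set of circuits
#'
#' Runs the full segmentation front end: transition removal
#' ([remove_transitions()]), five-pass windowing ([window_starts()]) and
#' per-channel feature extraction ([extract_features()], via a compiled
#' kernel) on every circuit. Window rows align all channels of the same
#' (circuit, run, pass, window index), giving `9 * C` feature values per
#' row in canonical channel order (9 consecutive columns per channel).
#'
#' @param circuits Circuit tibble; all circuits must carry the same channel
#'   columns.
#' @param cfg A [segmentation_config()].
#' @param median_mode Passed to the feature kernel; see [extract_features()].
#' @return A tibble: `subject_id`, `circuit_id`, `run_id`, `pass`,
#'   `window_index`, `activity` (factor) and `features`, a numeric matrix
#'   column of width `9 * C` with names `<channel>.<feature>`.
#' @export
build_feature_table <- function(circuits, cfg = segmentation_config(),
                                median_mode = c("sorted", "center")) {
  median_mode <- rlang::arg_match(median_mode)
  chans <- intersect(channel_names(), names(circuits))
  if (length(chans) == 0) {
    rlang::abort("circuits carry no canonical channel columns",
                 class = "gaitrec_config_error")
  }
  runs <- remove_transitions(circuits, cfg)
  meta <- list(); mats <- list()
  for (grp in split_circuits(circuits)) {
    cid <- grp$circuit_id[1]; sid <- grp$subject_id[1]
    rr <- runs[runs$subject_id == sid & runs$circuit_id == cid, ]
    if (nrow(rr) == 0) next
    M <- as.matrix(grp[, chans])
    for (i in seq_len(nrow(rr))) {
      ws <- window_starts(rr$len[i], cfg)
      if (nrow(ws) == 0) next
      seg <- M[(rr$start[i] + 1L):(rr$start[i] + rr$len[i]), , drop = FALSE]
      Fm <- feature_windows_cpp(seg, ws$start, cfg$window,
                                median_mode == "center")
      k <- length(meta) + 1L
      meta[[k]] <- tibble::tibble(
        subject_id = sid, circuit_id = cid, run_id = rr$run_id[i],
        pass = ws$pass, window_index = ws$window_index,
        activity = rr$activity[i])
      mats[[k]] <- Fm
    }
  }
  if (length(meta) == 0) {
    out <- tibble::tibble(subject_id = character(), circuit_id = character(),
                          run_id = integer(), pass = integer(),
                          window_index = integer(),
                          activity = activity_factor(character()))
    out$features <- matrix(numeric(), 0, 9L * length(chans),
                           dimnames = list(NULL, feature_colnames(chans)))
    return(out)
  }
  out <- dplyr::bind_rows(meta)
  out$activity <- activity_factor(out$activity)
  X <- do.call(rbind, mats)
  colnames(X) <- feature_colnames(chans)
  out$features <- X
  out
}

feature_colnames <- function(chans) {
  as.vector(t(outer(chans, feature_names(), paste, sep = ".")))
}
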