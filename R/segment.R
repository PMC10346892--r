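#' Windowing and segmentation configuration
#'
#' Controls how labeled circuits are cut into single-activity windows:
#' 25-sample windows (0.05 s at 500 Hz), five segmentation passes shifted by
#' 5 samples each (together equivalent to stride-5 sliding windows), removal
#' of 500 samples (1 s) around every activity transition, and a temporal
#' context of 3 consecutive windows stacked per classifier input.
#'
#' @param window Window size W in samples (default 25).
#' @param shift Pass-to-pass shift s in samples (default 5); the five passes
#'   start at offsets 0, s, 2s, ... within each activity run.
#' @param n_passes Number of shifted segmentation passes (default 5);
#'   `n_passes * shift` must not exceed `window` so passes tile distinct
#'   phases.
#' @param transition_removal Samples removed around each label change
#'   (default 500, split half before / half after the boundary; must be
#'   even).
#' @param context Number k of consecutive windows stacked per input row
#'   (default 3).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(window = 25L, shift = 5L, n_passes = 5L,
                                transition_removal = 500L, context = 3L) {
  window <- as.integer(window); shift <- as.integer(shift)
  n_passes <- as.integer(n_passes)
  transition_removal <- as.integer(transition_removal)
  context <- as.integer(context)
  stopifnot(window > 0, shift > 0, shift <= window,
            n_passes >= 1, n_passes * shift <= window,
            transition_removal >= 0, transition_removal %% 2L == 0L,
            context >= 1)
  structure(list(window = window, shift = shift, n_passes = n_passes,
                 transition_removal = transition_removal, context = context),
            class = "segmentation_config")
}

#' Split circuits into single-activity runs with transitions removed
#'
#' Splits each circuit's label vector into maximal constant runs, then
#' deletes `transition_removal / 2` samples from each side of every label
#' change, so the ambiguous second around a transition never contributes
#' windows. Runs left shorter than one window are dropped (their count is
#' reported in the `n_dropped` attribute).
#'
#' @param circuits Circuit tibble ([read_circuits()] / [generate_dataset()]).
#' @param cfg A [segmentation_config()].
#' @return A tibble of runs: `subject_id`, `circuit_id`, `run_id` (ordinal
#'   within circuit, numbered before dropping), `activity`, `start` (0-based
#'   sample offset into the circuit), `len`.
#' @export
#' @examples
#' circ <- tibble::tibble(subject_id = "S01", circuit_id = "C01",
#'                        sample_idx = 0:1999, waist_accel_x = 0,
#'                        label = rep(c("sitting", "walking"), each = 1000))
#' remove_transitions(circ, segmentation_config())
remove_transitions <- function(circuits, cfg = segmentation_config()) {
  half <- cfg$transition_removal %/% 2L
  pieces <- purrr::map(split_circuits(circuits), function(grp) {
    r <- rle(as.character(grp$label))
    ends <- cumsum(r$lengths)           # 1-based inclusive
    starts <- ends - r$lengths + 1L
    n_runs <- length(r$lengths)
    # trim half the transition region at every internal boundary
    trim_lo <- ifelse(seq_len(n_runs) > 1L, half, 0L)
    trim_hi <- ifelse(seq_len(n_runs) < n_runs, half, 0L)
    s <- starts + trim_lo
    e <- ends - trim_hi
    len <- pmax(e - s + 1L, 0L)
    tibble::tibble(
      subject_id = grp$subject_id[1], circuit_id = grp$circuit_id[1],
      run_id = seq_len(n_runs), activity = r$values,
      start = s - 1L, len = len)
  })
  if (length(pieces) == 0) {
    pieces <- list(tibble::tibble(
      subject_id = character(), circuit_id = character(),
      run_id = integer(), activity = character(),
      start = integer(), len = integer()))
  }
  out <- dplyr::bind_rows(pieces)
  keep <- out$len >= cfg$window
  res <- out[keep, ]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Window start offsets for the shifted segmentation passes
#'
#' For each pass offset `o` in `0, s, ..., (n_passes - 1) s`, windows tile
#' the run non-overlappingly from `o`; windows extending past the run end
#' are discarded. The union of the passes equals the stride-`s` sliding
#' window set `{p : p = 0 mod s, p + W <= L}`.
#'
#' @param len Run length L in samples.
#' @param cfg A [segmentation_config()].
#' @return A tibble: `pass` (0-based pass index), `window_index` (ordinal
#'   within its pass), `start` (0-based offset within the run).
#' @export
window_starts <- function(len, cfg = segmentation_config()) {
  purrr::map_dfr(seq_len(cfg$n_passes) - 1L, function(p) {
    o <- p * cfg$shift
    n <- if (len >= o + cfg$window) (len - o) %/% cfg$window else 0L
    tibble::tibble(pass = p,
                   window_index = seq_len(n) - 1L,
                   start = o + (seq_len(n) - 1L) * cfg$window)
  })
}

#' Segment one single-activity run into windows
#'
#' Reference (plain R) segmentation of one run: returns every window of
#' every pass together with its values. [build_feature_table()] uses a
#' compiled equivalent; the two paths are interchangeable.
#'
#' @param run Numeric vector (one channel) or matrix `[L x C]` (one column
#'   per channel) of samples for a single-activity run.
#' @param cfg A [segmentation_config()].
#' @return A tibble: `pass`, `window_index`, `start`, and `values`, a matrix
#'   column with W columns per window row (for matrix input, a list-column
#'   of `[W x C]` matrices).
#' @export
segment_run <- function(run, cfg = segmentation_config()) {
  len <- if (is.matrix(run)) nrow(run) else length(run)
  ws <- window_starts(len, cfg)
  if (is.matrix(run)) {
    ws$values <- purrr::map(ws$start, function(s)
      run[(s + 1L):(s + cfg$window), , drop = FALSE])
  } else {
    idx <- outer(ws$start, seq_len(cfg$window), "+")  # 1-based columns
    vals <- matrix(run[idx], nrow = nrow(ws))
    ws$values <- vals
  }
  ws
}
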