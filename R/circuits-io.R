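#' Read labeled motion-circuit recordings
#'
#' Circuit files are plain delimited text (comma separated) with a header and
#' one row per sample: `subject_id, circuit_id, sample_idx, <channel
#' columns>, label`. `sample_idx` is 0-based and contiguous within each
#' circuit; `label` holds the activity name per sample (integer codes 0-6 are
#' accepted as an alternate dialect). One file may hold many circuits.
#'
#' @param path Path to a circuit file.
#' @param channels Channel subset passed to [gait_channels()]: `"all"`,
#'   `"imu_only"`, `"gonio_only"` or a vector of canonical channel names.
#' @param sample_rate Sampling rate in Hz recorded on the result (constant
#'   within and across circuits; 500 Hz for the supported sensors).
#' @return A tibble with columns `subject_id`, `circuit_id`, `sample_idx`,
#'   the selected channels in canonical order, and `label` (a factor over
#'   [activity_levels()]), carrying a `sample_rate` attribute.
#' @export
read_circuits <- function(path, channels = "all", sample_rate = 500) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("circuit file not found: %s", path),
                 class = "gaitrec_io_error")
  }
  hdr <- readr::read_lines(path, n_max = 1L)
  if (length(hdr) == 0L) {
    rlang::abort("empty circuit file", class = "gaitrec_empty_error")
  }
  want <- channel_names(channels)
  cols <- strsplit(hdr, ",", fixed = TRUE)[[1]]
  missing <- setdiff(c("subject_id", "circuit_id", "sample_idx", want, "label"),
                     cols)
  if (length(missing) > 0) {
    rlang::abort(sprintf("circuit file is missing required column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "gaitrec_schema_error")
  }
  spec <- readr::cols_only(
    subject_id = readr::col_character(),
    circuit_id = readr::col_character(),
    sample_idx = readr::col_integer(),
    label = readr::col_character()
  )
  # channels come in as text and through as.numeric(): exact round-trip of
  # full-precision values (fast float parsers can be off by one ulp) and
  # precise row reporting for malformed fields
  for (ch in want) spec$cols[[ch]] <- readr::col_character()
  df <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (nrow(df) == 0L) {
    rlang::abort("circuit file has a header but no samples",
                 class = "gaitrec_empty_error")
  }
  for (ch in want) {
    num <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(num) & !is.na(df[[ch]]) &
                   !(df[[ch]] %in% c("NA", "NaN")))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "non-numeric value '%s' in column %s at data row %d",
        df[[ch]][bad[1]], ch, bad[1]), class = "gaitrec_parse_error")
    }
    df[[ch]] <- num
  }
  df$label <- activity_factor(parse_label_dialect(df$label))
  df <- df[, c("subject_id", "circuit_id", "sample_idx", want, "label")]
  attr(df, "sample_rate") <- sample_rate
  df
}

# integer-code label dialect: "0".."6" -> names
parse_label_dialect <- function(x) {
  if (all(grepl("^[0-9]+$", x))) as.integer(x) else x
}

#' Write circuits to the delimited-text schema
#'
#' @param circuits Circuit tibble as produced by [read_circuits()] or
#'   [generate_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circuits <- function(circuits, path) {
  df <- circuits
  df$label <- as.character(df$label)
  # format doubles at full precision so a read-back is bitwise identical
  for (ch in intersect(channel_names(), names(df))) {
    df[[ch]] <- sprintf("%.17g", df[[ch]])
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Validate circuit recordings
#'
#' Screens circuits for the defects that break downstream processing:
#' non-finite or missing sample values, labels outside the seven-activity
#' set, non-contiguous sample indices, and circuits shorter than one
#' analysis window. Findings are returned, not raised; callers must drop
#' circuits with any `"fatal"` finding (see [drop_fatal_circuits()]).
#'
#' @param circuits Circuit tibble.
#' @param cfg A [segmentation_config()]; supplies the minimum length (one
#'   window) a circuit must have.
#' @return A tibble of findings: `subject_id`, `circuit_id`, `severity`
#'   (`"fatal"` or `"warning"`), `check`, `detail`. Zero rows when clean.
#' @export
validate_circuits <- function(circuits, cfg = segmentation_config()) {
  chans <- intersect(channel_names(), names(circuits))
  out <- list()
  add <- function(sid, cid, severity, check, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      subject_id = sid, circuit_id = cid, severity = severity,
      check = check, detail = detail)
  }
  for (grp in split_circuits(circuits)) {
    sid <- grp$subject_id[1]
    cid <- grp$circuit_id[1]
    X <- as.matrix(grp[, chans])
    bad <- which(!is.finite(X), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      b <- bad[1, , drop = TRUE]
      add(sid, cid, "fatal", "non_finite_sample",
          sprintf("%d non-finite value(s); first at channel %s, sample_idx %d",
                  nrow(bad), chans[b[["col"]]], grp$sample_idx[b[["row"]]]))
    }
    if (anyNA(grp$label)) {
      add(sid, cid, "fatal", "missing_label",
          sprintf("%d missing label(s)", sum(is.na(grp$label))))
    }
    if (nrow(grp) < cfg$window) {
      add(sid, cid, "fatal", "too_short",
          sprintf("circuit has %d samples, below one window (%d)",
                  nrow(grp), cfg$window))
    }
    if (!identical(as.integer(grp$sample_idx),
                   seq.int(0L, length.out = nrow(grp)))) {
      add(sid, cid, "fatal", "sample_idx_gap",
          "sample_idx is not 0-based contiguous")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(subject_id = character(), circuit_id = character(),
                          severity = character(), check = character(),
                          detail = character()))
  }
  dplyr::bind_rows(out)
}

#' @rdname validate_circuits
#' @return `drop_fatal_circuits()`: the circuit tibble with every circuit
#'   carrying a fatal finding removed.
#' @export
drop_fatal_circuits <- function(circuits, cfg = segmentation_config()) {
  f <- validate_circuits(circuits, cfg)
  f <- f[f$severity == "fatal", ]
  if (nrow(f) == 0) return(circuits)
  bad <- unique(paste(f$subject_id, f$circuit_id, sep = "\r"))
  keep <- !(paste(circuits$subject_id, circuits$circuit_id, sep = "\r") %in% bad)
  circuits[keep, ]
}

# list of per-circuit tibbles, preserving first-appearance order
split_circuits <- function(circuits) {
  key <- paste(circuits$subject_id, circuits$circuit_id, sep = "\r")
  split(circuits, factor(key, levels = unique(key)))
}
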