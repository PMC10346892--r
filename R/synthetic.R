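#' Configuration for the synthetic gait-circuit generator
#'
#' The generator emulates the structure of benchmark lower-limb recordings:
#' 8 subjects each performing ~10 motion circuits at 500 Hz, every circuit a
#' fixed sequence of 9 labeled activity segments (see [activity_sequence()]).
#' Each channel within a segment is a sinusoid plus one harmonic plus
#' Gaussian noise, with activity-specific offset, amplitude and gait
#' frequency taken from a pinned profile table, and subject-level variation
#' applied as multiplicative amplitude/frequency scales and additive
#' per-channel offsets.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param circuits_per_subject Circuits per subject (default 10; parity
#'   alternates circuit-by-circuit, giving 5 even + 5 odd).
#' @param duration_range Min/max segment duration in seconds (default 4-10;
#'   each segment's duration is drawn uniformly).
#' @param sample_rate Sampling rate in Hz (default 500).
#' @param amp_spread,freq_spread SDs of the per-subject log-normal
#'   amplitude / gait-frequency scales (defaults 0.15 and 0.03).
#' @param offset_spread SD of the per-subject, per-channel additive offset
#'   shift, in signal units (default 0.15).
#' @param noise_scale Multiplier on every profile `noise_sd` (default 1).
#' @param seed Integer seed fixing the full generated dataset.
#' @param profiles Activity profile table; defaults to
#'   [default_activity_profiles()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 8L,
                             circuits_per_subject = 10L,
                             duration_range = c(4, 10),
                             sample_rate = 500,
                             amp_spread = 0.15,
                             freq_spread = 0.03,
                             offset_spread = 0.15,
                             noise_scale = 1,
                             seed = 1L,
                             profiles = default_activity_profiles()) {
  stopifnot(n_subjects >= 1, circuits_per_subject >= 1,
            length(duration_range) == 2, all(duration_range > 0),
            diff(duration_range) >= 0, sample_rate > 0,
            amp_spread >= 0, freq_spread >= 0, offset_spread >= 0,
            noise_scale >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    circuits_per_subject = as.integer(circuits_per_subject),
    duration_range = as.numeric(duration_range),
    sample_rate = sample_rate,
    amp_spread = amp_spread, freq_spread = freq_spread,
    offset_spread = offset_spread, noise_scale = noise_scale,
    seed = as.integer(seed), profiles = profiles
  ), class = "generator_config")
}

#' Default per-activity, per-channel signal profiles
#'
#' Ships as a plain-text table (`activity_profiles.csv` under `extdata`) so
#' tests can pin exact values. Columns: `activity`, `channel`, `offset`
#' (baseline, signal units), `amplitude` (fundamental), `frequency` (gait
#' frequency, Hz; 0 for sitting/standing), `harmonic_ratio` (amplitude of
#' the second harmonic relative to the fundamental), `noise_sd`.
#'
#' Goniometer profiles are identical within the ramp ascent/descent pair and
#' within the stair ascent/descent pair: joint-angle excursions alone do not
#' separate climbing direction, which the forward-tilt accelerometer offsets
#' do. This makes the goniometer-only ablation strictly harder by design.
#'
#' @return A tibble with 133 rows (7 activities x 19 channels).
#' @export
default_activity_profiles <- function() {
  path <- system.file("extdata", "activity_profiles.csv", package = "gaitrec",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    activity = readr::col_character(), channel = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

#' Draw per-subject variation profiles
#'
#' Each subject gets a log-normal amplitude scale and gait-frequency scale
#' and an additive per-channel offset shift, drawn once from the spreads in
#' `cfg`. Uses the current RNG state; call inside [withr::with_seed()] (as
#' [generate_dataset()] does) for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @return A tibble: `subject_id`, `amp_scale`, `freq_scale`, and
#'   `offset_shift` (list-column of named per-channel shifts).
#' @export
subject_profiles <- function(cfg = generator_config()) {
  chans <- channel_names()
  purrr::map_dfr(seq_len(cfg$n_subjects), function(i) {
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      amp_scale = exp(stats::rnorm(1, 0, cfg$amp_spread)),
      freq_scale = exp(stats::rnorm(1, 0, cfg$freq_spread)),
      offset_shift = list(stats::setNames(
        stats::rnorm(length(chans), 0, cfg$offset_spread), chans))
    )
  })
}

#' Generate one labeled synthetic motion circuit
#'
#' Concatenates one segment per element of [activity_sequence()] for the
#' given parity. Within a segment, channel `c` is
#' `offset + offset_shift + amp_scale * A * sin(2 pi f fs t + phi) +
#' amp_scale * A * h * sin(4 pi f fs t + 2 phi) + N(0, sd)`, with one phase
#' `phi` drawn per segment (right-side channels lag by pi). Labels are
#' constant within a segment. Uses the current RNG state.
#'
#' @param subject One row of [subject_profiles()].
#' @param circuit_id Circuit identifier string.
#' @param parity `"even"` or `"odd"` (selects the activity sequence).
#' @param cfg A [generator_config()].
#' @return A circuit tibble in the schema of [read_circuits()].
#' @export
generate_circuit <- function(subject, circuit_id, parity,
                             cfg = generator_config()) {
  chans <- channel_names()
  prof <- check_profile_coverage(cfg$profiles, chans)
  seq_acts <- activity_sequence(parity)
  sr <- cfg$sample_rate
  right <- grepl("_r_", chans, fixed = TRUE)
  shift <- subject$offset_shift[[1]]

  seg_mats <- vector("list", length(seq_acts))
  seg_labs <- vector("list", length(seq_acts))
  for (s in seq_along(seq_acts)) {
    act <- seq_acts[s]
    dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
    n <- as.integer(round(dur * sr))
    phi <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / sr
    M <- matrix(0, nrow = n, ncol = length(chans))
    for (ci in seq_along(chans)) {
      p <- prof[[act]][[chans[ci]]]
      ph <- phi + if (right[ci]) pi else 0
      x <- p$offset + shift[ci]
      if (p$amplitude > 0 && p$frequency > 0) {
        w <- 2 * pi * p$frequency * subject$freq_scale
        a <- subject$amp_scale * p$amplitude
        x <- x + a * sin(w * t + ph) +
          a * p$harmonic_ratio * sin(2 * w * t + 2 * ph)
      }
      sd <- p$noise_sd * cfg$noise_scale
      M[, ci] <- x + if (sd > 0) stats::rnorm(n, 0, sd) else 0
    }
    seg_mats[[s]] <- M
    seg_labs[[s]] <- rep(act, n)
  }
  M <- do.call(rbind, seg_mats)
  colnames(M) <- chans
  out <- tibble::tibble(
    subject_id = subject$subject_id,
    circuit_id = circuit_id,
    sample_idx = seq.int(0L, length.out = nrow(M))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(M))
  out$label <- activity_factor(unlist(seg_labs))
  attr(out, "sample_rate") <- sr
  out
}

#' Generate a full synthetic dataset of motion circuits
#'
#' Draws subject profiles once, then generates
#' `n_subjects * circuits_per_subject` circuits with parity alternating by
#' circuit index (circuit 2, 4, ... follow the even sequence). Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A circuit tibble (all circuits row-bound) in the schema of
#'   [read_circuits()].
#' @export
#' @examples
#' small <- generator_config(n_subjects = 2, circuits_per_subject = 2,
#'                           duration_range = c(0.3, 0.5), seed = 7)
#' circ <- generate_dataset(small)
#' dplyr::count(circ, subject_id, circuit_id)
generate_dataset <- function(cfg = generator_config()) {
  withr::with_seed(cfg$seed, {
    subs <- subject_profiles(cfg)
    out <- vector("list", cfg$n_subjects * cfg$circuits_per_subject)
    k <- 0L
    for (i in seq_len(cfg$n_subjects)) {
      for (j in seq_len(cfg$circuits_per_subject)) {
        k <- k + 1L
        parity <- if (j %% 2L == 0L) "even" else "odd"
        out[[k]] <- generate_circuit(subs[i, ], sprintf("C%02d", j),
                                     parity, cfg)
      }
    }
    res <- dplyr::bind_rows(out)
    attr(res, "sample_rate") <- cfg$sample_rate
    res
  })
}

# nested lookup list prof[[activity]][[channel]] -> row; errors on gaps
check_profile_coverage <- function(profiles, chans) {
  need <- expand.grid(activity = activity_levels(), channel = chans,
                      stringsAsFactors = FALSE)
  key <- paste(profiles$activity, profiles$channel)
  miss <- !(paste(need$activity, need$channel) %in% key)
  if (any(miss)) {
    m <- need[which(miss)[1], ]
    rlang::abort(sprintf(
      "activity profiles do not cover (%s, %s) [%d missing pairs]",
      m$activity, m$channel, sum(miss)), class = "gaitrec_config_error")
  }
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    r <- profiles[i, ]
    out[[r$activity]][[r$channel]] <- as.list(r)
  }
  out
}
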