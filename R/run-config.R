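#' Run configuration for reproducible command-line runs
#'
#' A single YAML file drives the command-line interface. Top-level keys:
#' `channels`, `seed`, and the nested blocks `generator` (fields of
#' [generator_config()] except `profiles`), `segmentation` (fields of
#' [segmentation_config()]), `ann` (fields of [ann_config()]) and
#' `experiment` (`val_per_subject`, `test_per_subject`, `train_cap`,
#' `n_per_class`, `balance_all`, `median_mode`). Unknown keys are rejected;
#' omitted keys take the package defaults. Every command writes a fully
#' resolved copy of its configuration next to its output.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file (used for command-line
#'   flag precedence: flags beat file beats defaults).
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    channels = "all",
    seed = 1L,
    generator = list(n_subjects = 8L, circuits_per_subject = 10L,
                     duration_range = c(4, 10), sample_rate = 500,
                     amp_spread = 0.15, freq_spread = 0.03,
                     offset_spread = 0.15, noise_scale = 1),
    segmentation = list(window = 25L, shift = 5L, n_passes = 5L,
                        transition_removal = 500L, context = 3L),
    ann = list(hidden = 100L, lambda = 2, max_iters = 1000L,
               c1 = 0.01, c2 = 0.5, int_step = 0.1, ext_factor = 3,
               max_evals = 20L, max_slope_ratio = 100, seed = 1L),
    experiment = list(val_per_subject = 2L, test_per_subject = 4L,
                      train_cap = 8L, n_per_class = NULL,
                      balance_all = FALSE, median_mode = "sorted"))
  user <- if (is.null(path)) list() else {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  }
  cfg <- merge_config(defaults, user, "")
  cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, prefix) {
  if (length(user) == 0) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste0(prefix, unknown, collapse = ", ")),
                 class = "gaitrec_config_error")
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[k] <- user[k]  # [<- keeps explicit NULLs
    }
  }
  base
}

#' @rdname load_run_config
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  rlang::check_installed("yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname load_run_config
#' @return Helper constructors: the package config objects built from a
#'   `run_config`.
#' @export
as_generator_config <- function(cfg) {
  do.call(generator_config, c(cfg$generator, list(seed = cfg$seed)))
}

#' @rdname load_run_config
#' @export
as_segmentation_config <- function(cfg) {
  do.call(segmentation_config, cfg$segmentation)
}

#' @rdname load_run_config
#' @export
as_ann_config <- function(cfg) {
  do.call(ann_config, cfg$ann)
}
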