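#' Canonical sensor channel layout
#'
#' The pipeline uses 19 channels from lower-limb wearables, all sampled at
#' 500 Hz: waist accelerometer x/y and waist gyroscope x; on each thigh and
#' shank, accelerometer x/z and gyroscope y; and four goniometer angles (both
#' knees, both ankles). Left/right sides are distinct named channels; no
#' mirroring or side-pooling is applied.
#'
#' `gait_channels()` returns the channel table for a named subset:
#' * `"all"` - all 19 channels;
#' * `"imu_only"` - the 15 accelerometer/gyroscope channels;
#' * `"gonio_only"` - the 4 goniometer angles;
#' * or an explicit character vector of canonical channel names.
#'
#' @param subset Subset name or character vector of channel names.
#' @return A tibble with columns `name`, `location`, `modality`, `axis`,
#'   in canonical order.
#' @export
#' @examples
#' gait_channels()
#' gait_channels("gonio_only")$name
gait_channels <- function(subset = "all") {
  spec <- channel_layout()
  if (length(subset) == 1L && subset %in% c("all", "imu_only", "gonio_only")) {
    keep <- switch(subset,
      all = rep(TRUE, nrow(spec)),
      imu_only = spec$modality %in% c("accel", "gyro"),
      gonio_only = spec$modality == "gonio"
    )
    return(spec[keep, ])
  }
  unknown <- setdiff(subset, spec$name)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown channel name(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "gaitrec_channel_error")
  }
  spec[spec$name %in% subset, ]  # canonical order, not request order
}

#' @rdname gait_channels
#' @export
channel_names <- function(subset = "all") gait_channels(subset)$name

channel_layout <- function() {
  seg <- function(loc) {
    tibble::tibble(
      name = paste0(loc, c("_accel_x", "_accel_z", "_gyro_y")),
      location = loc,
      modality = c("accel", "accel", "gyro"),
      axis = c("x", "z", "y")
    )
  }
  dplyr::bind_rows(
    tibble::tibble(
      name = c("waist_accel_x", "waist_accel_y", "waist_gyro_x"),
      location = "waist",
      modality = c("accel", "accel", "gyro"),
      axis = c("x", "y", "x")
    ),
    seg("thigh_l"), seg("thigh_r"),
    seg("shank_l"), seg("shank_r"),
    tibble::tibble(
      name = c("knee_l_angle", "knee_r_angle", "ankle_l_angle", "ankle_r_angle"),
      location = c("knee_l", "knee_r", "ankle_l", "ankle_r"),
      modality = "gonio",
      axis = "angle"
    )
  )
}
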