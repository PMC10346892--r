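#' The seven activities of daily living
#'
#' The package recognises seven lower-limb activities. Their order is fixed
#' and used everywhere an ordering matters: integer codes, one-hot columns,
#' network output units and confusion-matrix rows/columns all follow it.
#'
#' @return Character vector of the seven activity names, in canonical order
#'   (integer code = position - 1).
#' @export
#' @examples
#' activity_levels()
#' activity_code(c("walking", "sitting"))
activity_levels <- function() {
  c("sitting", "standing", "walking",
    "ramp_ascent", "ramp_descent",
    "stair_ascent", "stair_descent")
}

#' @rdname activity_levels
#' @param x Character vector of activity names, or integers 0-6 (the alternate
#'   dialect accepted in circuit files).
#' @return `activity_code()`: integer codes 0-6; `activity_factor()`: a factor
#'   over the canonical levels.
#' @export
activity_code <- function(x) {
  f <- activity_factor(x)
  as.integer(f) - 1L
}

#' @rdname activity_levels
#' @export
activity_factor <- function(x) {
  lv <- activity_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 0 | x > 6 | x != floor(x))
    if (any(bad)) {
      rlang::abort(sprintf("invalid integer activity code(s): %s",
                           paste(unique(x[bad]), collapse = ", ")),
                   class = "gaitrec_label_error")
    }
    x <- lv[as.integer(x) + 1L]
  }
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    rlang::abort(sprintf("unknown activity label(s): %s",
                         paste(unique(x[bad]), collapse = ", ")),
                 class = "gaitrec_label_error")
  }
  factor(x, levels = lv)
}

#' Activity sequence of a motion circuit
#'
#' Each recorded circuit follows a fixed activity script. Even-numbered
#' circuits run sitting, standing, walking, ramp ascent, walking, stair
#' descent, walking, standing, sitting; odd-numbered circuits run the reverse
#' variant with stair ascent and ramp descent in the middle.
#'
#' @param parity `"even"` or `"odd"`.
#' @return Character vector of 9 activity names.
#' @export
#' @examples
#' activity_sequence("even")
activity_sequence <- function(parity = c("even", "odd")) {
  parity <- rlang::arg_match(parity)
  mid <- switch(parity,
    even = c("ramp_ascent", "walking", "stair_descent"),
    odd  = c("stair_ascent", "walking", "ramp_descent")
  )
  c("sitting", "standing", "walking", mid, "walking", "standing", "sitting")
}
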