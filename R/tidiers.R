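#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers and plots for fitted networks
#'
#' `tidy()` returns the optimisation trace (one row per accepted
#' conjugate-gradient iteration), `glance()` a one-row model summary, and
#' `autoplot()` the training-cost curve.
#'
#' @param x A `gait_ann`.
#' @param ... Unused.
#' @return `tidy()`: tibble `iter`, `cost`, `grad_norm`, `step`, `n_evals`,
#'   `wolfe_ok`; `glance()`: one-row tibble.
#' @method tidy gait_ann
#' @export
tidy.gait_ann <- function(x, ...) x$trace

#' @rdname tidy.gait_ann
#' @method glance gait_ann
#' @export
glance.gait_ann <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    n_params = p$H * (p$D + 1L) + p$K * (p$H + 1L),
    hidden = p$H, lambda = x$config$lambda,
    iterations = nrow(x$trace),
    final_cost = if (nrow(x$trace)) x$trace$cost[nrow(x$trace)] else NA_real_,
    n_train = x$n_train)
}

#' @rdname tidy.gait_ann
#' @param object A `gait_ann`.
#' @method autoplot gait_ann
#' @export
autoplot.gait_ann <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iter, y = .data$cost)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "conjugate-gradient iteration",
                  y = "cross-entropy + L2 cost",
                  title = "Training cost trace") +
    ggplot2::theme_minimal()
}

#' Tidiers and plots for experiment reports
#'
#' `tidy()` returns per-fold, per-split metrics; `glance()` the
#' across-fold means (unweighted over folds); `autoplot()` shows per-fold
#' accuracies by split.
#'
#' @param x A `gait_eval` from [run_experiment()].
#' @param ... Unused.
#' @method tidy gait_eval
#' @export
tidy.gait_eval <- function(x, ...) x$metrics

#' @rdname tidy.gait_eval
#' @method glance gait_eval
#' @export
glance.gait_eval <- function(x, ...) {
  m <- x$metrics
  agg <- function(split, col) mean(m[[col]][m$split == split])
  tibble::tibble(
    n_folds = length(unique(m$fold)),
    mean_train_accuracy = agg("train", "accuracy"),
    mean_val_accuracy = agg("val", "accuracy"),
    mean_test_accuracy = agg("test", "accuracy"),
    mean_val_macro_f1 = agg("val", "macro_f1"),
    mean_test_macro_f1 = agg("test", "macro_f1"))
}

#' @rdname tidy.gait_eval
#' @param object A `gait_eval`.
#' @method autoplot gait_eval
#' @export
autoplot.gait_eval <- function(object, ...) {
  m <- object$metrics
  m$split <- factor(m$split, levels = c("train", "val", "test"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$split, y = .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0),
                        size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "accuracy", colour = "fold",
                  title = "Leave-one-subject-out accuracy by split") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- tibble::as_tibble(as.data.frame.table(cm, responseName = "count"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
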