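#' Training configuration for the shallow activity-recognition network
#'
#' The classifier is a single-hidden-layer network: D inputs (513 for the
#' default 19-channel, 3-window context), 100 tanh hidden units and 7
#' independent sigmoid outputs (one per activity; no softmax coupling). It
#' is trained full-batch on summed binary cross-entropy with an L2 penalty
#' on non-bias weights, by [fmincg()].
#'
#' @param hidden Hidden units H (default 100).
#' @param lambda L2 strength (default 2). The cost is normalised by 1/N and
#'   the penalty by lambda/(2N), so lambda keeps its meaning across dataset
#'   sizes.
#' @param max_iters Accepted conjugate-gradient iterations (default 1000;
#'   one full-batch iteration per epoch).
#' @param c1,c2,int_step,ext_factor,max_evals,max_slope_ratio Line-search
#'   constants, passed to [fmincg()].
#' @param init_scale Half-width of the uniform weight initialisation; the
#'   default (`NULL`) uses `sqrt(6) / sqrt(fan_in + fan_out)` per layer.
#' @param seed Seed for weight initialisation.
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden = 100L, lambda = 2, max_iters = 1000L,
                       c1 = 0.01, c2 = 0.5, int_step = 0.1, ext_factor = 3,
                       max_evals = 20L, max_slope_ratio = 100,
                       init_scale = NULL, seed = 1L) {
  stopifnot(hidden >= 1, lambda >= 0, max_iters >= 1, c1 > 0, c1 < c2, c2 < 1)
  structure(list(hidden = as.integer(hidden), lambda = lambda,
                 max_iters = as.integer(max_iters), c1 = c1, c2 = c2,
                 int_step = int_step, ext_factor = ext_factor,
                 max_evals = as.integer(max_evals),
                 max_slope_ratio = max_slope_ratio,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "ann_config")
}

#' Initialise network parameters
#'
#' Weights (including biases) are drawn uniformly in `[-eps, eps]` with
#' `eps = sqrt(6) / sqrt(fan_in + fan_out)` per layer unless `init_scale`
#' overrides it; reproducible from `seed`.
#'
#' @param D,H,K Input, hidden and output dimensions.
#' @param seed Integer seed.
#' @param init_scale Optional fixed `eps` for both layers (0 gives all-zero
#'   weights).
#' @return A `gait_params` list: `W1` (`H x (D+1)`, bias first column),
#'   `W2` (`K x (H+1)`), and `D`, `H`, `K`.
#' @export
init_params <- function(D, H, K, seed = 1L, init_scale = NULL) {
  stopifnot(D >= 1, H >= 1, K >= 1)
  e1 <- if (is.null(init_scale)) sqrt(6) / sqrt(D + H) else init_scale
  e2 <- if (is.null(init_scale)) sqrt(6) / sqrt(H + K) else init_scale
  withr::with_seed(seed, {
    W1 <- matrix(stats::runif(H * (D + 1), -e1, e1), nrow = H)
    W2 <- matrix(stats::runif(K * (H + 1), -e2, e2), nrow = K)
    structure(list(W1 = W1, W2 = W2, D = as.integer(D), H = as.integer(H),
                   K = as.integer(K)), class = "gait_params")
  })
}

#' @rdname init_params
#' @param params A `gait_params` object.
#' @return `flatten_params()`: a numeric vector (layer 1 row-major, then
#'   layer 2 row-major); `unflatten_params()` inverts it.
#' @export
flatten_params <- function(params) {
  c(as.vector(t(params$W1)), as.vector(t(params$W2)))
}

#' @rdname init_params
#' @param theta Flattened parameter vector.
#' @export
unflatten_params <- function(theta, D, H, K) {
  n1 <- H * (D + 1)
  stopifnot(length(theta) == n1 + K * (H + 1))
  structure(list(
    W1 = matrix(theta[seq_len(n1)], nrow = H, byrow = TRUE),
    W2 = matrix(theta[-seq_len(n1)], nrow = K, byrow = TRUE),
    D = as.integer(D), H = as.integer(H), K = as.integer(K)),
    class = "gait_params")
}

#' Forward pass of the network
#'
#' `a1 = tanh(W1 [1; x])`, `yhat = sigmoid(W2 [1; a1])`. Outputs are
#' independent per-class sigmoids in (0, 1); they are not normalised across
#' classes.
#'
#' @param params A `gait_params` object.
#' @param X Numeric matrix `[N x D]` of (already scaled) inputs.
#' @return Matrix `[N x K]` of output activations.
#' @export
ann_forward <- function(params, X) {
  forward_pass(params, X)$yhat
}

forward_pass <- function(params, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != params$D) {
    rlang::abort(sprintf("input has %d columns, network expects %d",
                         ncol(X), params$D), class = "gaitrec_shape_error")
  }
  A1 <- tanh(cbind(1, X) %*% t(params$W1))
  yhat <- stats::plogis(cbind(1, A1) %*% t(params$W2))
  list(a1 = A1, yhat = yhat)
}

#' One-hot encode activity labels
#'
#' @param y Factor (or anything [activity_factor()] accepts).
#' @param levels Class levels defining the column order.
#' @return Binary matrix `[N x K]`.
#' @export
one_hot <- function(y, levels = activity_levels()) {
  f <- factor(as.character(y), levels = levels)
  Y <- matrix(0, length(f), length(levels),
              dimnames = list(NULL, levels))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Cross-entropy cost and analytic gradient
#'
#' `J = -(1/N) sum(y log yhat + (1-y) log(1-yhat)) + lambda/(2N) sum(w^2)`
#' over non-bias weights; the gradient comes from backpropagation and is
#' flattened in the [flatten_params()] order. Output activations are
#' clipped to `[1e-12, 1 - 1e-12]` before the logarithms.
#'
#' @param theta Flattened parameter vector.
#' @param X Scaled input matrix `[N x D]`.
#' @param Y One-hot label matrix `[N x K]`.
#' @param lambda L2 strength.
#' @param D,H,K Network dimensions.
#' @return `list(cost, grad)`.
#' @export
ann_cost_grad <- function(theta, X, Y, lambda, D, H, K) {
  if (anyNA(X) || anyNA(Y)) {
    rlang::abort("NaN/NA in network inputs", class = "gaitrec_input_error")
  }
  p <- unflatten_params(theta, D, H, K)
  N <- nrow(X)
  fp <- forward_pass(p, X)
  yh <- fp$yhat
  yc <- pmin(pmax(yh, 1e-12), 1 - 1e-12)
  J <- -sum(Y * log(yc) + (1 - Y) * log1p(-yc)) / N +
    lambda / (2 * N) * (sum(p$W1[, -1]^2) + sum(p$W2[, -1]^2))

  dZ2 <- (yh - Y) / N                      # [N x K]
  dW2 <- crossprod(dZ2, cbind(1, fp$a1))   # [K x (H+1)]
  dA1 <- dZ2 %*% p$W2[, -1, drop = FALSE]  # [N x H]
  dZ1 <- dA1 * (1 - fp$a1 * fp$a1)
  dW1 <- crossprod(dZ1, cbind(1, X))       # [H x (D+1)]
  if (lambda > 0) {
    dW1[, -1] <- dW1[, -1] + lambda / N * p$W1[, -1]
    dW2[, -1] <- dW2[, -1] + lambda / N * p$W2[, -1]
  }
  list(cost = J, grad = c(as.vector(t(dW1)), as.vector(t(dW2))))
}

#' Train the network on a scaled design matrix
#'
#' Low-level trainer: full-batch [fmincg()] on [ann_cost_grad()]. Most
#' users want [gait_ann()], which also fits the scaler and returns a
#' predictable model object.
#'
#' @param X Scaled design matrix `[N x D]`.
#' @param y Activity labels (factor or names/codes).
#' @param config An [ann_config()].
#' @param init Optional `gait_params` start; defaults to [init_params()]
#'   with `config$seed`.
#' @param levels Class levels (columns of the one-hot encoding).
#' @return A list: `params` (`gait_params`), `trace` (tibble from
#'   [fmincg()]), `n_evals`.
#' @export
ann_train <- function(X, y, config = ann_config(), init = NULL,
                      levels = activity_levels()) {
  K <- length(levels)
  D <- ncol(X)
  Y <- one_hot(y, levels)
  p0 <- if (is.null(init)) {
    init_params(D, config$hidden, K, config$seed, config$init_scale)
  } else init
  H <- p0$H
  fn <- function(th) ann_cost_grad(th, X, Y, config$lambda, D, H, K)
  res <- fmincg(fn, flatten_params(p0), max_iters = config$max_iters,
                c1 = config$c1, c2 = config$c2, int_step = config$int_step,
                ext_factor = config$ext_factor, max_evals = config$max_evals,
                max_slope_ratio = config$max_slope_ratio)
  list(params = unflatten_params(res$par, D, H, K), trace = res$trace,
       n_evals = res$n_evals)
}

#' Fit the activity-recognition network on a stacked dataset
#'
#' Fits the feature scaler on the supplied (training) rows, standardises
#' them, and trains the shallow network. The returned object carries
#' everything needed for standalone inference: weights, scaler statistics,
#' class levels and the training trace.
#'
#' @param data Stacked tibble from [stack_context()] (typically balanced
#'   with [balance_classes()] first).
#' @param config An [ann_config()].
#' @return A `gait_ann` object.
#' @export
#' @seealso [predict.gait_ann()], [tidy.gait_ann()], [autoplot.gait_ann()]
gait_ann <- function(data, config = ann_config()) {
  scaler <- fit_scaler(data)
  X <- scale_mat(design_matrix(data), scaler)
  fit <- ann_train(X, data$activity, config)
  structure(list(params = fit$params, scaler = scaler,
                 levels = activity_levels(), config = config,
                 trace = fit$trace, n_train = nrow(X),
                 feature_names = colnames(design_matrix(data))),
            class = "gait_ann")
}

#' Predict activities with a fitted network
#'
#' Applies the model's stored scaler, runs the forward pass and returns the
#' argmax class (ties broken toward the lowest class index).
#'
#' @param object A `gait_ann`.
#' @param newdata Stacked tibble or raw (unscaled) feature matrix.
#' @param type `"class"` (default) for a factor of activities, `"prob"` for
#'   the `[N x K]` sigmoid activation matrix.
#' @param ... Unused.
#' @return Factor of predicted activities, or an activation matrix.
#' @export
predict.gait_ann <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- rlang::arg_match(type)
  X <- scale_mat(design_matrix(newdata), object$scaler)
  yh <- ann_forward(object$params, X)
  if (type == "prob") {
    colnames(yh) <- object$levels
    return(yh)
  }
  factor(object$levels[max.col(yh, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.gait_ann <- function(x, ...) {
  cat(sprintf(
    "<gait_ann> %d-%d-%d network, lambda = %g, %d CG iterations, final cost %.5f\n",
    x$params$D, x$params$H, x$params$K, x$config$lambda,
    nrow(x$trace), if (nrow(x$trace)) x$trace$cost[nrow(x$trace)] else NA_real_))
  invisible(x)
}

#' Save / load a fitted model container
#'
#' The container is a structured JSON file holding the weights, dimensions,
#' scaler statistics and class levels - everything needed for standalone
#' inference on new stacked feature rows.
#'
#' @param object A `gait_ann`.
#' @param path File path.
#' @return `read_gait_ann()`: the restored `gait_ann`.
#' @export
write_gait_ann <- function(object, path) {
  rlang::check_installed("jsonlite")
  payload <- list(
    dims = list(D = object$params$D, H = object$params$H, K = object$params$K),
    W1 = object$params$W1, W2 = object$params$W2,
    scaler_mean = unname(object$scaler$mean),
    scaler_scale = unname(object$scaler$scale),
    levels = object$levels,
    feature_names = object$feature_names,
    lambda = object$config$lambda)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_gait_ann
#' @export
read_gait_ann <- function(path) {
  rlang::check_installed("jsonlite")
  p <- jsonlite::fromJSON(path)
  params <- structure(list(W1 = p$W1, W2 = p$W2, D = as.integer(p$dims$D),
                           H = as.integer(p$dims$H), K = as.integer(p$dims$K)),
                      class = "gait_params")
  structure(list(params = params,
                 scaler = structure(list(mean = p$scaler_mean,
                                         scale = p$scaler_scale),
                                    class = "gait_scaler"),
                 levels = p$levels, config = ann_config(lambda = p$lambda),
                 trace = tibble::tibble(), n_train = NA_integer_,
                 feature_names = p$feature_names),
            class = "gait_ann")
}
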