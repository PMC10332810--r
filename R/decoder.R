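#' Optimizer settings for the logistic decoder
#'
#' Full-batch gradient descent with backtracking (a step that would raise
#' the cost is retried at half the rate), stopping when the cost change
#' drops below `cost_tolerance` or after `max_iter` iterations. Fully
#' deterministic given the data and starting weights.
#'
#' @param learning_rate initial step size (default 0.1).
#' @param max_iter iteration cap (default 10000).
#' @param cost_tolerance convergence threshold on |delta cost|
#'   (default 1e-8).
#' @return a `fit_settings` list.
#' @export
fit_settings <- function(learning_rate = 0.1, max_iter = 10000,
                         cost_tolerance = 1e-8) {
  stopifnot(learning_rate > 0, max_iter >= 1, cost_tolerance > 0)
  structure(list(learning_rate = learning_rate, max_iter = as.integer(max_iter),
                 cost_tolerance = cost_tolerance),
            class = "fit_settings")
}

EPS_PROB <- 1e-12

#' Logistic decoder prediction
#'
#' `h = 1 / (1 + exp(-X %*% theta))`: the probability that each trial's
#' population activity vector was evoked by the target odor. The model has
#' no intercept; `theta` has one weight per cell.
#'
#' @param theta weight vector (length n) or a fitted `odor_decoder`.
#' @param X m x n matrix of per-trial per-cell response features.
#' @return numeric vector of length m with values in (0, 1).
#' @export
decoder_predict <- function(theta, X) {
  if (inherits(theta, "odor_decoder")) theta <- theta$theta
  X <- as.matrix(X)
  if (ncol(X) != length(theta))
    stop("X has ", ncol(X), " columns but theta has length ", length(theta),
         call. = FALSE)
  as.vector(1 / (1 + exp(-(X %*% theta))))
}

check_labels <- function(y) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  invisible(y)
}

#' Decoder cost: binary cross-entropy with quadratic regularization
#'
#' `cost = -(1/m) * sum(y*log(h) + (1-y)*log(1-h)) + (lambda/(2m)) * sum(theta^2)`.
#' Predictions are clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param theta weight vector or fitted `odor_decoder`.
#' @param X m x n feature matrix.
#' @param y binary labels (0/1), length m.
#' @param lambda regularization constant (>= 0; default 1, the standard
#'   setting for odor decoding; transfer-protocol fits use 0).
#' @return scalar cost.
#' @export
decoder_cost <- function(theta, X, y, lambda = 1) {
  if (inherits(theta, "odor_decoder")) {
    if (missing(lambda)) lambda <- theta$lambda
    theta <- theta$theta
  }
  check_labels(y)
  stopifnot(lambda >= 0)
  m <- nrow(as.matrix(X))
  h <- decoder_predict(theta, X)
  h <- pmin(pmax(h, EPS_PROB), 1 - EPS_PROB)
  -mean(y * log(h) + (1 - y) * log(1 - h)) + lambda / (2 * m) * sum(theta^2)
}

#' Analytic gradient of the decoder cost
#'
#' `(1/m) * t(X) %*% (h - y) + (lambda/m) * theta`.
#'
#' @inheritParams decoder_cost
#' @return numeric vector of length n.
#' @export
decoder_gradient <- function(theta, X, y, lambda = 1) {
  if (inherits(theta, "odor_decoder")) {
    if (missing(lambda)) lambda <- theta$lambda
    theta <- theta$theta
  }
  check_labels(y)
  X <- as.matrix(X)
  m <- nrow(X)
  h <- decoder_predict(theta, X)
  as.vector(crossprod(X, h - y) / m + (lambda / m) * theta)
}

#' Initialize weights from connectome synapse counts
#'
#' Synapse counts from a KC to an MBON are taken as linearly related to
#' synaptic weight and normalized to the maximum count observed; starting
#' weights are sampled uniformly with replacement from that empirical
#' distribution, so every initial weight lies in (0, 1].
#'
#' @param counts positive per-KC synapse counts (e.g. from
#'   [gen_synapse_counts()]).
#' @param n number of weights to draw.
#' @param seed RNG seed for the sampling.
#' @return numeric vector of length `n`.
#' @export
init_weights_connectome <- function(counts, n, seed = 1) {
  if (length(counts) == 0) stop("empty synapse-count vector", call. = FALSE)
  if (any(counts <= 0)) stop("synapse counts must be positive", call. = FALSE)
  w <- counts / max(counts)
  withr::with_seed(seed, sample(w, n, replace = TRUE))
}

#' Initialize all weights at one
#'
#' The initialization used for the MBON-emulation transfer models.
#'
#' @param n number of weights.
#' @return numeric vector of `n` ones.
#' @export
init_weights_ones <- function(n) {
  stopifnot(n >= 1)
  rep(1, n)
}

#' Fit a logistic decoder by gradient descent
#'
#' Deterministic full-batch gradient descent from `theta0`. Steps that
#' would increase the cost are retried at half the learning rate, so the
#' accepted cost sequence is non-increasing; fitting stops when the cost
#' improvement falls below `cost_tolerance` or at `max_iter`.
#'
#' @param X m x n feature matrix.
#' @param y binary labels (both classes must be present).
#' @param theta0 starting weights (length n).
#' @param lambda regularization constant (default 1).
#' @param settings a [fit_settings()].
#' @param threshold decision threshold on the prediction (default 0.5;
#'   a prediction exactly at threshold is classified positive).
#' @param init_scheme provenance tag stored with the model.
#' @return an `odor_decoder`: `theta`, `lambda`, `threshold`,
#'   `init_scheme`, and fit diagnostics (`final_cost`, `iterations`,
#'   `converged`, `cost_path` first/last).
#' @export
fit_decoder <- function(X, y, theta0 = NULL, lambda = 1,
                        settings = fit_settings(), threshold = 0.5,
                        init_scheme = "ones") {
  X <- as.matrix(X)
  check_labels(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present for fitting", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)", call. = FALSE)
  if (is.null(theta0)) theta0 <- init_weights_ones(ncol(X))
  if (length(theta0) != ncol(X)) stop("theta0 has wrong length", call. = FALSE)

  # inlined cost/gradient (same formulas as decoder_cost / decoder_gradient,
  # without per-call validation) to keep many-fold cross-validation fast
  m <- nrow(X)
  cost_at <- function(th) {
    h <- 1 / (1 + exp(-(X %*% th)))
    h <- pmin(pmax(h, EPS_PROB), 1 - EPS_PROB)
    -mean(y * log(h) + (1 - y) * log(1 - h)) + lambda / (2 * m) * sum(th^2)
  }
  theta <- theta0
  cost <- cost_at(theta)
  lr <- settings$learning_rate
  it <- 0L
  converged <- FALSE
  first_cost <- cost
  while (it < settings$max_iter) {
    it <- it + 1L
    h <- as.vector(1 / (1 + exp(-(X %*% theta))))
    g <- as.vector(crossprod(X, h - y)) / m + (lambda / m) * theta
    step_lr <- lr
    repeat {
      cand <- theta - step_lr * g
      cand_cost <- cost_at(cand)
      if (!is.finite(cand_cost))
        stop("cost diverged; try a smaller learning_rate", call. = FALSE)
      if (cand_cost <= cost + 1e-15) break
      step_lr <- step_lr / 2
      if (step_lr < 1e-15) { cand <- theta; cand_cost <- cost; break }
    }
    delta <- cost - cand_cost
    theta <- cand
    cost <- cand_cost
    if (delta < settings$cost_tolerance) { converged <- TRUE; break }
  }
  structure(list(theta = theta, lambda = lambda, threshold = threshold,
                 init_scheme = init_scheme,
                 final_cost = cost, iterations = it, converged = converged,
                 initial_cost = first_cost),
            class = "odor_decoder")
}

#' @export
print.odor_decoder <- function(x, ...) {
  cat(sprintf("<odor_decoder> %d weights, lambda = %g, cost %.4g after %d iterations%s\n",
              length(x$theta), x$lambda, x$final_cost, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Tidy a fitted odor decoder
#'
#' @param x an `odor_decoder`.
#' @param ... unused.
#' @return tibble with one row per cell: `term`, `estimate`.
#' @method tidy odor_decoder
#' @export
tidy.odor_decoder <- function(x, ...) {
  tibble::tibble(term = paste0("cell_", seq_along(x$theta)), estimate = x$theta)
}

#' One-row fit summary of an odor decoder
#'
#' @param x an `odor_decoder`.
#' @param ... unused.
#' @return tibble with `lambda`, `threshold`, `final_cost`, `iterations`,
#'   `converged`, `theta_norm`.
#' @method glance odor_decoder
#' @export
glance.odor_decoder <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, threshold = x$threshold,
                 final_cost = x$final_cost, iterations = x$iterations,
                 converged = x$converged, theta_norm = sqrt(sum(x$theta^2)))
}

#' @export
predict.odor_decoder <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  h <- decoder_predict(object$theta, newdata)
  if (type == "class") as.integer(h >= object$threshold) else h
}

#' Correlation between decoder weights and odor responses
#'
#' Pearson correlation between the fitted weight vector and the per-cell
#' mean response amplitude to one odor. After training a model to report
#' the dissimilar odor (low output for the paired and similar odors),
#' weights are expected to correlate negatively with responses to the
#' paired odor.
#'
#' @param model an `odor_decoder` or plain weight vector.
#' @param amplitudes per-cell mean response amplitudes (length n).
#' @return scalar Pearson r.
#' @export
weight_response_correlation <- function(model, amplitudes) {
  theta <- if (inherits(model, "odor_decoder")) model$theta else model
  if (length(amplitudes) != length(theta))
    stop("amplitude vector length must match the number of weights", call. = FALSE)
  if (stats::sd(theta) == 0 || stats::sd(amplitudes) == 0)
    stop("zero variance in weights or amplitudes", call. = FALSE)
  stats::cor(theta, amplitudes)
}
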