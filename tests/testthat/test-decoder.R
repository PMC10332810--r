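test_that("prediction is the elementwise logistic of X * theta", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(decoder_predict(rep(0, 3), X), rep(0.5, 4))
  # hand evaluation: x = [1, 2], theta = [0.5, -0.25] -> sigma(0) = 0.5
  expect_equal(decoder_predict(c(0.5, -0.25), matrix(c(1, 2), 1)), 0.5)
  # saturation
  expect_gt(decoder_predict(20, matrix(1, 1, 1)), 0.999999)
  # invariant to jointly permuting cells in X and theta
  th <- rnorm(3)
  p <- sample(3)
  expect_equal(decoder_predict(th, X), decoder_predict(th[p], X[, p]))
  expect_error(decoder_predict(c(1, 2), X), "columns")
})

test_that("the cost is cross-entropy plus lambda/(2m) * sum(theta^2)", {
  # theta = 0 -> h = 0.5 -> cost = ln 2, any labels
  X <- matrix(rnorm(20), 5, 4)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(decoder_cost(rep(0, 4), X, y, lambda = 0), log(2))
  expect_equal(decoder_cost(rep(0, 4), X, y, lambda = 7), log(2))  # theta = 0
  # worked single-trial case: y = 1, h = 0.5, lambda = 2, theta = [1, 1]
  # -> -log(0.5) + (2 / (2*1)) * 2 = 0.6931... + 2
  expect_equal(decoder_cost(c(1, 1), matrix(c(1, -1), 1), y = 1, lambda = 2),
               log(2) + 2, tolerance = 1e-12)
  expect_equal(round(decoder_cost(c(1, 1), matrix(c(1, -1), 1), 1, 2), 4),
               2.6931)
  expect_error(decoder_cost(c(1, 1), matrix(c(1, -1), 1), y = 2), "0 or 1")
})

test_that("the analytic gradient matches central finite differences", {
  worst <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      X <- matrix(rnorm(20), 5, 4)
      y <- rbinom(5, 1, 0.5)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      th <- rnorm(4)
      lam <- runif(1, 0, 2)
    })
    g <- decoder_gradient(th, X, y, lam)
    eps <- 1e-6
    fd <- vapply(1:4, function(j) {
      e <- rep(0, 4); e[j] <- eps
      (decoder_cost(th + e, X, y, lam) - decoder_cost(th - e, X, y, lam)) /
        (2 * eps)
    }, numeric(1))
    worst <- max(worst, max(abs(g - fd)) / max(abs(fd)))
  }
  expect_lt(worst, 1e-6)
  # lambda term alone: with y = h by construction (theta = 0, y = 0.5 not
  # allowed), use the decomposition g(lam) - g(0) = (lam/m) * theta
  X <- matrix(rnorm(12), 3, 4); y <- c(1, 0, 1); th <- rnorm(4)
  expect_equal(decoder_gradient(th, X, y, 3) - decoder_gradient(th, X, y, 0),
               th, tolerance = 1e-12)
})

separable_xy <- function(seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(10, mean = 2, sd = 0.3), 5, 2),
               matrix(rnorm(10, mean = -2, sd = 0.3), 5, 2))
    list(X = X, y = rep(c(1, 0), each = 5))
  })
}

test_that("gradient descent solves a separable problem with monotone cost", {
  d <- separable_xy()
  fit <- fit_decoder(d$X, d$y, lambda = 0)
  h <- decoder_predict(fit, d$X)
  expect_equal(as.integer(h >= 0.5), d$y)   # training accuracy 1.0
  expect_lt(fit$final_cost, fit$initial_cost)
  # monotonicity probe: final cost is non-increasing in the iteration budget
  costs <- vapply(c(1, 3, 10, 50, 200), function(k) {
    fit_decoder(d$X, d$y, lambda = 0,
                settings = fit_settings(max_iter = k))$final_cost
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("strong regularization shrinks weights toward chance output", {
  d <- separable_xy()
  fit <- fit_decoder(d$X, d$y, theta0 = c(1, 1), lambda = 1e6)
  expect_lt(sqrt(sum(fit$theta^2)), sqrt(2))
  h <- decoder_predict(fit, d$X)
  expect_true(all(abs(h - 0.5) < 0.05))
  # ||theta|| non-increasing along a lambda grid
  norms <- vapply(c(0, 1, 10, 100), function(l) {
    sqrt(sum(fit_decoder(d$X, d$y, theta0 = c(1, 1), lambda = l)$theta^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("fitting is deterministic and validates its inputs", {
  d <- separable_xy()
  f1 <- fit_decoder(d$X, d$y, lambda = 1)
  f2 <- fit_decoder(d$X, d$y, lambda = 1)
  expect_identical(f1$theta, f2$theta)
  expect_error(fit_decoder(d$X, rep(1, 10)), "both classes")
  expect_error(fit_decoder(d$X, d$y, theta0 = 1), "wrong length")
  expect_error(fit_decoder(d$X, d$y, threshold = 1.2), "threshold")
})

test_that("connectome initialization normalizes to the max and samples from it", {
  w <- init_weights_connectome(c(10, 20, 40), n = 200, seed = 2)
  expect_true(all(w %in% c(0.25, 0.5, 1.0)))
  expect_true(all(w > 0 & w <= 1))
  expect_identical(w, init_weights_connectome(c(10, 20, 40), 200, seed = 2))
  expect_equal(init_weights_connectome(c(7, 7, 7), 5), rep(1, 5))
  expect_error(init_weights_connectome(numeric(0), 5), "empty")
  expect_equal(init_weights_ones(3), c(1, 1, 1))
  expect_equal(init_weights_ones(1), 1)
})

test_that("tidy and glance summarize fitted decoders", {
  d <- separable_xy()
  fit <- fit_decoder(d$X, d$y, lambda = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$estimate, fit$theta)
  gl <- glance(fit)
  expect_equal(gl$lambda, 1)
  expect_equal(gl$theta_norm, sqrt(sum(fit$theta^2)))
  expect_equal(predict(fit, d$X, type = "class"), d$y)
})

test_that("weight-response correlations recover planted sign structure", {
  amp <- runif(30)
  expect_equal(weight_response_correlation(-amp, amp), -1)
  # independent weights: |r| small on average over seeds
  rs <- vapply(1:30, function(s) {
    withr::with_seed(s, weight_response_correlation(rnorm(30), amp))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.1)
  expect_error(weight_response_correlation(rep(1, 30), amp), "variance")
  expect_error(weight_response_correlation(rnorm(10), amp), "length")
})
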