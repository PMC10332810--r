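test_that("background subtraction applies once, in the right order", {
  t <- const_tensor(5, background = 1)
  t2 <- subtract_background(t)
  expect_true(all(t2$values == 4))
  expect_equal(t2$kind, "raw")
  t0 <- subtract_background(const_tensor(5, background = 0))
  expect_true(all(t0$values == 5))
  expect_error(subtract_background(t2), "already subtracted")
  d <- dff_tensor_from(matrix(0, 10, 1))
  expect_error(subtract_background(d), "dF/F")
  expect_warning(subtract_background(const_tensor(5, background = 7)),
                 "negative F")
})

test_that("dF/F follows (F - F0)/F0 with a per-trial pre-odor baseline", {
  # F = F0 everywhere -> 0
  t <- compute_dff(subtract_background(const_tensor(5, background = 0)))
  expect_true(all(abs(t$values) < 1e-12))
  expect_equal(t$kind, "dff")

  # baseline 2, response 3 -> dff = 0.5 in the response frames
  vals <- array(2, dim = c(1, 200, 1))
  vals[1, 81:130, 1] <- 3
  tr <- trial_tensor(vals, 10, "raw")
  d <- compute_dff(subtract_background(tr))
  expect_equal(unique(d$values[1, 81:130, 1]), 0.5)
  # and the baseline window itself averages to 0
  expect_equal(mean(d$values[1, 1:80, 1]), 0)

  # joint scaling of F and background by c > 0 leaves dff unchanged
  tr_a <- trial_tensor(vals + 10, 10, "raw", background = 10)
  tr_b <- trial_tensor(3 * (vals + 10), 10, "raw", background = 30)
  d_a <- compute_dff(subtract_background(tr_a))
  d_b <- compute_dff(subtract_background(tr_b))
  expect_equal(d_a$values, d_b$values, tolerance = 1e-12)

  # non-positive F0 is an error naming the offender
  bad <- trial_tensor(array(0, c(1, 200, 1)), 10, "raw")
  bad <- suppressWarnings(subtract_background(bad))
  expect_error(compute_dff(bad), "cell 1, trial 1")
  expect_error(compute_dff(const_tensor(5)), "subtract background")
})

test_that("boxcar filtering is a shrinking-window moving average, plot-only", {
  # constant trace unchanged
  expect_equal(boxcar_filter(rep(3, 50), 0.2, rate = 10), rep(3, 50))
  # impulse of height h at 10 Hz with 0.2 s window (2 frames) -> plateau h/2
  imp <- rep(0, 20); imp[10] <- 1
  f <- boxcar_filter(imp, 0.2, rate = 10)
  expect_equal(sum(f == 0.5), 2)
  expect_equal(sum(f), 1)  # interior mass preserved
  # mean preserved for interior-dominated traces
  x <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(mean(boxcar_filter(x, 0.5, rate = 10)), mean(x), tolerance = 1e-2)
  # a filtered tensor is refused by quantification
  d <- dff_tensor_from(matrix(rnorm(100), 100, 1))
  df <- boxcar_filter(d)
  expect_true(df$filtered)
  sched <- pulse_schedule(1)
  expect_error(response_amplitude(df, sched), "unfiltered")
})

test_that("response amplitudes are window means anchored at epoch onsets", {
  sched <- pulse_schedule(1, onset = 8, dur = 8)
  tr <- matrix(0, 200, 1); tr[81:160, 1] <- 0.4
  d <- dff_tensor_from(tr, labels = "A")
  a <- response_amplitude(d, sched, "first", response_window(0, 8))
  expect_equal(a$amplitude, 0.4)

  # linear ramp 0 -> 1 over the 8 s window averages to 0.5 (+- one frame)
  tr2 <- matrix(0, 200, 1); tr2[81:160, 1] <- seq(0, 1, length.out = 80)
  d2 <- dff_tensor_from(tr2, labels = "A")
  a2 <- response_amplitude(d2, sched, "first", response_window(0, 8))
  expect_equal(a2$amplitude, 0.5, tolerance = 1 / 80)

  # linearity in the trace
  d3 <- dff_tensor_from(2 * tr2 + 0.1, labels = "A")
  a3 <- response_amplitude(d3, sched, "first", response_window(0, 8))
  expect_equal(a3$amplitude, 2 * a2$amplitude + 0.1, tolerance = 1e-12)

  expect_error(response_amplitude(d, sched, "first", response_window(30, 8)),
               "outside")
})

test_that("transition contrast is max(second) - min(first), offset-invariant", {
  sched <- stim_schedule(trial = 1, stimulus = "A_to_Aprime", epoch = 1:2,
                         odor = c("A", "Aprime"),
                         onset_s = c(8, 13), offset_s = c(13, 18))
  tr <- matrix(0.5, 200, 1)
  tr[81:130, 1] <- seq(0.5, 0.1, length.out = 50)   # first pulse dips to 0.1
  tr[131:180, 1] <- seq(0.1, 0.9, length.out = 50)  # second rises to 0.9
  d <- dff_tensor_from(tr, labels = "A_to_Aprime")
  ct <- transition_contrast(d, sched)
  expect_equal(ct$contrast, 0.8, tolerance = 1e-9)

  # flat trace -> 0; +5 offset leaves the score unchanged
  d_flat <- dff_tensor_from(matrix(0.2, 200, 1), labels = "A_to_Aprime")
  expect_equal(transition_contrast(d_flat, sched)$contrast, 0)
  d_off <- dff_tensor_from(tr + 5, labels = "A_to_Aprime")
  expect_equal(transition_contrast(d_off, sched)$contrast, ct$contrast,
               tolerance = 1e-12)
  expect_equal(abs(ct$contrast),
               transition_contrast(d, sched, signed = FALSE)$contrast)

  # single-pulse trial is rejected
  sp <- pulse_schedule(1)
  dd <- dff_tensor_from(tr, labels = "A")
  expect_error(transition_contrast(dd, sp, trials = 1), "not transition")
})

test_that("trial-averaged heatmaps sort cells by descending response", {
  sched <- pulse_schedule(2, onset = 8, dur = 5)
  arr <- array(0, dim = c(2, 200, 2))
  arr[1, 81:130, ] <- 0.1   # weak cell
  arr[2, 81:130, ] <- 0.9   # strong cell
  t <- trial_tensor(arr, 10, "raw", trial_labels = c("A", "A"))
  t$kind <- "dff"
  hm <- trial_average_sorted(t, sched, "A")
  expect_equal(hm$cell_order, c(2, 1))
  # single trial: averaging is the identity
  t1 <- trial_tensor(arr[, , 1, drop = FALSE], 10, "raw", trial_labels = "A")
  t1$kind <- "dff"
  hm1 <- trial_average_sorted(t1, pulse_schedule(1), "A")
  m <- tidyr::pivot_wider(hm1$traces[, c("cell", "frame", "dff")],
                          names_from = "frame", values_from = "dff")
  expect_equal(unname(as.matrix(m[, -1])), arr[, , 1])
  # permuting input cells permutes provenance, not content
  arr_p <- arr[c(2, 1), , ]
  tp <- trial_tensor(arr_p, 10, "raw", trial_labels = c("A", "A"))
  tp$kind <- "dff"
  hmp <- trial_average_sorted(tp, sched, "A")
  expect_equal(hmp$cell_order, c(1, 2))
  ranked <- function(h) dplyr::arrange(h$traces, .data$rank, .data$frame)$dff
  expect_equal(ranked(hmp), ranked(hm))
})

test_that("PCA projection matches a direct eigen-decomposition oracle", {
  set.seed(11)
  X <- matrix(rnorm(9 * 7), 9, 7)
  proj <- pca_project(X)
  # oracle: eigenvectors of the covariance of the centered matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(proj[[paste0("PC", j)]], as.vector(Xc %*% v), tolerance = 1e-8)
  }
  # projected variance cannot exceed total variance
  expect_lte(stats::var(proj$PC1) + stats::var(proj$PC2),
             sum(apply(Xc, 2, stats::var)) + 1e-12)
  # duplicated trials project to identical points (rank-1 input also
  # exercises the degenerate-rank warning path)
  Xd <- rbind(X[1, ], X[1, ], X[2, ])
  expect_warning(pd <- pca_project(Xd), "rank")
  expect_equal(pd$PC1[1], pd$PC1[2])
  expect_equal(pd$PC2[1], pd$PC2[2])
})

test_that("well-separated odor clusters separate in PC space", {
  set.seed(4)
  A <- matrix(rnorm(8 * 20, mean = 0), 8, 20)
  B <- matrix(rnorm(8 * 20, mean = 3), 8, 20)
  feats <- dplyr::bind_rows(
    purrr::imap_dfr(asplit(A, 1), function(row, i)
      tibble::tibble(trial = i, stimulus = "A", cell = 1:20, feature = row)),
    purrr::imap_dfr(asplit(B, 1), function(row, i)
      tibble::tibble(trial = 8 + i, stimulus = "B", cell = 1:20, feature = row)))
  pr <- pca_project(feats)
  cents <- pr |> dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(x = mean(.data$PC1), y = mean(.data$PC2))
  between <- sqrt(diff(cents$x)^2 + diff(cents$y)^2)
  within <- pr |> dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(w = mean(sqrt((.data$PC1 - mean(.data$PC1))^2 +
                                   (.data$PC2 - mean(.data$PC2))^2)))
  expect_gt(between, max(within$w))
})

test_that("per-cell odor correlations pool cells and flag degenerate input", {
  amp <- tibble::tibble(cell = rep(1:10, 2),
                        stimulus = rep(c("A", "Aprime"), each = 10),
                        amplitude = c(1:10, 1:10))
  r <- odor_response_correlation(amp, c("A", "Aprime"))
  expect_equal(r$estimate, 1)
  amp2 <- amp
  amp2$amplitude[11:20] <- -(1:10)
  expect_equal(odor_response_correlation(amp2, c("A", "Aprime"))$estimate, -1)
  amp3 <- amp
  amp3$amplitude[11:20] <- 2
  expect_error(odor_response_correlation(amp3, c("A", "Aprime")), "variance")
})
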