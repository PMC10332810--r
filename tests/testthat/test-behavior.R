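traj_from <- function(x, y, rate = 5, run = 1) {
  n <- length(x)
  out <- tibble::tibble(run_id = run, fly_id = rep(seq_along(x), each = 1),
                        frame = 1L, t_s = 0, x_mm = x, y_mm = y)
  attr(out, "frame_rate_hz") <- rate
  attr(out, "center") <- c(0, 0)
  out
}

test_that("quadrant counting follows the CCW boundary convention", {
  # all flies in quadrant 1
  t1 <- traj_from(x = rep(3, 7), y = rep(2, 7))
  c1 <- quadrant_counts(t1)
  expect_equal(unlist(c1[1, paste0("q", 1:4)], use.names = FALSE), c(7, 0, 0, 0))
  expect_equal(c1$n_total, 7)
  # a fly exactly on the +x axis (angle 0) starts quadrant 1; on +y, quadrant 2
  expect_equal(quadrant_of(1, 0), 1L)
  expect_equal(quadrant_of(0, 1), 2L)
  expect_equal(quadrant_of(-1, 0), 3L)
  expect_equal(quadrant_of(0, -1), 4L)
  # rotating all positions by 90 degrees permutes counts cyclically
  x <- rnorm(20); y <- rnorm(20)
  q0 <- tabulate(quadrant_of(x, y), 4)
  q90 <- tabulate(quadrant_of(-y, x), 4)
  expect_equal(q90, q0[c(4, 1, 2, 3)])
})

test_that("the performance index is (paired - unpaired)/total with its symmetries", {
  counts <- tibble::tibble(frame = 1:2, q1 = c(10, 0), q2 = c(5, 0),
                           q3 = c(0, 15), q4 = c(0, 0), n_total = 15)
  pi <- performance_index_series(counts, c(1, 3), frame_rate_hz = 1,
                                 summary_window_s = 2)
  expect_equal(pi$pi_series$pi, c(1 / 3, 1))
  # uniform occupancy -> 0
  u <- tibble::tibble(frame = 1, q1 = 4, q2 = 4, q3 = 4, q4 = 4, n_total = 16)
  expect_equal(performance_index_series(u, c(1, 3), 1)$pi_scalar, 0)
  # swapping paired/unpaired labels negates PI; bounds always hold
  pi_sw <- performance_index_series(counts, c(2, 4), 1, summary_window_s = 2)
  expect_equal(pi_sw$pi_series$pi, -pi$pi_series$pi)
  expect_true(all(abs(pi$pi_series$pi) <= 1))
  z <- tibble::tibble(frame = 1, q1 = 0, q2 = 0, q3 = 0, q4 = 0, n_total = 0)
  expect_error(performance_index_series(z, c(1, 3), 1), "zero flies")
})

test_that("reciprocal and generalization scores combine PIs as defined", {
  expect_equal(reciprocal_pi(0.4, 0.2), 0.3)
  expect_equal(reciprocal_pi(0.7, 0.7), 0.7)
  expect_equal(reciprocal_pi(0.5, -0.5), 0)

  mk_pi <- function(scalar, baseline) {
    structure(list(pi_series = NULL, pi_scalar = scalar,
                   baseline_pi = baseline, design = "unpaired-control"),
              class = "pi_result")
  }
  expect_equal(generalization_score(mk_pi(0.5, 0.1), mk_pi(0.2, 0.1)), 0.3)
  expect_equal(generalization_score(mk_pi(0.4, 0.2), mk_pi(0.4, 0.2)), 0)
  # adding the same constant to all four inputs changes nothing
  expect_equal(generalization_score(mk_pi(0.5 + 0.3, 0.1 + 0.3),
                                    mk_pi(0.2 + 0.3, 0.1 + 0.3)), 0.3)
  expect_error(generalization_score(mk_pi(0.5, NA), mk_pi(0.2, 0.1)),
               "baseline")
})

test_that("upwind displacement is radial change from the onset position", {
  # one fly static at (3, 4), another moving radially 3 mm -> 5 mm
  n <- 11
  tr <- tibble::tibble(
    run_id = 1,
    fly_id = rep(1:2, each = n),
    frame = rep(1:n, 2),
    t_s = rep(seq(0, 2, by = 0.2), 2),
    x_mm = c(rep(3, n), seq(3, 5, length.out = n)),
    y_mm = c(rep(4, n), rep(0, n)))
  attr(tr, "frame_rate_hz") <- 5
  attr(tr, "center") <- c(0, 0)
  up <- upwind_displacement(tr, onset_s = 0, window_s = 2)
  d1 <- up$per_fly$displacement_mm[up$per_fly$fly_id == 1]
  d2 <- up$per_fly$displacement_mm[up$per_fly$fly_id == 2]
  expect_true(all(d1 == 0))
  expect_equal(max(d2), 2, tolerance = 0.21)   # one-frame discretization
  expect_equal(d2[1], 0)                        # exactly 0 at onset
  # rigid rotation about the center leaves displacement unchanged
  th <- pi / 3
  tr_rot <- tr
  tr_rot$x_mm <- cos(th) * tr$x_mm - sin(th) * tr$y_mm
  tr_rot$y_mm <- sin(th) * tr$x_mm + cos(th) * tr$y_mm
  attr(tr_rot, "frame_rate_hz") <- 5
  up_rot <- upwind_displacement(tr_rot, onset_s = 0, window_s = 2)
  expect_equal(up_rot$arena_series$mean_displacement_mm,
               up$arena_series$mean_displacement_mm, tolerance = 1e-9)
  expect_error(upwind_displacement(tr, onset_s = 99), "outside")
})

test_that("radial positions report distance from the center", {
  tr <- traj_from(x = c(0, 3), y = c(0, 4))
  rp <- radial_position_at(tr, 0)
  expect_equal(rp$per_fly$r_mm, c(0, 5))
  expect_equal(rp$mean_mm, 2.5)
  # rotation invariance
  tr2 <- traj_from(x = c(0, -4), y = c(0, 3))
  expect_equal(radial_position_at(tr2, 0)$per_fly$r_mm, c(0, 5))
})

test_that("planted drift is recovered by the paired-control estimator", {
  tl_p <- arena_timeline(tibble::tibble(type = c("air", "pulse"),
                                        onset_s = c(0, 5), offset_s = c(5, 15)))
  tl_0 <- arena_timeline(tibble::tibble(type = "air", onset_s = 0,
                                        offset_s = 15))
  ests <- vapply(1:25, function(i) {
    cfg <- arena_synth_config(seed = 300 + i, upwind_drift = 1.5)
    stim <- gen_arena_trajectories(cfg, tl_p, duration_s = 11)
    ctrl <- gen_arena_trajectories(cfg, tl_0, duration_s = 11)
    estimate_upwind_drift(stim, ctrl, onset_s = 5)$drift_mm_s
  }, numeric(1))
  expect_equal(mean(ests), 1.5, tolerance = 0.1 * 1.5)
})
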