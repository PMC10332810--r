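small_kc <- function(..., seed = 5) {
  kc_synth_config(n_cells = 60, n_trials_per_stim = 3, seed = seed, ...)
}

test_that("full overlap with perfect amplitude coupling makes A and Aprime identical", {
  cfg <- small_kc(overlap_AAprime = 1, amplitude_corr_target = 1,
                  trial_noise_sd = 0, order_effect_eps = 0)
  d <- gen_kc_dataset(cfg)
  iA <- which(d$tensor$trial_labels == "A")
  iAp <- which(d$tensor$trial_labels == "Aprime")
  expect_equal(d$tensor$values[, , iA], d$tensor$values[, , iAp],
               tolerance = 1e-12)
})

test_that("the realized A-Aprime amplitude correlation hits its target", {
  d <- gen_kc_dataset(kc_synth_config(n_cells = 500,
                                      amplitude_corr_target = 0.74, seed = 2))
  expect_gte(d$ground_truth$realized_corr_AAprime, 0.64)
  expect_lte(d$ground_truth$realized_corr_AAprime, 0.84)
  # and at a different feasible target
  d2 <- gen_kc_dataset(kc_synth_config(n_cells = 500, overlap_AAprime = 0.6,
                                       amplitude_corr_target = 0.5, seed = 2))
  expect_equal(d2$ground_truth$realized_corr_AAprime, 0.5, tolerance = 0.1)
})

test_that("disjoint A/B codes yield the correlation of disjoint gated vectors", {
  cfg <- small_kc(overlap_B = 0, trial_noise_sd = 0)
  d <- gen_kc_dataset(cfg)
  amp <- d$ground_truth$amplitudes
  # independent oracle: plain arithmetic Pearson on the ground-truth table
  expect_equal(stats::cor(amp[, "A"], amp[, "B"]),
               pearson_oracle(amp[, "A"], amp[, "B"]), tolerance = 1e-12)
  # disjoint responder sets force a negative product-moment correlation
  expect_lt(pearson_oracle(amp[, "A"], amp[, "B"]), 0.1)
  r <- d$ground_truth$responders
  expect_equal(sum(r$responds_A & r$responds_B), 0)
})

test_that("transition trials equal the second odor's pulse response plus the order term", {
  cfg <- small_kc(trial_noise_sd = 0, order_effect_eps = 0)
  d <- gen_kc_dataset(cfg)
  dff <- compute_dff(subtract_background(d$tensor),
                     baseline_window_s = 8, first_onset_s = 8)
  f <- kc_feature_table(dff, d$schedule)
  mean_feat <- function(st) {
    x <- f[f$stimulus == st, ] |>
      dplyr::group_by(cell) |>
      dplyr::summarise(m = mean(feature))
    x$m
  }
  # with eps = 0 the second-pulse feature vector matches the pulse response
  expect_equal(mean_feat("A_to_Aprime"), mean_feat("Aprime"), tolerance = 1e-6)
  expect_equal(mean_feat("Aprime_to_A"), mean_feat("A"), tolerance = 1e-6)

  cfg2 <- small_kc(trial_noise_sd = 0, order_effect_eps = 0.5)
  d2 <- gen_kc_dataset(cfg2)
  gt <- d2$ground_truth
  # planted construction: amp(second) + eps * signed perturbation
  dff2 <- compute_dff(subtract_background(d2$tensor), 8, 8)
  a2 <- response_amplitude(dff2, d2$schedule, epoch = "second",
                           stimuli = "A_to_Aprime")
  a_pulse <- response_amplitude(dff2, d2$schedule, epoch = "first",
                                stimuli = "Aprime")
  per_cell_diff <- tapply(a2$amplitude, a2$cell, mean) -
    tapply(a_pulse$amplitude, a_pulse$cell, mean)
  pert_cells <- which(gt$order_perturbation != 0)
  expect_gt(stats::cor(per_cell_diff[pert_cells],
                       0.5 * gt$order_perturbation[pert_cells]), 0.99)
})

test_that("generators are seed-deterministic and reject degenerate codes", {
  a <- gen_kc_dataset(small_kc())
  b <- gen_kc_dataset(small_kc())
  expect_identical(a$tensor$values, b$tensor$values)
  expect_identical(a$ground_truth$amplitudes, b$ground_truth$amplitudes)
  c_ <- gen_kc_dataset(small_kc(seed = 6))
  expect_false(identical(a$tensor$values, c_$tensor$values))
  expect_error(gen_kc_dataset(small_kc(responder_fraction = 0)), "degenerate")
  expect_error(kc_synth_config(responder_fraction = 1.2), "0, 1")
  expect_error(gen_kc_dataset(small_kc(responder_fraction = 0.05,
                                       amplitude_corr_target = 0.9,
                                       overlap_AAprime = 0.2)), "infeasible")
})
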