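#' End-to-end run configuration
#'
#' Bundles the stage configurations, a global seed, and stage toggles into
#' one serializable object. Per-stage seeds are derived deterministically
#' from the global seed, so a stored config reproduces all outputs
#' bit-identically.
#'
#' @param seed global seed.
#' @param kc a [kc_synth_config()] (or `NULL` to skip the KC stage).
#' @param mbon an [mbon_synth_config()] (or `NULL`).
#' @param arena an [arena_synth_config()] (or `NULL`).
#' @param arena_n_runs arena runs per condition (default 6).
#' @param arena_timeline an [arena_timeline()]; default: 60 s air, a 30 s
#'   odor pulse, then a 60 s choice test.
#' @param loocv_lambda regularization for the odor decoders (default 1).
#' @param loocv_init `"connectome"` or `"ones"` initialization for the
#'   odor decoders (default `"connectome"`).
#' @param decode_window a [response_window()] for decoding features
#'   (`NULL` = odor-on epoch).
#' @param amplitude_window a [response_window()] for amplitude summaries
#'   (default 8 s from onset).
#' @param fit a [fit_settings()].
#' @param stages character subset of `c("kc", "mbon", "arena")`.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1,
                       kc = kc_synth_config(seed = seed),
                       mbon = mbon_synth_config(seed = seed + 1),
                       arena = arena_synth_config(seed = seed + 2),
                       arena_n_runs = 6,
                       arena_timeline = default_arena_timeline(),
                       loocv_lambda = 1, loocv_init = "connectome",
                       decode_window = NULL,
                       amplitude_window = response_window(0, 8),
                       fit = fit_settings(),
                       stages = c("kc", "mbon", "arena")) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @export
default_arena_timeline <- function() {
  arena_timeline(tibble::tibble(
    type = c("air", "pulse", "choice"),
    onset_s = c(0, 60, 90),
    offset_s = c(60, 90, 150)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages: (kc) synthesize a Kenyon-cell dataset,
#' quantify \eqn{\Delta F/F}, measure the similar-odor amplitude
#' correlation and per-odor LOOCV decoding accuracies, and run both
#' pulse-to-transition transfer protocols; (mbon) synthesize pre/post
#' pairing MBON traces and recover depression ratios and transition
#' contrasts; (arena) simulate arena runs and compute performance indices
#' and upwind displacement, with rank-sum tests against unstimulated
#' controls, Holm-corrected within the behavioral family.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tidy CSV tables, a
#'   results JSON and figure PDFs are written there.
#' @param write_plots write figure PDFs when `out_dir` is given
#'   (default TRUE).
#' @return a `recall_run` list with one element per stage plus `stats`,
#'   and a `results` tibble of named scalar outcomes.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, write_plots = TRUE) {
  stopifnot(inherits(config, "run_config"))
  res <- list(config = config)
  scalars <- list()

  if ("kc" %in% config$stages && !is.null(config$kc)) {
    kc <- gen_kc_dataset(config$kc)
    dff <- kc$tensor |> subtract_background() |>
      compute_dff(baseline_window_s = config$kc$baseline_s,
                  first_onset_s = config$kc$baseline_s)
    amp <- response_amplitude(dff, kc$schedule, epoch = "first",
                              window = config$amplitude_window)
    corr <- odor_response_correlation(amp, c("A", "Aprime"))
    feats <- kc_feature_table(dff, kc$schedule, window = config$decode_window)
    pulse_feats <- feats[feats$stimulus %in% c("A", "Aprime", "B"), ]
    counts <- gen_synapse_counts(synapse_count_model(seed = config$seed + 10))
    acc <- loocv_all_odors(pulse_feats, lambda = config$loocv_lambda,
                           init = config$loocv_init, counts = counts,
                           settings = config$fit, seed = config$seed + 11)
    emu <- protocol_mbon_emulation(feats, settings = config$fit)
    trans <- protocol_transition_trained(feats, settings = config$fit)
    mean_amp_A <- amp |>
      dplyr::filter(.data$stimulus == "A") |>
      dplyr::group_by(.data$cell) |>
      dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
    w_corr <- weight_response_correlation(emu$mean_theta, mean_amp_A$amplitude)
    res$kc <- list(data = kc, dff = dff, amplitudes = amp, correlation = corr,
                   accuracies = acc, emulation = emu,
                   transition_trained = trans, weight_corr_A = w_corr)
    scalars <- c(scalars, list(
      corr_A_Aprime = corr$estimate,
      acc_A = acc$accuracy[acc$odor == "A"],
      acc_Aprime = acc$accuracy[acc$odor == "Aprime"],
      acc_B = acc$accuracy[acc$odor == "B"],
      emu_out_A_to_Aprime = emu$summary$mean_output[
        emu$summary$stimulus == "A_to_Aprime"],
      emu_out_Aprime_to_A = emu$summary$mean_output[
        emu$summary$stimulus == "Aprime_to_A"],
      trans_out_A_to_Aprime = trans$summary$mean_output[
        trans$summary$stimulus == "A_to_Aprime"],
      trans_out_Aprime_to_A = trans$summary$mean_output[
        trans$summary$stimulus == "Aprime_to_A"],
      weight_corr_A = w_corr))
  }

  if ("mbon" %in% config$stages && !is.null(config$mbon)) {
    mb <- gen_mbon_dataset(config$mbon)
    prep <- function(t) t |> subtract_background() |>
      compute_dff(baseline_window_s = config$mbon$baseline_s,
                  first_onset_s = config$mbon$baseline_s)
    pre <- prep(mb$pre); post <- prep(mb$post)
    w <- config$amplitude_window
    amp_ratio <- function(stim) {
      a_pre <- response_amplitude(pre, mb$schedule, "first", w, stimuli = stim)
      a_post <- response_amplitude(post, mb$schedule, "first", w, stimuli = stim)
      mean(a_post$amplitude) / mean(a_pre$amplitude)
    }
    ratios <- tibble::tibble(
      stimulus = c("A", "Aprime", "B"),
      post_pre_ratio = vapply(c("A", "Aprime", "B"), amp_ratio, numeric(1)))
    contrast <- transition_contrast(post, mb$schedule) |>
      dplyr::group_by(.data$stimulus) |>
      dplyr::summarise(mean_contrast = mean(.data$contrast), .groups = "drop")
    res$mbon <- list(data = mb, pre = pre, post = post, ratios = ratios,
                     contrast = contrast)
    scalars <- c(scalars, list(
      ratio_A = ratios$post_pre_ratio[ratios$stimulus == "A"],
      ratio_Aprime = ratios$post_pre_ratio[ratios$stimulus == "Aprime"],
      ratio_B = ratios$post_pre_ratio[ratios$stimulus == "B"],
      contrast_A_to_Aprime = contrast$mean_contrast[
        contrast$stimulus == "A_to_Aprime"],
      contrast_Aprime_to_A = contrast$mean_contrast[
        contrast$stimulus == "Aprime_to_A"]))
  }

  if ("arena" %in% config$stages && !is.null(config$arena)) {
    tl <- config$arena_timeline
    n_runs <- config$arena_n_runs
    rate <- config$arena$frame_rate_hz
    run_one <- function(i, cfg) {
      cfg$seed <- cfg$seed + 100 * i
      gen_arena_trajectories(cfg, tl, run_id = i)
    }
    stim_cfg <- config$arena
    null_cfg <- config$arena
    null_cfg$upwind_drift <- 0; null_cfg$quadrant_bias <- 1
    null_cfg$seed <- null_cfg$seed + 5000
    choice <- tl$epochs[tl$epochs$type == "choice", ]
    pulse <- tl$epochs[tl$epochs$type == "pulse", ]
    baseline_frames <- seq_len(max(1, floor(choice$onset_s[1] * rate)))
    summarise_runs <- function(cfg) {
      purrr::map(seq_len(n_runs), function(i) {
        traj <- run_one(i, cfg)
        cts <- quadrant_counts(traj)
        pi <- performance_index_series(cts, tl$paired_quadrants, rate,
                                       baseline_frames = baseline_frames)
        up <- upwind_displacement(traj, onset_s = pulse$onset_s[1],
                                  window_s = pulse$offset_s[1] - pulse$onset_s[1])
        list(traj = traj, pi = pi, upwind = up)
      })
    }
    stim_runs <- summarise_runs(stim_cfg)
    null_runs <- summarise_runs(null_cfg)
    pis <- vapply(stim_runs, function(r) r$pi$pi_scalar, numeric(1))
    pis_null <- vapply(null_runs, function(r) r$pi$pi_scalar, numeric(1))
    ups <- vapply(stim_runs, function(r) r$upwind$summary_mm, numeric(1))
    ups_null <- vapply(null_runs, function(r) r$upwind$summary_mm, numeric(1))
    stats_tbl <- dplyr::bind_rows(
      independent_rank_sum(pis, pis_null, family = "behavior"),
      independent_rank_sum(ups, ups_null, family = "behavior")) |>
      adjust_families()
    stats_tbl$comparison <- c("PI stim vs null", "upwind stim vs null")
    res$arena <- list(stim = stim_runs, control = null_runs,
                      pi = tibble::tibble(condition = rep(c("stim", "null"),
                                                          each = n_runs),
                                          run = rep(seq_len(n_runs), 2),
                                          pi = c(pis, pis_null)),
                      upwind = tibble::tibble(condition = rep(c("stim", "null"),
                                                              each = n_runs),
                                              run = rep(seq_len(n_runs), 2),
                                              displacement_mm = c(ups, ups_null)),
                      stats = stats_tbl)
    scalars <- c(scalars, list(
      mean_pi = mean(pis), mean_pi_null = mean(pis_null),
      mean_upwind_mm = mean(ups), mean_upwind_null_mm = mean(ups_null)))
  }

  res$results <- tibble::tibble(metric = names(scalars),
                                value = unlist(scalars, use.names = FALSE))
  class(res) <- "recall_run"
  if (!is.null(out_dir)) write_run(res, out_dir, write_plots = write_plots)
  res
}

#' @export
print.recall_run <- function(x, ...) {
  cat("<recall_run> stages:", paste(intersect(c("kc", "mbon", "arena"),
                                              names(x)), collapse = ", "), "\n")
  print(x$results, n = Inf)
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits `results.json` (named scalar outcomes), tidy CSV tables per stage
#' and, optionally, figure PDFs.
#'
#' @param run a `recall_run` from [run_all()].
#' @param out_dir output directory (created if needed).
#' @param write_plots also write figure PDFs.
#' @return `out_dir` invisibly.
#' @export
write_run <- function(run, out_dir, write_plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vals <- as.list(stats::setNames(run$results$value, run$results$metric))
  vals$seed <- run$config$seed
  jsonlite::write_json(vals, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$kc)) {
    readr::write_csv(run$kc$accuracies, file.path(out_dir, "kc_accuracies.csv"))
    readr::write_csv(run$kc$emulation$outputs,
                     file.path(out_dir, "transfer_pulse_trained.csv"))
    readr::write_csv(run$kc$transition_trained$outputs,
                     file.path(out_dir, "transfer_transition_trained.csv"))
  }
  if (!is.null(run$mbon)) {
    readr::write_csv(run$mbon$ratios, file.path(out_dir, "mbon_ratios.csv"))
    readr::write_csv(run$mbon$contrast, file.path(out_dir, "mbon_contrast.csv"))
  }
  if (!is.null(run$arena)) {
    readr::write_csv(run$arena$pi, file.path(out_dir, "arena_pi.csv"))
    readr::write_csv(run$arena$upwind, file.path(out_dir, "arena_upwind.csv"))
    readr::write_csv(run$arena$stats, file.path(out_dir, "arena_stats.csv"))
  }
  if (write_plots) {
    pdf_quiet <- function(name, p, w = 7, h = 5)
      suppressMessages(ggplot2::ggsave(file.path(out_dir, name), p,
                                       width = w, height = h))
    if (!is.null(run$kc)) {
      hm <- trial_average_sorted(run$kc$dff, run$kc$data$schedule, "A")
      pdf_quiet("kc_heatmap.pdf", autoplot(hm), 9, 6)
      pdf_quiet("transfer_outputs.pdf", autoplot(run$kc$transition_trained))
    }
    if (!is.null(run$mbon))
      pdf_quiet("mbon_traces.pdf", plot_trace_summary(run$mbon$post))
    if (!is.null(run$arena)) {
      pdf_quiet("arena_pi.pdf", autoplot(run$arena$stim[[1]]$pi,
                                         frame_rate_hz = run$config$arena$frame_rate_hz))
      pdf_quiet("arena_upwind.pdf", plot_upwind(run$arena$stim[[1]]$upwind))
    }
  }
  invisible(out_dir)
}
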