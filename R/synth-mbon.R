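#' Configuration for the synthetic MBON dataset
#'
#' Emulates learning-induced depression of a mushroom-body output neuron:
#' after pairing odor `A` with reinforcement, isolated-pulse responses to
#' both `A` and the similar odor `Aprime` are depressed (multiplicative
#' factors), while responses to the dissimilar odor `B` are unchanged. At
#' odor transitions the depression is order-asymmetric: when `Aprime`
#' follows `A` its response recovers toward the pre-pairing level by
#' `transition_recovery`, whereas `A` arriving second stays depressed.
#'
#' @param depression_factor_A post/pre response scale for isolated `A`
#'   pulses, in `[0, 1]` (default 0.3).
#' @param depression_factor_Aprime same for isolated `Aprime` pulses
#'   (default 0.3).
#' @param transition_recovery scale of the `Aprime`-second response in an
#'   `A -> Aprime` transition relative to its pre-pairing level, in
#'   `[0, 1]` (default 1: full recovery).
#' @param amp_A,amp_Aprime,amp_B pre-pairing response amplitudes (dF/F;
#'   all must be positive).
#' @param tau_rise_s,tau_decay_s response kinetics, seconds.
#' @param noise_sd per-frame additive Gaussian noise on the dF/F scale.
#' @param frame_rate_hz,pulse_s,baseline_s,tail_s trial timing (seconds, Hz).
#' @param n_trials_per_stim repeats per stimulus (default 8).
#' @param f0_base,background raw-fluorescence baseline and field background
#'   (a.u.).
#' @param seed RNG seed.
#' @return an `mbon_synth_config` list.
#' @export
mbon_synth_config <- function(depression_factor_A = 0.3,
                              depression_factor_Aprime = 0.3,
                              transition_recovery = 1.0,
                              amp_A = 1.0, amp_Aprime = 0.9, amp_B = 1.1,
                              tau_rise_s = 0.3, tau_decay_s = 1.5,
                              noise_sd = 0.05, frame_rate_hz = 10,
                              pulse_s = 5, baseline_s = 8, tail_s = 5,
                              n_trials_per_stim = 8,
                              f0_base = 100, background = 20, seed = 1) {
  cfg <- as.list(environment())
  scales <- c(depression_factor_A, depression_factor_Aprime, transition_recovery)
  if (any(scales < 0 | scales > 1))
    stop("depression/recovery factors must lie in [0, 1]", call. = FALSE)
  if (any(c(amp_A, amp_Aprime, amp_B) <= 0))
    stop("pre-pairing response amplitudes must be positive", call. = FALSE)
  structure(cfg, class = "mbon_synth_config")
}

#' Build the six-stimulus MBON test schedule
#'
#' Three single pulses (`A`, `Aprime`, `B`), both similar-odor transitions
#' (`A_to_Aprime`, `Aprime_to_A`), and a `B`-containing control transition
#' (`B_to_Aprime`), each repeated `n_trials_per_stim` times.
#'
#' @param config an [mbon_synth_config()].
#' @return a [stim_schedule()].
#' @export
mbon_schedule <- function(config) {
  c_ <- config
  stims <- c("A", "Aprime", "B", "A_to_Aprime", "Aprime_to_A", "B_to_Aprime")
  odor_of <- list(A = "A", Aprime = "Aprime", B = "B",
                  A_to_Aprime = c("A", "Aprime"), Aprime_to_A = c("Aprime", "A"),
                  B_to_Aprime = c("B", "Aprime"))
  trial_labels <- rep(stims, each = c_$n_trials_per_stim)
  rows <- purrr::imap_dfr(trial_labels, function(st, tr) {
    od <- odor_of[[st]]
    ons <- c_$baseline_s + (seq_along(od) - 1) * c_$pulse_s
    tibble::tibble(trial = tr, stimulus = st, epoch = seq_along(od),
                   odor = od, onset_s = ons, offset_s = ons + c_$pulse_s)
  })
  stim_schedule(rows$trial, rows$stimulus, rows$epoch, rows$odor,
                rows$onset_s, rows$offset_s)
}

mbon_required_stims <- c("A", "Aprime", "B", "A_to_Aprime", "Aprime_to_A")

#' Generate a pre/post pairing MBON dataset
#'
#' Returns raw-fluorescence single-ROI trial tensors for the schedule's
#' stimuli before and after pairing. Post-pairing amplitudes are the
#' pre-pairing amplitudes scaled per stimulus: isolated `A` and `Aprime`
#' pulses by their depression factors, `B` unchanged, the second pulse of
#' `A -> Aprime` by `transition_recovery`, the second pulse of
#' `Aprime -> A` (and any other second `A`) by `depression_factor_A`, and
#' a second `Aprime` after `B` by `depression_factor_Aprime` (recovery is
#' specific to the `A -> Aprime` order). First-pulse responses in
#' transitions follow their isolated-pulse scaling.
#'
#' @param config an [mbon_synth_config()].
#' @param schedule a [stim_schedule()] containing at least the three single
#'   pulses, both similar-odor transition orders, and a `B`-containing
#'   control; defaults to [mbon_schedule()].
#' @return list with `pre` and `post` [trial_tensor()]s (kind `"raw"`),
#'   the `schedule`, and `ground_truth` (the per-epoch amplitude scalings).
#' @export
gen_mbon_dataset <- function(config, schedule = mbon_schedule(config)) {
  stopifnot(inherits(config, "mbon_synth_config"))
  c_ <- config
  missing <- setdiff(mbon_required_stims, unique(schedule$stimulus))
  if (length(missing) > 0)
    stop("schedule missing stimulus types: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!any(grepl("^B_to_|_to_B$", unique(schedule$stimulus))))
    stop("schedule missing a B-containing control transition", call. = FALSE)

  pre_amp <- c(A = c_$amp_A, Aprime = c_$amp_Aprime, B = c_$amp_B)
  post_scale <- function(odor, epoch, stimulus) {
    if (odor == "B") return(1)
    if (epoch == 2 && stimulus == "A_to_Aprime") return(c_$transition_recovery)
    if (odor == "A") return(c_$depression_factor_A)
    c_$depression_factor_Aprime
  }

  trials <- unique(schedule$trial)
  trial_labels <- vapply(trials, function(tr)
    schedule$stimulus[schedule$trial == tr][1], character(1))
  max_off <- max(schedule$offset_s)
  nf <- ceiling((max_off + c_$tail_s) * c_$frame_rate_hz)
  tt <- frame_times_vec(nf, c_$frame_rate_hz)

  withr::with_seed(c_$seed, {
    build <- function(phase) {
      vals <- array(0, dim = c(1, nf, length(trials)))
      for (i in seq_along(trials)) {
        ep <- schedule[schedule$trial == trials[i], ]
        dff <- numeric(nf)
        for (k in seq_len(nrow(ep))) {
          a <- pre_amp[[ep$odor[k]]]
          if (phase == "post")
            a <- a * post_scale(ep$odor[k], ep$epoch[k], ep$stimulus[k])
          cut <- if (k < nrow(ep)) ep$onset_s[k + 1] - ep$onset_s[k] else Inf
          dff <- dff + a * response_kernel(tt - ep$onset_s[k],
                                          ep$offset_s[k] - ep$onset_s[k],
                                          c_$tau_rise_s, c_$tau_decay_s,
                                          cut_at = cut)
        }
        if (c_$noise_sd > 0) dff <- dff + stats::rnorm(nf, sd = c_$noise_sd)
        vals[1, , i] <- c_$background + c_$f0_base * (1 + dff)
      }
      trial_tensor(vals, c_$frame_rate_hz, kind = "raw",
                   trial_labels = trial_labels, background = c_$background)
    }
    pre <- build("pre")
    post <- build("post")
    gt <- schedule |>
      dplyr::mutate(pre_amplitude = unname(pre_amp[.data$odor]),
                    post_scale = purrr::pmap_dbl(
                      list(.data$odor, .data$epoch, .data$stimulus), post_scale))
    list(pre = pre, post = post, schedule = schedule,
         ground_truth = list(epoch_amplitudes = gt, config = c_))
  })
}
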