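#' Configuration for the synthetic Kenyon-cell dataset
#'
#' Parameters describing a sparse odor code over three odors: a paired odor
#' `A`, a chemically similar unpaired odor `Aprime`, and a dissimilar odor
#' `B`. The per-cell amplitude correlation between `A` and `Aprime` over
#' the whole population is controlled analytically: within the shared
#' responder set, latent amplitudes are drawn with the correlation that
#' makes the population-level Pearson r equal `amplitude_corr_target`
#' (given the responder fraction and overlap; an error is raised when the
#' combination is infeasible).
#'
#' @param n_cells number of Kenyon cells.
#' @param responder_fraction probability a cell responds to a given odor
#'   (sparse coding; default 0.1).
#' @param overlap_AAprime fraction of A-responders shared with Aprime
#'   (default 0.8, a strongly overlapping similar-odor pair).
#' @param overlap_B fraction of A-responders shared with B (default 0.05,
#'   near-disjoint).
#' @param amplitude_corr_target target population Pearson r between per-cell
#'   A and Aprime amplitudes (default 0.74).
#' @param mean_amplitude,amplitude_sd mean and SD of responder amplitudes
#'   (dF/F units; defaults 1.0 and 0.3).
#' @param trial_noise_sd per-frame additive Gaussian noise on the dF/F
#'   scale (default 0.05).
#' @param n_trials_per_stim trials per stimulus (default 8).
#' @param frame_rate_hz acquisition rate (default 10).
#' @param pulse_s odor pulse duration, seconds (default 5).
#' @param gap_s gap between pulses in a transition (default 0: immediate
#'   handoff).
#' @param baseline_s pre-odor baseline, seconds (default 8).
#' @param tail_s post-stimulus recording, seconds (default 5).
#' @param order_effect_eps scale of the order-signed perturbation added to
#'   second-pulse responses in transitions (default 0.15).
#' @param order_effect_fraction fraction of cells carrying the perturbation
#'   (default 0.2).
#' @param tau_rise_s,tau_decay_s response kinetics, seconds.
#' @param f0_base,background raw-fluorescence baseline and field background
#'   (a.u.) used to wrap dF/F into realistic raw traces.
#' @param seed RNG seed.
#' @return a `kc_synth_config` list.
#' @export
kc_synth_config <- function(n_cells = 500, responder_fraction = 0.1,
                            overlap_AAprime = 0.8, overlap_B = 0.05,
                            amplitude_corr_target = 0.74,
                            mean_amplitude = 1.0, amplitude_sd = 0.3,
                            trial_noise_sd = 0.05, n_trials_per_stim = 8,
                            frame_rate_hz = 10, pulse_s = 5, gap_s = 0,
                            baseline_s = 8, tail_s = 5,
                            order_effect_eps = 0.15,
                            order_effect_fraction = 0.2,
                            tau_rise_s = 0.3, tau_decay_s = 1.0,
                            f0_base = 100, background = 20, seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(responder_fraction, overlap_AAprime, overlap_B)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions/probabilities must lie in [0, 1]", call. = FALSE)
  if (n_trials_per_stim < 2) stop("need n_trials_per_stim >= 2", call. = FALSE)
  if (any(c(pulse_s, baseline_s, frame_rate_hz) <= 0))
    stop("durations and frame rate must be positive", call. = FALSE)
  structure(cfg, class = "kc_synth_config")
}

# Solve the latent within-shared-set correlation rho so that the
# population-level Pearson r between indicator-gated amplitude vectors hits
# the target. With responder probability p, co-responder probability
# q = overlap * p, responder amplitude ~ N(mu, s^2):
#   Var(a)  = p s^2 + mu^2 p (1 - p)
#   Cov     = q (mu^2 + s^2 rho) - p^2 mu^2
solve_latent_rho <- function(target, p, overlap, mu, s) {
  q <- overlap * p
  if (q <= 0) {
    if (abs(target) > 0.2) stop("amplitude_corr_target unreachable with zero overlap",
                                call. = FALSE)
    return(0)
  }
  v <- p * s^2 + mu^2 * p * (1 - p)
  rho <- (target * v - q * mu^2 + p^2 * mu^2) / (q * s^2)
  if (rho > 1 + 1e-9 || rho < -1 - 1e-9)
    stop(sprintf(paste0("amplitude_corr_target %.2f infeasible for ",
                        "responder_fraction %.2f and overlap %.2f"),
                 target, p, overlap), call. = FALSE)
  min(1, max(-1, rho))
}

# double-exponential rise/decay; `cut_at` zeroes the response from that time
# on (used for the first pulse of a transition, where the odor handoff
# terminates the response so that the second-pulse window reflects the
# second odor alone)
response_kernel <- function(t_rel, dur, tau_r, tau_d, cut_at = Inf) {
  y <- numeric(length(t_rel))
  on <- t_rel >= 0 & t_rel < dur
  y[on] <- 1 - exp(-t_rel[on] / tau_r)
  peak <- 1 - exp(-dur / tau_r)
  post <- t_rel >= dur
  y[post] <- peak * exp(-(t_rel[post] - dur) / tau_d)
  y[t_rel >= cut_at] <- 0
  y
}

#' Generate a synthetic Kenyon-cell dataset
#'
#' Builds raw-fluorescence trial tensors for three single odor pulses
#' (`A`, `Aprime`, `B`) and both odor transitions (`A_to_Aprime`,
#' `Aprime_to_A`), with a fixed responder set and per-cell mean amplitude
#' for each odor, per-frame Gaussian noise, and second-pulse transition
#' responses equal to the second odor's single-pulse response plus an
#' order-signed perturbation of scale `order_effect_eps` on a random cell
#' subset. The latent parameters used are returned for recovery tests.
#'
#' @param config a [kc_synth_config()].
#' @return list with `tensor` (raw [trial_tensor()]), `schedule`
#'   ([stim_schedule()]), and `ground_truth` (list with the responder
#'   table, amplitude matrix, perturbation vector, and realized A-Aprime
#'   amplitude correlation).
#' @export
gen_kc_dataset <- function(config) {
  stopifnot(inherits(config, "kc_synth_config"))
  c_ <- config
  withr::with_seed(c_$seed, {
    n <- c_$n_cells
    n_resp <- round(c_$responder_fraction * n)
    if (n_resp == 0) stop("degenerate code: responder set empty", call. = FALSE)
    if (round(c_$overlap_AAprime * n_resp) > n_resp ||
        n_resp + n_resp - round(c_$overlap_AAprime * n_resp) > n)
      stop("overlap fractions inconsistent with responder_fraction", call. = FALSE)

    set_A <- sample.int(n, n_resp)
    n_shared <- round(c_$overlap_AAprime * n_resp)
    shared_Ap <- sample(set_A, n_shared)
    pool <- setdiff(seq_len(n), set_A)
    set_Ap <- c(shared_Ap, sample(pool, n_resp - n_shared))
    n_shared_B <- round(c_$overlap_B * n_resp)
    shared_B <- if (n_shared_B > 0) sample(set_A, n_shared_B) else integer(0)
    pool_B <- setdiff(seq_len(n), union(set_A, shared_B))
    set_B <- c(shared_B, sample(pool_B, min(n_resp - n_shared_B, length(pool_B))))
    if (length(set_Ap) == 0 || length(set_B) == 0)
      stop("degenerate code: responder set empty", call. = FALSE)

    mu <- c_$mean_amplitude; s <- c_$amplitude_sd
    rho <- solve_latent_rho(c_$amplitude_corr_target, c_$responder_fraction,
                            c_$overlap_AAprime, mu, s)
    amp <- matrix(0, n, 3, dimnames = list(NULL, c("A", "Aprime", "B")))
    xA <- stats::rnorm(length(set_A))
    amp[set_A, "A"] <- mu + s * xA
    yAp <- stats::rnorm(length(set_Ap))
    shared_pos <- match(shared_Ap, set_A)        # latent coupling on shared cells
    shared_in_Ap <- match(shared_Ap, set_Ap)
    yAp[shared_in_Ap] <- rho * xA[shared_pos] +
      sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(shared_Ap))
    amp[set_Ap, "Aprime"] <- mu + s * yAp
    amp[set_B, "B"] <- mu + s * stats::rnorm(length(set_B))

    realized_r <- stats::cor(amp[, "A"], amp[, "Aprime"])

    # order-signed perturbation: +d for A_to_Aprime, -d for Aprime_to_A
    n_pert <- max(1L, round(c_$order_effect_fraction * n))
    pert_cells <- sample.int(n, n_pert)
    d <- numeric(n)
    d[pert_cells] <- stats::rnorm(n_pert, mean = 0, sd = mu)

    stims <- c("A", "Aprime", "B", "A_to_Aprime", "Aprime_to_A")
    n_rep <- c_$n_trials_per_stim
    trial_labels <- rep(stims, each = n_rep)
    m <- length(trial_labels)
    trial_len_s <- c_$baseline_s + 2 * c_$pulse_s + c_$gap_s + c_$tail_s
    nf <- ceiling(trial_len_s * c_$frame_rate_hz)
    tt <- frame_times_vec(nf, c_$frame_rate_hz)

    pulse_amp <- function(stim) switch(stim,
      A = list(ons = c_$baseline_s, amps = amp[, "A", drop = FALSE]),
      Aprime = list(ons = c_$baseline_s, amps = amp[, "Aprime", drop = FALSE]),
      B = list(ons = c_$baseline_s, amps = amp[, "B", drop = FALSE]),
      A_to_Aprime = list(
        ons = c(c_$baseline_s, c_$baseline_s + c_$pulse_s + c_$gap_s),
        amps = cbind(amp[, "A"], amp[, "Aprime"] + c_$order_effect_eps * d)),
      Aprime_to_A = list(
        ons = c(c_$baseline_s, c_$baseline_s + c_$pulse_s + c_$gap_s),
        amps = cbind(amp[, "Aprime"], amp[, "A"] - c_$order_effect_eps * d))
    )

    vals <- array(0, dim = c(n, nf, m))
    sched <- vector("list", m)
    odor_of <- list(A = "A", Aprime = "Aprime", B = "B",
                    A_to_Aprime = c("A", "Aprime"), Aprime_to_A = c("Aprime", "A"))
    for (tr in seq_len(m)) {
      st <- trial_labels[tr]
      pa <- pulse_amp(st)
      dff <- matrix(0, n, nf)
      n_ep <- length(pa$ons)
      for (k in seq_len(n_ep)) {
        cut <- if (k < n_ep) pa$ons[k + 1] - pa$ons[k] else Inf
        kern <- response_kernel(tt - pa$ons[k], c_$pulse_s,
                                c_$tau_rise_s, c_$tau_decay_s, cut_at = cut)
        dff <- dff + pa$amps[, k] %o% kern
      }
      if (c_$trial_noise_sd > 0)
        dff <- dff + matrix(stats::rnorm(n * nf, sd = c_$trial_noise_sd), n, nf)
      vals[, , tr] <- c_$background + c_$f0_base * (1 + dff)
      od <- odor_of[[st]]
      sched[[tr]] <- tibble::tibble(
        trial = tr, stimulus = st, epoch = seq_along(od), odor = od,
        onset_s = pa$ons, offset_s = pa$ons + c_$pulse_s)
    }
    schedule <- do.call(rbind, sched)
    schedule <- stim_schedule(schedule$trial, schedule$stimulus, schedule$epoch,
                              schedule$odor, schedule$onset_s, schedule$offset_s)
    tensor <- trial_tensor(vals, c_$frame_rate_hz, kind = "raw",
                           trial_labels = trial_labels,
                           background = c_$background)
    responders <- tibble::tibble(
      cell = seq_len(n),
      responds_A = seq_len(n) %in% set_A,
      responds_Aprime = seq_len(n) %in% set_Ap,
      responds_B = seq_len(n) %in% set_B)
    list(tensor = tensor, schedule = schedule,
         ground_truth = list(
           responders = responders, amplitudes = amp,
           order_perturbation = d, latent_rho = rho,
           realized_corr_AAprime = realized_r, config = c_))
  })
}

frame_times_vec <- function(nf, rate) (seq_len(nf) - 1) / rate
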