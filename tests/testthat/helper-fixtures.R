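# Small builders shared across tests. All fixtures are generated in code.

# a raw tensor with constant fluorescence, 1 cell unless asked otherwise
const_tensor <- function(value, n_cells = 1, n_frames = 200, n_trials = 1,
                         rate = 10, background = 0, labels = NULL) {
  trial_tensor(array(value, dim = c(n_cells, n_frames, n_trials)),
               frame_rate_hz = rate, kind = "raw",
               trial_labels = labels, background = background)
}

# single-pulse schedule: one odor epoch per trial
pulse_schedule <- function(n_trials, stimulus = "A", odor = "A",
                           onset = 8, dur = 5) {
  stim_schedule(trial = seq_len(n_trials), stimulus = stimulus,
                epoch = 1L, odor = odor,
                onset_s = onset, offset_s = onset + dur)
}

# a dff tensor built directly from given per-trial traces (matrix frame x trial
# or a list of cell x frame matrices per trial)
dff_tensor_from <- function(traces, rate = 10, labels = NULL) {
  if (is.matrix(traces)) {
    arr <- array(0, dim = c(1, nrow(traces), ncol(traces)))
    for (i in seq_len(ncol(traces))) arr[1, , i] <- traces[, i]
  } else {
    nc <- nrow(traces[[1]]); nf <- ncol(traces[[1]])
    arr <- array(0, dim = c(nc, nf, length(traces)))
    for (i in seq_along(traces)) arr[, , i] <- traces[[i]]
  }
  t <- trial_tensor(arr, frame_rate_hz = rate, kind = "raw",
                    trial_labels = labels)
  t$kind <- "dff"   # bypass the raw pipeline for direct-trace fixtures
  t
}

# independent Pearson correlation oracle (plain arithmetic, no stats::cor)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# feature table with block-structured odor codes: each stimulus activates a
# disjoint (or specified) set of cells at `amp`, plus Gaussian noise
block_features <- function(stim_cells, n_cells, n_trials = 8, amp = 1,
                           noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    tr <- 0L
    for (st in names(stim_cells)) {
      for (k in seq_len(n_trials)) {
        tr <- tr + 1L
        f <- rnorm(n_cells, sd = noise_sd)
        f[stim_cells[[st]]] <- f[stim_cells[[st]]] + amp
        rows[[tr]] <- tibble::tibble(trial = tr, stimulus = st,
                                     cell = seq_len(n_cells), feature = f)
      }
    }
    dplyr::bind_rows(rows)
  })
}
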