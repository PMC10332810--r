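#' MBON-emulation transfer protocol (pulse-trained)
#'
#' Trains logistic decoders to emulate a depressed MBON: model outputs are
#' pushed low for the paired odor `A` and the similar odor `Aprime` and
#' high for the dissimilar odor `B`, using isolated-pulse trials only
#' (targets A = 0, Aprime = 0, B = 1; weights initialized at 1; no
#' regularization). Each leave-one-out fold over the pulse trials fits a
#' model and evaluates it on its held-out pulse trial and on every
#' transition trial, yielding a distribution of outputs per stimulus. If
#' transition responses simply equal the second odor's pulse response, both
#' transition orders inherit the low outputs of `A` and `Aprime`.
#'
#' @param features feature table (`trial`, `stimulus`, `cell`, `feature`)
#'   containing pulse stimuli `A`, `Aprime`, `B` and transition stimuli
#'   `A_to_Aprime`, `Aprime_to_A` (transition features from the
#'   second-pulse window, as built by [kc_feature_table()]).
#' @param lambda regularization constant (default 0, the transfer-protocol
#'   setting).
#' @param settings a [fit_settings()].
#' @param threshold decision threshold (default 0.5).
#' @return an `mbon_emulation` list: `outputs` (tibble `stimulus`, `fold`,
#'   `trial`, `output`, `held_out`), `summary` (tibble `stimulus`,
#'   `mean_output`, `sem_output`), `mean_theta` (fold-averaged weights),
#'   `models` (list of fold models), `protocol`.
#' @export
protocol_mbon_emulation <- function(features, lambda = 0,
                                    settings = fit_settings(),
                                    threshold = 0.5) {
  run_transfer_protocol(features, include_transitions_in_training = FALSE,
                        lambda = lambda, settings = settings,
                        threshold = threshold, protocol = "pulse_trained")
}

#' Transition-trained transfer protocol
#'
#' Re-trains the MBON-emulation models with the added requirement that
#' they respond differentially to the two transition orders: the training
#' set is the pulse trials (targets A = 0, Aprime = 0, B = 1) plus the
#' transition trials (targets Aprime_to_A = 0, A_to_Aprime = 1). Each
#' leave-one-out fold over the full training set returns the output for
#' its held-out trial. Separating the two orders is only possible when
#' transitions carry order information beyond the identity of the second
#' odor.
#'
#' @inheritParams protocol_mbon_emulation
#' @return an `mbon_emulation` list (see [protocol_mbon_emulation()]).
#' @export
protocol_transition_trained <- function(features, lambda = 0,
                                        settings = fit_settings(),
                                        threshold = 0.5) {
  run_transfer_protocol(features, include_transitions_in_training = TRUE,
                        lambda = lambda, settings = settings,
                        threshold = threshold, protocol = "transition_trained")
}

protocol_targets <- c(A = 0, Aprime = 0, B = 1,
                      Aprime_to_A = 0, A_to_Aprime = 1)

run_transfer_protocol <- function(features, include_transitions_in_training,
                                  lambda, settings, threshold, protocol) {
  pulse_stims <- c("A", "Aprime", "B")
  trans_stims <- c("A_to_Aprime", "Aprime_to_A")
  have <- unique(features$stimulus)
  missing <- setdiff(c(pulse_stims, trans_stims), have)
  if (length(missing) > 0)
    stop("missing stimulus classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fm <- features_to_matrix(features)
  is_pulse <- fm$stimulus %in% pulse_stims
  train_pool <- if (include_transitions_in_training) seq_along(fm$stimulus) else
    which(is_pulse)
  y_all <- unname(protocol_targets[fm$stimulus])
  theta0 <- init_weights_ones(ncol(fm$X))

  models <- vector("list", length(train_pool))
  rows <- vector("list", length(train_pool))
  for (k in seq_along(train_pool)) {
    i <- train_pool[k]
    tr_idx <- setdiff(train_pool, i)
    mod <- fit_decoder(fm$X[tr_idx, , drop = FALSE], y_all[tr_idx],
                       theta0 = theta0, lambda = lambda, settings = settings,
                       threshold = threshold, init_scheme = "ones")
    models[[k]] <- mod
    eval_idx <- if (include_transitions_in_training) i else
      c(i, which(!is_pulse))
    h <- decoder_predict(mod, fm$X[eval_idx, , drop = FALSE])
    rows[[k]] <- tibble::tibble(stimulus = fm$stimulus[eval_idx],
                                fold = k, trial = fm$trial[eval_idx],
                                output = h, held_out = eval_idx == i)
  }
  outputs <- dplyr::bind_rows(rows)
  summary <- outputs |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(mean_output = mean(.data$output),
                     sem_output = sem(.data$output), .groups = "drop")
  mean_theta <- Reduce(`+`, lapply(models, `[[`, "theta")) / length(models)
  structure(list(outputs = outputs, summary = summary,
                 mean_theta = mean_theta, models = models,
                 protocol = protocol, threshold = threshold),
            class = "mbon_emulation")
}

#' @export
print.mbon_emulation <- function(x, ...) {
  cat(sprintf("<mbon_emulation> %s, %d folds\n", x$protocol, length(x$models)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s mean output %.3f\n", s$stimulus[i], s$mean_output[i]))
  invisible(x)
}

#' Standard error of the mean
#'
#' `sd(x) / sqrt(n)`, the mean +/- SEM convention used for trace and
#' summary plots.
#'
#' @param x numeric vector.
#' @return scalar SEM.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))
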