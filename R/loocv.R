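#' Build a per-trial feature table from a dF/F tensor
#'
#' Features for decoding are per-cell mean \eqn{\Delta F/F} over a response
#' window. For single-pulse trials the window is anchored at the odor
#' onset; for transition trials it is anchored at the second pulse onset
#' (the transition amplitude convention), so a transition trial's feature
#' vector describes the response to the odor the fly has just entered.
#'
#' @param t a dF/F [trial_tensor()] (unfiltered).
#' @param schedule a [stim_schedule()].
#' @param window a [response_window()]; `NULL` = full odor-on epoch.
#' @param fly optional fly id attached to every row.
#' @return tibble with columns (`fly`,) `trial`, `stimulus`, `cell`,
#'   `feature`.
#' @export
kc_feature_table <- function(t, schedule, window = NULL, fly = NULL) {
  check_quantifiable(t)
  amp <- response_amplitude(t, schedule, epoch = "last", window = window)
  out <- amp |>
    dplyr::transmute(trial = .data$trial, stimulus = .data$stimulus,
                     cell = .data$cell, feature = .data$amplitude)
  if (!is.null(fly)) out <- dplyr::mutate(out, fly = fly, .before = 1)
  out
}

features_to_matrix <- function(features) {
  wide <- features |>
    dplyr::select("trial", "stimulus", "cell", "feature") |>
    dplyr::arrange(.data$trial, .data$cell) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "feature")
  X <- as.matrix(wide[, -(1:2)])
  list(X = X, trial = wide$trial, stimulus = wide$stimulus)
}

#' Leave-one-out cross-validated odor decoding accuracy
#'
#' Fits one-vs-rest logistic decoders for a target odor: trials of that
#' odor are labelled 1, all other trials 0. Each fold holds out exactly one
#' trial and fits on all remaining trials (all classes); a fold whose
#' training set lost a class is skipped with a warning. The reported
#' per-odor accuracy is the fraction of held-out target-odor trials with
#' prediction at or above the threshold (hit rate); `mode = "balanced"`
#' additionally scores held-out non-target trials as correct when below
#' threshold and reports overall accuracy.
#'
#' @param features feature table (`trial`, `stimulus`, `cell`, `feature`;
#'   optionally `fly`, in which case decoders are fitted per fly and a
#'   per-fly accuracy table is returned).
#' @param odor target stimulus id.
#' @param lambda regularization constant (default 1).
#' @param init `"ones"` or `"connectome"`.
#' @param counts synapse counts for `init = "connectome"`.
#' @param settings a [fit_settings()].
#' @param threshold decision threshold (default 0.5; ties positive).
#' @param mode `"hit"` (target-odor hit rate) or `"balanced"`.
#' @param seed seed for connectome-sampled initial weights.
#' @return list with `accuracy` (scalar, or tibble per fly), and `folds`:
#'   tibble `fly` (if present), `trial`, `stimulus`, `label`, `output`,
#'   `predicted`, `correct`.
#' @export
loocv_odor_accuracy <- function(features, odor, lambda = 1,
                                init = c("ones", "connectome"), counts = NULL,
                                settings = fit_settings(), threshold = 0.5,
                                mode = c("hit", "balanced"), seed = 1) {
  init <- match.arg(init)
  mode <- match.arg(mode)
  if ("fly" %in% names(features)) {
    flies <- unique(features$fly)
    res <- purrr::map(flies, function(f) {
      loocv_odor_accuracy(dplyr::select(features[features$fly == f, ], -"fly"),
                          odor, lambda, init, counts, settings, threshold,
                          mode, seed)
    })
    folds <- purrr::map2_dfr(res, flies, ~ dplyr::mutate(.x$folds, fly = .y, .before = 1))
    acc <- tibble::tibble(fly = flies,
                          accuracy = vapply(res, `[[`, numeric(1), "accuracy"))
    return(list(accuracy = acc, folds = folds))
  }
  fm <- features_to_matrix(features)
  y <- as.integer(fm$stimulus == odor)
  if (sum(y) < 2) stop("need at least 2 trials of the target odor", call. = FALSE)
  if (sum(1 - y) < 1) stop("need at least 1 trial of another stimulus", call. = FALSE)
  m <- nrow(fm$X)
  theta0 <- switch(init,
    ones = init_weights_ones(ncol(fm$X)),
    connectome = {
      if (is.null(counts)) stop("`counts` required for connectome init", call. = FALSE)
      init_weights_connectome(counts, ncol(fm$X), seed = seed)
    })
  folds <- purrr::map_dfr(seq_len(m), function(i) {
    y_train <- y[-i]
    if (length(unique(y_train)) < 2) {
      warning("fold ", i, " skipped: a class is absent from its training set",
              call. = FALSE)
      return(tibble::tibble(trial = fm$trial[i], stimulus = fm$stimulus[i],
                            label = y[i], output = NA_real_,
                            predicted = NA_integer_, correct = NA))
    }
    mod <- fit_decoder(fm$X[-i, , drop = FALSE], y_train, theta0 = theta0,
                       lambda = lambda, settings = settings,
                       threshold = threshold, init_scheme = init)
    h <- decoder_predict(mod, fm$X[i, , drop = FALSE])
    pred <- as.integer(h >= threshold)
    tibble::tibble(trial = fm$trial[i], stimulus = fm$stimulus[i],
                   label = y[i], output = h, predicted = pred,
                   correct = pred == y[i])
  })
  evaluated <- folds[!is.na(folds$correct), ]
  acc <- if (mode == "hit") {
    mean(evaluated$correct[evaluated$label == 1])
  } else {
    mean(evaluated$correct)
  }
  list(accuracy = acc, folds = folds)
}

#' LOOCV accuracies for every odor in a dataset
#'
#' Convenience wrapper running [loocv_odor_accuracy()] for each listed
#' stimulus (by default the three single-pulse odors).
#'
#' @inheritParams loocv_odor_accuracy
#' @param odors stimulus ids to decode (default `c("A", "Aprime", "B")`).
#' @return tibble with columns `odor`, `accuracy`, `n_folds`.
#' @export
loocv_all_odors <- function(features, odors = c("A", "Aprime", "B"),
                            lambda = 1, init = c("ones", "connectome"),
                            counts = NULL, settings = fit_settings(),
                            threshold = 0.5, mode = c("hit", "balanced"),
                            seed = 1) {
  init <- match.arg(init); mode <- match.arg(mode)
  purrr::map_dfr(odors, function(od) {
    r <- loocv_odor_accuracy(features, od, lambda, init, counts, settings,
                             threshold, mode, seed)
    if (is.data.frame(r$accuracy)) {
      dplyr::mutate(r$accuracy, odor = od, .before = 1)
    } else {
      tibble::tibble(odor = od, accuracy = r$accuracy,
                     n_folds = sum(!is.na(r$folds$correct)))
    }
  })
}
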