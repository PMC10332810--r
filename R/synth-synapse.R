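#' Connectome-style KC-to-MBON synapse-count model
#'
#' Per-KC synapse counts onto a single MBON are modelled as a heavy-tailed
#' positive distribution: lognormal, rounded to integers, floored at 1.
#' The default target mean of 8.8 synapses per KC matches the anatomy of a
#' mushroom-body compartment receiving roughly 2,959 synapses from 336
#' Kenyon cells.
#'
#' @param n_kcs number of Kenyon cells.
#' @param mean_count target mean synapse count per KC (default 2959/336).
#' @param sdlog lognormal shape parameter (default 0.8).
#' @param seed RNG seed.
#' @return a `synapse_count_model` list.
#' @export
synapse_count_model <- function(n_kcs = 336, mean_count = 2959 / 336,
                                sdlog = 0.8, seed = 1) {
  if (n_kcs < 1 || mean_count <= 0 || sdlog <= 0)
    stop("n_kcs, mean_count and sdlog must be positive", call. = FALSE)
  structure(list(n_kcs = as.integer(n_kcs), mean_count = mean_count,
                 sdlog = sdlog, seed = seed),
            class = "synapse_count_model")
}

#' Sample per-KC synapse counts
#'
#' Draws lognormal counts with the configured mean, rounds to integers and
#' floors at 1 (every connected KC contributes at least one synapse).
#'
#' @param model a [synapse_count_model()].
#' @return integer vector of length `n_kcs`, all counts >= 1.
#' @export
gen_synapse_counts <- function(model) {
  stopifnot(inherits(model, "synapse_count_model"))
  withr::with_seed(model$seed, {
    meanlog <- log(model$mean_count) - model$sdlog^2 / 2
    x <- stats::rlnorm(model$n_kcs, meanlog = meanlog, sdlog = model$sdlog)
    pmax(1L, as.integer(round(x)))
  })
}
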