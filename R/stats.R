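#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment of a family of p-values: the ordered p-values
#' are multiplied by `m, m-1, ..., 1`, a running maximum enforces
#' monotonicity, and the result is capped at 1, then mapped back to the
#' input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_correction <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

wilcox_result <- function(test_name, n1, n2, ht, family = NA_character_) {
  tibble::tibble(test = test_name, n1 = n1, n2 = n2,
                 statistic = unname(ht$statistic), p.value = ht$p.value,
                 adj.p.value = NA_real_, family = family)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test; the exact null distribution is used when the
#' number of non-zero pairs is at most 8 (and there are no ties), the
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param family optional family id for later Holm correction.
#' @return a one-row `StatResult` tibble: `test`, `n1`, `n2`, `statistic`,
#'   `p.value`, `adj.p.value` (NA until corrected), `family`.
#' @export
paired_signed_rank <- function(x, y, family = NA_character_) {
  if (length(x) != length(y))
    stop("paired test requires equal lengths", call. = FALSE)
  d <- x - y
  if (all(d == 0)) stop("all paired differences are zero", call. = FALSE)
  if (length(x) < 5) warning("fewer than 5 pairs", call. = FALSE)
  n_eff <- sum(d != 0)
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = "two.sided",
    exact = n_eff <= 8, correct = TRUE))
  wilcox_result("signed-rank", length(x), length(y), ht, family)
}

#' Independent-samples Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test, the test used to compare
#' performance indices across treatment groups; exact null for group sizes
#' up to 8 without ties, normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric samples.
#' @param family optional family id for later Holm correction.
#' @return a one-row `StatResult` tibble (see [paired_signed_rank()]).
#' @export
independent_rank_sum <- function(x, y, family = NA_character_) {
  if (length(x) < 5 || length(y) < 5)
    warning("group with fewer than 5 observations", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, paired = FALSE, alternative = "two.sided",
    exact = length(x) <= 8 && length(y) <= 8, correct = TRUE))
  wilcox_result("rank-sum", length(x), length(y), ht, family)
}

#' Holm-adjust a table of test results within families
#'
#' Applies [holm_correction()] separately within each `family` of a
#' StatResult table (rows with `NA` family form their own singleton
#' families and are returned unchanged apart from `adj.p.value = p.value`).
#'
#' @param results tibble of StatResult rows (from [paired_signed_rank()] /
#'   [independent_rank_sum()]).
#' @return the table with `adj.p.value` filled in.
#' @export
adjust_families <- function(results) {
  stopifnot(all(c("p.value", "family") %in% names(results)))
  results$adj.p.value <- results$p.value
  fams <- unique(results$family[!is.na(results$family)])
  for (f in fams) {
    i <- which(results$family == f)
    results$adj.p.value[i] <- holm_correction(results$p.value[i])
  }
  results
}
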