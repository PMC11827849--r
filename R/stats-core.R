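#' Welch's unpaired two-sample t test
#'
#' Two-tailed unpaired t test with Welch's correction for unequal variances,
#' the default group comparison used throughout the pipeline (reporter
#' activities, allelic ratios, filament counts, force summaries).
#'
#' @param a,b Numeric vectors of observations for the two groups; each must
#'   contain at least two values and at least one group must have positive
#'   variance.
#' @return A one-row data frame with columns `statistic` (the t statistic),
#'   `df` (Welch-Satterthwaite degrees of freedom, fractional), `p_value`
#'   (two-tailed) and `method`.
#' @examples
#' welch_t(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_t() needs at least two observations per group")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      # degenerate but well-defined: identical constants in both groups
      return(test_result(0, length(a) + length(b) - 2, 1, "welch_t"))
    }
    stop("welch_t(): both samples have zero variance with different means")
  }
  fit <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  test_result(unname(fit$statistic), unname(fit$parameter), fit$p.value,
              "welch_t")
}

#' Chi-square goodness-of-fit test
#'
#' Tests observed category counts against expected proportions, e.g. offspring
#' genotype counts against a Mendelian 1:2:1 expectation. Uses the asymptotic
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param observed Non-negative integer counts per category.
#' @param expected_weights Positive weights giving the expected proportions
#'   (normalized internally); recycled names are matched positionally.
#' @return A one-row data frame with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chi2_gof(c(0, 94, 47), c(1, 2, 1))
#' @export
chi2_gof <- function(observed, expected_weights) {
  observed <- as.numeric(observed)
  k <- length(observed)
  if (k < 2) stop("chi2_gof() needs at least two categories (df would be 0)")
  if (length(expected_weights) != k) {
    stop("observed and expected_weights must have the same length")
  }
  if (any(expected_weights <= 0)) stop("expected weights must all be positive")
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  expected <- expected_weights / sum(expected_weights) * n
  stat <- sum((observed - expected)^2 / expected)
  test_result(stat, k - 1,
              stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
              "chi2_gof")
}

#' Exact binomial enrichment test
#'
#' Exact binomial tail probability of observing at least `carriers` successes
#' in `n_trials` given a population frequency, used to ask whether a variant
#' is over-represented in a patient cohort relative to a reference population.
#' One-sided (upper tail) by default since the enrichment claim is
#' directional; the two-sided variant doubles the tail and caps at 1.
#'
#' @param carriers Observed number of carriers (successes), `0..n_trials`.
#' @param n_trials Number of trials (e.g. alleles or individuals assayed).
#' @param population_freq Reference success probability, strictly in (0, 1).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row data frame with `statistic` (the carrier count), `df`
#'   (`NA`), `p_value`, `method`.
#' @examples
#' binomial_enrichment(1, 4, 1e-4)
#' @export
binomial_enrichment <- function(carriers, n_trials, population_freq,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (population_freq <= 0 || population_freq >= 1) {
    stop("population_freq must lie strictly in (0, 1)")
  }
  if (carriers < 0 || carriers > n_trials) {
    stop("carriers must lie in 0..n_trials")
  }
  # exact upper-tail summation of the binomial mass function
  p <- sum(stats::dbinom(seq(carriers, n_trials), n_trials, population_freq))
  p <- min(1, p)
  if (alternative == "two.sided") p <- min(1, 2 * p)
  test_result(carriers, NA_real_, p, paste0("binomial_", alternative))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values. The family
#' is always the set of p-values passed in one call; families are never pooled
#' across calls.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p_values, method = "BH")
}

test_result <- function(statistic, df, p_value, method) {
  data.frame(statistic = statistic, df = df, p_value = p_value,
             method = method, stringsAsFactors = FALSE)
}
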