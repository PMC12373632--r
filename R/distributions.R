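# Empirical distributions: the atomic ingredient of a characteristics bundle.
# A distribution is a weighted support: observed values plus non-negative
# weights (counts or frequencies). Sampling is multinomial over the support,
# so simulated quantities can only take values that occur (or are declared)
# in the characterised data.

#' Construct an empirical distribution
#'
#' @param values Numeric support values.
#' @param weights Non-negative numeric weights (counts or frequencies),
#'   same length as `values`. Defaults to equal weights, i.e. the empirical
#'   distribution of the raw observations.
#' @return An object of class `empirical_distribution`.
#' @examples
#' d <- empirical_distribution(c(200, 500), weights = c(3, 2))
#' sample_distribution(d, 10)
#' @export
empirical_distribution <- function(values, weights = NULL) {
  if (is.null(weights)) {
    tab <- table(values)
    values <- as.numeric(names(tab))
    weights <- as.numeric(tab)
  }
  stopifnot(is.numeric(values), is.numeric(weights),
            length(values) == length(weights))
  if (length(values) == 0L) {
    stop("empirical distribution needs a non-empty support")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  keep <- weights > 0
  ord <- order(values[keep])
  structure(list(values = unname(values[keep][ord]),
                 weights = unname(weights[keep][ord])),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat(sprintf("empirical distribution: %d support points, mean %.3f\n",
              length(x$values), distribution_mean(x)))
  invisible(x)
}

is_empirical_distribution <- function(x) inherits(x, "empirical_distribution")

#' Sample from an empirical distribution
#'
#' Draws `n` values from the weighted support with replacement. Sampling is
#' reproducible under `set.seed()`.
#'
#' @param dist An `empirical_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`; every value is in the support.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(is_empirical_distribution(dist), n >= 0)
  if (n == 0L) return(numeric(0))
  if (length(dist$values) == 1L) return(rep(dist$values, n))
  sample(dist$values, n, replace = TRUE, prob = dist$weights)
}

#' Mean of an empirical distribution
#' @param dist An `empirical_distribution`.
#' @return The weight-weighted mean of the support.
#' @export
distribution_mean <- function(dist) {
  stopifnot(is_empirical_distribution(dist))
  sum(dist$values * dist$weights) / sum(dist$weights)
}

#' Weighted variance of an empirical distribution
#' @param dist An `empirical_distribution`.
#' @return The population variance under the normalised weights.
#' @export
distribution_var <- function(dist) {
  m <- distribution_mean(dist)
  w <- dist$weights / sum(dist$weights)
  sum(w * (dist$values - m)^2)
}

# weighted empirical CDF evaluated at q (right-continuous)
distribution_cdf <- function(dist, q) {
  w <- dist$weights / sum(dist$weights)
  vapply(q, function(z) sum(w[dist$values <= z]), numeric(1))
}

#' Two-sample Kolmogorov-Smirnov statistic against an empirical distribution
#'
#' Computes sup |F_sample - F_dist| where F_dist is the weighted CDF of the
#' reference distribution. Used by the round-trip checks that compare
#' re-measured simulated quantities to the characteristics they were drawn
#' from.
#'
#' @param sample Numeric vector of observations.
#' @param dist Reference `empirical_distribution`.
#' @return The KS statistic in \[0, 1\].
#' @export
ks_statistic <- function(sample, dist) {
  stopifnot(length(sample) > 0)
  q <- sort(unique(c(sample, dist$values)))
  fs <- stats::ecdf(sample)(q)
  fd <- distribution_cdf(dist, q)
  max(abs(fs - fd))
}

#' Resampling-calibrated KS threshold
#'
#' Draws `reps` samples of size `n` from `dist` and returns the upper
#' `1 - alpha` quantile of their KS statistics against `dist` itself. A
#' re-measured sample whose statistic falls below this threshold is
#' indistinguishable from direct sampling at that size.
#'
#' @param dist Reference `empirical_distribution`.
#' @param n Sample size of the comparison.
#' @param reps Number of resampling replicates.
#' @param alpha Tail probability.
#' @return Numeric threshold.
#' @export
ks_null_threshold <- function(dist, n, reps = 200, alpha = 0.01) {
  stats::quantile(
    vapply(seq_len(reps),
           function(i) ks_statistic(sample_distribution(dist, n), dist),
           numeric(1)),
    1 - alpha, names = FALSE)
}
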