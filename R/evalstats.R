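#' Evaluation statistics for rating questionnaires
#'
#' Summaries and one-sample tests for Likert-style questionnaire data of
#' the kind used to evaluate training tools: per-question central-tendency
#' summaries, a one-sample t-test computable directly from printed summary
#' statistics (mean, sd, n), and a one-sample Wilcoxon signed-rank test for
#' raw ratings.
#'
#' @name evalstats
NULL

#' Summarize a vector of ratings
#'
#' Sample mean, sample sd (n-1 denominator), min, max, median and
#' interquartile range. Quartiles use linear interpolation of the order
#' statistics (R's default type-7 convention).
#'
#' @param ratings numeric vector, `n >= 1`
#' @return a `likert_summary` list: `n`, `mean`, `sd`, `min`, `max`,
#'   `median`, `iqr`
#' @export
summarize_likert <- function(ratings) {
  if (!length(ratings)) .abort("no ratings supplied", "empty_input")
  ratings <- as.numeric(ratings)
  structure(list(n = length(ratings), mean = mean(ratings),
                 sd = if (length(ratings) > 1) sd(ratings) else 0,
                 min = min(ratings), max = max(ratings),
                 median = median(ratings),
                 iqr = unname(diff(stats::quantile(ratings, c(0.25, 0.75),
                                                   type = 7)))),
            class = "likert_summary")
}

#' One-sample t-test from summary statistics
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `df = n - 1` and a two-sided p
#' from the t distribution. Works from printed summaries (mean, sd, n)
#' when raw data are unavailable. `sd = 0` with `mean != mu0` yields an
#' infinite statistic and p = 0.
#'
#' @param mean sample mean
#' @param sd sample standard deviation (n-1 denominator), `>= 0`
#' @param n sample size, `>= 2`
#' @param mu0 null-hypothesis value
#' @return a `t_test_result`: `t`, `df`, `p_two_sided`, `mean_difference`
#' @export
one_sample_t_from_summary <- function(mean, sd, n, mu0) {
  if (n < 2) .abort("need n >= 2", "bad_input")
  if (sd < 0) .abort("sd must be >= 0", "bad_input")
  diff <- mean - mu0
  t <- if (sd == 0) {
    if (diff == 0) 0 else Inf * sign(diff)
  } else diff / (sd / sqrt(n))
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df = n - 1)
  structure(list(t = t, df = n - 1, p_two_sided = p, mean_difference = diff),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("one-sample t = %.3f, df = %d, two-sided p = %.4g, mean diff = %.3f\n",
              x$t, x$df, x$p_two_sided, x$mean_difference))
  invisible(x)
}

# Exact two-sided p for the signed-rank statistic by enumeration of sign
# assignments (handles tied, averaged ranks). W = sum of ranks of positive
# differences; the null distribution is symmetric about sum(ranks)/2.
.wilcoxon_exact_p <- function(ranks, w_obs) {
  n <- length(ranks)
  mu <- sum(ranks) / 2
  dev <- abs(w_obs - mu)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(ranks[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (abs(w - mu) >= dev - 1e-9) count <- count + 1L
  }
  count / 2^n
}

#' One-sample Wilcoxon signed-rank test
#'
#' Differences equal to `mu0` are dropped; tied absolute differences
#' receive average ranks. With effective `n <= 12` the two-sided p is exact
#' (enumeration over all sign assignments, valid under ties); otherwise a
#' normal approximation with tie correction is used, with `Z` signed so
#' that ratings above `mu0` give `Z > 0`. All differences zero leaves the
#' statistic undefined and raises a classed error.
#'
#' @param ratings numeric vector
#' @param mu0 null-hypothesis location
#' @param exact_max largest effective n for which the exact p is enumerated
#' @return list: `Z`, `p_two_sided`, `n_effective`, `W` (sum of positive
#'   ranks), `exact` (logical)
#' @export
wilcoxon_one_sample <- function(ratings, mu0, exact_max = 12L) {
  d <- as.numeric(ratings) - mu0
  d <- d[d != 0]
  n <- length(d)
  if (!n) .abort("all ratings equal mu0; signed-rank statistic undefined",
                 "undefined_statistic")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    p <- .wilcoxon_exact_p(r, W)
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    exact <- FALSE
  }
  list(Z = Z, p_two_sided = p, n_effective = n, W = W, exact = exact)
}
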