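#' Cochran's Q and I-squared heterogeneity statistics
#'
#' Q is the weighted sum of squared deviations of each study's log odds
#' ratio from the fixed-effects pooled estimate, with inverse-variance
#' weights; under homogeneity it follows a chi-squared distribution with
#' k - 1 degrees of freedom. I-squared expresses the proportion of the
#' variation across studies attributable to heterogeneity rather than
#' chance: `I2 = max(0, 1 - df/Q)`, clamped to [0, 1].
#'
#' @inheritParams pool_fixed_iv
#' @return A `heterogeneity_result`: `q`, `df`, upper-tail `p_value`, `i2`.
#' @export
cochran_q <- function(estimates) {
  df <- as_estimates(estimates)
  k <- nrow(df)
  if (k < 2L) stopf("heterogeneity assessment requires at least 2 studies")
  w <- 1 / df$se^2
  mu <- sum(w * df$log_or) / sum(w)
  q <- sum(w * (df$log_or - mu)^2)
  dfq <- k - 1L
  i2 <- if (q > 0) max(0, min(1, 1 - dfq / q)) else 0
  structure(list(
    q = q,
    df = dfq,
    p_value = stats::pchisq(q, df = dfq, lower.tail = FALSE),
    i2 = i2
  ), class = "heterogeneity_result")
}

#' Power approximation for a meta-analytic Z-test
#'
#' Hedges-Pigott normal approximation to the power of the two-sided Z-test
#' on the pooled log odds ratio: with noncentrality `lambda =
#' delta / pooled_se`, power = 1 - Phi(z_{1-alpha/2} - lambda) +
#' Phi(-z_{1-alpha/2} - lambda).
#'
#' @param delta assumed true log odds ratio under the alternative.
#' @param pooled_se standard error of the pooled estimate (> 0).
#' @param alpha two-sided significance level.
#' @return Power in [0, 1]; equals `alpha` when `delta = 0`.
#' @export
power_approximation <- function(delta, pooled_se, alpha = 0.05) {
  if (!is.numeric(pooled_se) || pooled_se <= 0) stopf("pooled_se must be > 0")
  if (!is_prob(alpha)) stopf("alpha must lie strictly in (0, 1)")
  za <- stats::qnorm(1 - alpha / 2)
  lambda <- delta / pooled_se
  stats::pnorm(lambda - za) + stats::pnorm(-za - lambda)
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f (df = %d), p = %s, I^2 = %.1f%%\n",
              x$q, x$df, format.pval(x$p_value, digits = 4), 100 * x$i2))
  invisible(x)
}
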