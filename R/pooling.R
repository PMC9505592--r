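new_pooled_result <- function(model, k, pooled_log_or, pooled_se, alpha,
                              tau2, weights, q = NA_real_, study_ids = NULL) {
  z <- pooled_log_or / pooled_se
  zq <- stats::qnorm(1 - alpha / 2)
  structure(list(
    model = model,
    k = as.integer(k),
    pooled_log_or = pooled_log_or,
    pooled_se = pooled_se,
    or_value = exp(pooled_log_or),
    ci_low = exp(pooled_log_or - zq * pooled_se),
    ci_high = exp(pooled_log_or + zq * pooled_se),
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    tau2 = tau2,
    q = q,
    per_study_weights = stats::setNames(weights, study_ids),
    alpha = alpha
  ), class = "pooled_result")
}

#' Fixed-effects inverse-variance pooling
#'
#' Pools per-study log odds ratios with weights equal to the reciprocal of
#' their variances, assuming one common true effect.
#'
#' @param estimates effect estimates: a list of [study_odds_ratio()] results
#'   or a data frame with `log_or` and `se` columns (optionally `study_id`).
#' @param alpha significance level for the pooled confidence interval.
#' @return A `pooled_result` with model tag `"fixed_iv"`, the pooled log OR
#'   and its standard error, OR-scale CI, Z statistic and two-sided p-value,
#'   `tau2 = 0`, and normalized per-study weights.
#' @export
pool_fixed_iv <- function(estimates, alpha = 0.05) {
  df <- as_estimates(estimates)
  w <- 1 / df$se^2
  mu <- sum(w * df$log_or) / sum(w)
  new_pooled_result("fixed_iv", nrow(df), mu, 1 / sqrt(sum(w)), alpha,
                    tau2 = 0, weights = w / sum(w), study_ids = df$study_id)
}

#' Mantel-Haenszel fixed-effects pooling of 2x2 tables
#'
#' Pools stratified 2x2 allele-count tables with the Mantel-Haenszel
#' estimator `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`. The variance
#' of `log(OR_MH)` uses the Robins-Breslow-Greenland estimator, which is
#' consistent in both the sparse-data and the large-stratum limit. No
#' per-stratum continuity correction is applied: zero cells are handled by
#' the estimator itself as long as discordant information remains.
#'
#' @param tables a list of [contingency_table()] objects, a `study_table`
#'   data frame, or a data frame with the four count columns.
#' @param alpha significance level for the pooled confidence interval.
#' @return A `pooled_result` with model tag `"fixed_mh"`; per-study weights
#'   are the normalized `b_i c_i / n_i` terms.
#' @export
pool_mantel_haenszel <- function(tables, alpha = 0.05) {
  tb <- as_tables(tables)
  a <- tb$case_risk; b <- tb$case_other
  cc <- tb$control_risk; d <- tb$control_other
  n <- a + b + cc + d
  R <- a * d / n
  S <- b * cc / n
  if (sum(S) == 0 || sum(R) == 0) {
    stopf("Mantel-Haenszel estimate undefined: no discordant information across strata")
  }
  or_mh <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + cc) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  ids <- if (inherits(tables, "data.frame") && "study_id" %in% names(tables)) {
    as.character(tables$study_id)
  } else {
    paste0("study_", seq_along(n))
  }
  new_pooled_result("fixed_mh", nrow(tb), log(or_mh), sqrt(var_log), alpha,
                    tau2 = 0, weights = S / sum(S), study_ids = ids)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study log odds ratios allowing the true effect to vary between
#' studies. The between-study variance is the DerSimonian-Laird moment
#' estimator `tau2 = max(0, (Q - (k-1)) / (S1 - S2/S1))` with fixed-effects
#' weights `w_i = 1/se_i^2`, `S1 = sum(w)`, `S2 = sum(w^2)` and Cochran's Q;
#' random-effects weights are `1/(se_i^2 + tau2)`. When Q does not exceed
#' its degrees of freedom, `tau2` truncates to zero and the result
#' coincides numerically with [pool_fixed_iv()].
#'
#' @inheritParams pool_fixed_iv
#' @return A `pooled_result` with model tag `"random_dl"`, including `tau2`
#'   and Cochran's `q`.
#' @export
pool_random_dl <- function(estimates, alpha = 0.05) {
  df <- as_estimates(estimates)
  k <- nrow(df)
  if (k == 1L) {
    warnf("random-effects pooling of a single study: between-study variance is not estimable; returning the fixed-effects (single-study) estimate")
    res <- pool_fixed_iv(df, alpha)
    res$model <- "random_dl"
    return(res)
  }
  w <- 1 / df$se^2
  mu_fixed <- sum(w * df$log_or) / sum(w)
  q <- sum(w * (df$log_or - mu_fixed)^2)
  s1 <- sum(w)
  s2 <- sum(w^2)
  denom <- s1 - s2 / s1
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  ws <- 1 / (df$se^2 + tau2)
  mu <- sum(ws * df$log_or) / sum(ws)
  new_pooled_result("random_dl", k, mu, 1 / sqrt(sum(ws)), alpha,
                    tau2 = tau2, weights = ws / sum(ws), q = q,
                    study_ids = df$study_id)
}

#' Z-test on a pooled log odds ratio
#'
#' @param pooled_log_or pooled estimate on the log scale.
#' @param pooled_se its standard error (> 0).
#' @return A `test_result` with `statistic = pooled_log_or / pooled_se` and
#'   a two-sided normal p-value.
#' @export
z_test <- function(pooled_log_or, pooled_se) {
  if (!is.numeric(pooled_se) || pooled_se <= 0) stopf("pooled_se must be > 0")
  z <- pooled_log_or / pooled_se
  new_test_result(z, NA_integer_, 2 * stats::pnorm(-abs(z)), "standard Z-test")
}

#' Bonferroni correction
#'
#' Adjusts p-values for `m` simultaneous comparisons: `min(1, p * m)`,
#' preserving order.
#'
#' @param p_values numeric vector of p-values.
#' @param m number of comparisons; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m) {
  if (!is_count(m) || m < 1) stopf("m must be a positive integer")
  if (m < length(p_values)) {
    stopf("m (%d) must be at least the number of p-values (%d)",
          m, length(p_values))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the pooling with one study omitted at a time.
#'
#' @inheritParams pool_fixed_iv
#' @param model `"fixed_iv"` or `"random_dl"`.
#' @return A named list of `k` `pooled_result` objects; the i-th pools all
#'   studies except the i-th, named after the omitted study.
#' @export
leave_one_out <- function(estimates, model = c("fixed_iv", "random_dl"),
                          alpha = 0.05) {
  model <- match.arg(model)
  df <- as_estimates(estimates)
  if (nrow(df) < 2L) stopf("leave-one-out requires at least 2 studies")
  pool_fun <- switch(model, fixed_iv = pool_fixed_iv, random_dl = pool_random_dl)
  out <- lapply(seq_len(nrow(df)), function(i) {
    res <- pool_fun(df[-i, , drop = FALSE], alpha)
    res$omitted <- df$study_id[i]
    res
  })
  stats::setNames(out, df$study_id)
}

#' @export
print.pooled_result <- function(x, ...) {
  tag <- switch(x$model,
                fixed_iv = "Fixed effects (inverse variance)",
                fixed_mh = "Fixed effects (Mantel-Haenszel)",
                random_dl = "Random effects (DerSimonian-Laird)",
                x$model)
  cat(sprintf("%s, k = %d studies\n", tag, x$k))
  cat(sprintf("  OR = %.4f [%.4f, %.4f]  Z = %.3f  p = %s\n",
              x$or_value, x$ci_low, x$ci_high, x$z,
              format.pval(x$p_value, digits = 4)))
  if (x$model == "random_dl") {
    cat(sprintf("  tau^2 = %.4f\n", x$tau2))
  }
  invisible(x)
}
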