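new_test_result <- function(statistic, df, p_value, method, ...) {
  p_value <- if (is.na(p_value)) NA_real_ else min(1, max(0, p_value))
  structure(list(statistic = unname(statistic), df = df,
                 p_value = p_value, method = method, ...),
            class = "test_result")
}

new_effect_estimate <- function(log_or, se, alpha, corrected) {
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    log_or = log_or,
    se = se,
    or_value = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    weight = 1 / se^2,
    corrected = corrected
  ), class = "effect_estimate")
}

#' Odds ratio and confidence interval for one study
#'
#' Computes the cross-product odds ratio of a 2x2 allele-count table, its
#' standard error on the log scale (square root of the sum of reciprocal
#' cells), and a Wald (1 - alpha) confidence interval. When any cell is zero
#' the Haldane-Anscombe continuity correction (0.5 added to all four cells)
#' is applied and flagged in the result.
#'
#' @param table a [contingency_table()], or a numeric vector of the four
#'   cells in the order case_risk, case_other, control_risk, control_other.
#' @param alpha significance level for the confidence interval.
#' @return An `effect_estimate`: log odds ratio, standard error, OR-scale
#'   point estimate and CI bounds, inverse-variance weight, and a
#'   `corrected` flag.
#' @examples
#' study_odds_ratio(c(20, 80, 10, 90))  # OR = 2.25
#' @export
study_odds_ratio <- function(table, alpha = 0.05) {
  tb <- as_tables(table)
  if (nrow(tb) != 1L) stopf("study_odds_ratio expects a single 2x2 table")
  a <- tb$case_risk; b <- tb$case_other
  cc <- tb$control_risk; d <- tb$control_other
  if (a + cc == 0 || b + d == 0) {
    stopf("odds ratio undefined: the '%s' allele column is empty in both arms",
          if (a + cc == 0) "risk" else "other")
  }
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  log_or <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  new_effect_estimate(log_or, se, alpha, corrected)
}

#' Pearson chi-squared test on a count matrix
#'
#' Uncorrected Pearson chi-squared test of independence for an r x c count
#' table (used for comparing gender, genotype and allele distributions
#' between arms).
#'
#' @param table a numeric matrix of non-negative counts, at least 2x2, with
#'   strictly positive row and column margins.
#' @return A `test_result` with statistic, degrees of freedom
#'   (rows-1)(cols-1), and upper-tail p-value.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stopf("need at least a 2x2 table")
  if (any(!is.finite(table) | table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("chi-squared test undefined: a row or column margin is zero")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result(res$statistic, as.integer(res$parameter), res$p.value,
                  "Pearson chi-squared (uncorrected)")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test using the point-probability rule: the p-value sums
#' the hypergeometric probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table.
#'
#' @param table a [contingency_table()] or numeric vector of four cells.
#' @return A `test_result`; the statistic is the conditional maximum
#'   likelihood estimate of the odds ratio, `df` is `NA`.
#' @export
fisher_exact <- function(table) {
  tb <- as_tables(table)
  if (nrow(tb) != 1L) stopf("fisher_exact expects a single 2x2 table")
  m <- matrix(c(tb$case_risk, tb$case_other, tb$control_risk, tb$control_other),
              nrow = 2, byrow = TRUE)
  res <- stats::fisher.test(m)
  new_test_result(unname(res$estimate), NA_integer_, res$p.value,
                  "Fisher exact (point-probability rule)")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups, with mid-ranks for ties.
#' Uses exact enumeration when the combined sample size is at most 10 and no
#' ties are present; otherwise a normal approximation with tie-corrected
#' variance and no continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return A `test_result` with the rank-sum statistic W.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stopf("both groups must be non-empty")
  }
  n <- length(group_a) + length(group_b)
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- n <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  p <- res$p.value
  if (!is.finite(p)) p <- 1  # all observations tied: no evidence either way
  new_test_result(res$statistic, NA_integer_, p,
                  if (exact) "Wilcoxon rank-sum (exact)"
                  else "Wilcoxon rank-sum (normal approximation)")
}

# Exact Hardy-Weinberg test: conditional distribution of the heterozygote
# count given the allele count (Levene/Haldane), two-sided by summing the
# probabilities of all outcomes no more likely than the observed one.
hwe_exact_p <- function(n_hom_risk, n_het, n_hom_other) {
  n <- n_hom_risk + n_het + n_hom_other
  n_a <- 2 * n_hom_risk + n_het  # risk-allele count
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_a + hets) / 2) +
    hets * log(2) - lchoose(2 * n, n_a)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-7)])
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) implied by the sample allele frequency. Uses the Pearson
#' chi-squared goodness-of-fit statistic with 1 degree of freedom; when any
#' expected genotype count falls below 5 the chi-squared approximation is
#' anti-conservative, so the p-value switches to the exact conditional test
#' on the heterozygote count. A monomorphic sample is flagged as undefined
#' rather than raising an error.
#'
#' @param counts a [genotype_counts()] object or numeric vector
#'   (hom-risk, het, hom-other).
#' @return A `test_result` with an extra `monomorphic` flag; `statistic` is
#'   the chi-squared statistic (reported for both methods).
#' @examples
#' hwe_test(c(30, 40, 30))  # chi-squared 4.0
#' @export
hwe_test <- function(counts) {
  if (is.numeric(counts) && length(counts) == 3L) {
    counts <- genotype_counts(counts[1], counts[2], counts[3])
  }
  if (!inherits(counts, "genotype_counts")) {
    stopf("counts must be a genotype_counts object or numeric vector of length 3")
  }
  obs <- c(counts$n_hom_risk, counts$n_het, counts$n_hom_other)
  n <- sum(obs)
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) {
    res <- new_test_result(NA_real_, NA_integer_, NA_real_,
                           "HWE test undefined (monomorphic sample)")
    res$monomorphic <- TRUE
    return(res)
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  statistic <- sum((obs - expected)^2 / expected)
  if (any(expected < 5)) {
    res <- new_test_result(statistic, NA_integer_,
                           hwe_exact_p(obs[1], obs[2], obs[3]),
                           "HWE exact test (sparse expected counts)")
  } else {
    res <- new_test_result(statistic, 1L,
                           stats::pchisq(statistic, df = 1, lower.tail = FALSE),
                           "HWE chi-squared test")
  }
  res$monomorphic <- FALSE
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %s%s, p = %s\n",
              if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 4),
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %d", x$df) else "",
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR = %.4f [%.4f, %.4f]  (log OR %.4f, SE %.4f)%s\n",
              x$or_value, x$ci_low, x$ci_high, x$log_or, x$se,
              if (isTRUE(x$corrected)) "  [continuity-corrected]" else ""))
  invisible(x)
}
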