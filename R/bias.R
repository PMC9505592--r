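#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect (log OR divided by its
#' standard error) on precision (1 / standard error). Under symmetry the
#' regression line passes through the origin; a non-zero intercept indicates
#' small-study asymmetry of the kind produced by publication bias. The
#' intercept is tested with a t statistic on k - 2 degrees of freedom.
#'
#' @inheritParams pool_fixed_iv
#' @return An `egger_test` object: `intercept`, `se`, `t`, `df`, two-sided
#'   `p_value`, and the fitted `slope` (an estimate of the common effect).
#' @export
egger_test <- function(estimates) {
  df <- as_estimates(estimates)
  k <- nrow(df)
  if (k < 3L) stopf("Egger regression requires at least 3 studies")
  precision <- 1 / df$se
  if (stats::var(precision) == 0) {
    stopf("Egger regression undefined: all studies have identical precision")
  }
  y <- df$log_or / df$se
  fit <- stats::lm(y ~ precision)
  cf <- summary(fit)$coefficients
  structure(list(
    intercept = cf[1, 1],
    se = cf[1, 2],
    t = cf[1, 3],
    df = k - 2L,
    p_value = cf[1, 4],
    slope = cf[2, 1]
  ), class = "egger_test")
}

# All permutations of 1..n as a matrix (n! rows); used for the exact null
# distribution of Kendall's S at small k.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- sub + (sub >= i)
    cbind(rep.int(i, nrow(rest)), rest)
  }))
}

# Kendall tau-b with tie correction; p two-sided. Exact permutation null for
# n <= exact_max when neither vector has ties, else normal approximation on
# S = C - D with the tie-corrected variance and no continuity correction.
kendall_tau <- function(x, y, exact_max = 8L) {
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  upper <- upper.tri(dx)
  s_terms <- (dx * dy)[upper]
  s <- sum(s_terms)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1 <- sum(tx * (tx - 1) / 2)
  u1 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - t1) * (n0 - u1))
  tau <- if (denom > 0) s / denom else 0
  no_ties <- t1 == 0 && u1 == 0
  if (n <= exact_max && no_ties) {
    perms <- all_permutations(n)
    ranks_x <- rank(x)
    s_null <- apply(perms, 1, function(p) {
      dyp <- sign(outer(y[p], y[p], "-"))
      sum((dx * dyp)[upper])
    })
    p <- mean(abs(s_null) >= abs(s) - 1e-9)
    method <- "exact permutation"
  } else {
    t_v <- as.numeric(tx); u_v <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_v * (t_v - 1) * (2 * t_v + 5))
    vu <- sum(u_v * (u_v - 1) * (2 * u_v + 5))
    v1 <- sum(t_v * (t_v - 1)) * sum(u_v * (u_v - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_v * (t_v - 1) * (t_v - 2)) * sum(u_v * (u_v - 1) * (u_v - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    if (v <= 0) {
      p <- 1
    } else {
      p <- 2 * stats::pnorm(-abs(s) / sqrt(v))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(tau = tau, s = s, p_value = min(1, p), method = method)
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Each study's deviation from the fixed-effects pooled log odds ratio is
#' standardized by its variance-stabilized standard error
#' `sqrt(se_i^2 - 1/sum(w))`; Kendall's tau-b between these standardized
#' deviations and the study variances is then tested against independence.
#' The p-value is exact (full permutation enumeration) for k <= 8 without
#' ties and otherwise uses the tie-corrected normal approximation without
#' continuity correction.
#'
#' @inheritParams pool_fixed_iv
#' @return A `begg_test` object: `tau`, Kendall `s` statistic (concordant
#'   minus discordant pairs), two-sided `p_value`, and the method used.
#' @export
begg_test <- function(estimates) {
  df <- as_estimates(estimates)
  k <- nrow(df)
  if (k < 3L) stopf("Begg rank-correlation test requires at least 3 studies")
  w <- 1 / df$se^2
  mu <- sum(w * df$log_or) / sum(w)
  vstar <- df$se^2 - 1 / sum(w)  # variance of (theta_i - pooled)
  vstar <- pmax(vstar, .Machine$double.eps)
  t_i <- (df$log_or - mu) / sqrt(vstar)
  kt <- kendall_tau(t_i, df$se^2)
  structure(list(
    tau = kt$tau,
    s = kt$s,
    p_value = kt$p_value,
    method = kt$method,
    k = k
  ), class = "begg_test")
}

#' Duval-Tweedie trim-and-fill adjustment
#'
#' Estimates the number of studies suppressed from one side of the funnel
#' with the L0 rank-based estimator, trims them, re-centres, iterates to
#' convergence, then "fills" by mirroring the trimmed studies about the
#' final centre and re-pools observed plus imputed studies.
#'
#' At each iteration the studies are centred at the fixed-effects pooled
#' estimate of the trimmed set; with `T` the sum of the absolute-deviation
#' ranks on the over-represented side and `n` the number of studies,
#' `k0 = max(0, round((4T - n(n+1)) / (2n - 1)))`.
#'
#' @inheritParams pool_fixed_iv
#' @param side side of the funnel on which studies are presumed missing:
#'   `"left"`, `"right"`, or `"auto"` (choose the side with rank-sum
#'   evidence of suppression).
#' @param model pooling model for the adjusted estimate.
#' @return A `trim_fill` object: `k0` (estimated number of missing
#'   studies), `side`, `center` (final trimmed pooled log OR),
#'   `filled_estimates` (data frame of imputed mirror studies, `k0` rows),
#'   `adjusted` (a `pooled_result` over observed plus filled studies),
#'   `converged`, and `iterations`.
#' @export
trim_and_fill <- function(estimates, side = c("auto", "left", "right"),
                          alpha = 0.05, model = c("fixed_iv", "random_dl")) {
  side <- match.arg(side)
  model <- match.arg(model)
  df <- as_estimates(estimates)
  n <- nrow(df)
  if (n < 3L) stopf("trim-and-fill requires at least 3 studies")

  if (side == "auto") {
    mu0 <- pool_fixed_iv(df, alpha)$pooled_log_or
    d0 <- df$log_or - mu0
    r0 <- rank(abs(d0))
    # missing studies sit on the side with the smaller rank-sum
    side <- if (sum(r0[d0 > 0]) >= sum(r0[d0 < 0])) "left" else "right"
  }
  # work on a flipped scale so the missing side is always the left
  flip <- if (side == "right") -1 else 1
  y <- flip * df$log_or

  k0 <- 0L
  converged <- FALSE
  iterations <- 0L
  mu <- NA_real_
  for (iter in seq_len(20L)) {
    iterations <- iter
    keep <- seq_len(n)
    if (k0 > 0) {
      keep <- keep[!(keep %in% order(y, decreasing = TRUE)[seq_len(k0)])]
    }
    w <- 1 / df$se[keep]^2
    mu <- sum(w * y[keep]) / sum(w)
    d <- y - mu
    r <- rank(abs(d))
    t_sum <- sum(r[d > 0])
    l0 <- (4 * t_sum - n * (n + 1)) / (2 * n - 1)
    k0_new <- min(max(0L, as.integer(round(l0))), n - 1L)
    if (k0_new == k0) {
      converged <- TRUE
      break
    }
    k0 <- k0_new
  }
  if (!converged) {
    warnf("trim-and-fill did not converge in 20 iterations; returning last iterate")
  }

  if (k0 > 0) {
    trim_idx <- order(y, decreasing = TRUE)[seq_len(k0)]
    filled <- data.frame(
      study_id = paste0("filled_", df$study_id[trim_idx]),
      log_or = flip * (2 * mu - y[trim_idx]),
      se = df$se[trim_idx],
      stringsAsFactors = FALSE
    )
    augmented <- rbind(df[c("study_id", "log_or", "se")], filled)
  } else {
    filled <- data.frame(study_id = character(0), log_or = numeric(0),
                         se = numeric(0), stringsAsFactors = FALSE)
    augmented <- df[c("study_id", "log_or", "se")]
  }
  pool_fun <- switch(model, fixed_iv = pool_fixed_iv, random_dl = pool_random_dl)
  structure(list(
    k0 = k0,
    side = side,
    center = flip * mu,
    filled_estimates = filled,
    adjusted = pool_fun(augmented, alpha),
    converged = converged,
    iterations = iterations
  ), class = "trim_fill")
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger regression: intercept = %.4f (SE %.4f), t = %.3f (df %d), p = %s\n",
              x$intercept, x$se, x$t, x$df, format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' @export
print.begg_test <- function(x, ...) {
  cat(sprintf("Begg rank correlation: tau = %.4f, p = %s (%s)\n",
              x$tau, format.pval(x$p_value, digits = 4), x$method))
  invisible(x)
}

#' @export
print.trim_fill <- function(x, ...) {
  cat(sprintf("Trim-and-fill (L0, missing on %s side): k0 = %d%s\n",
              x$side, x$k0,
              if (!x$converged) " [not converged]" else ""))
  cat("Adjusted estimate:\n")
  print(x$adjusted)
  invisible(x)
}

#' Funnel plot of a study collection
#'
#' Diagnostic funnel plot: per-study log odds ratio against standard error
#' (inverted axis, so more precise studies sit at the top). Imputed studies
#' from [trim_and_fill()] can be overlaid as open symbols.
#'
#' @inheritParams pool_fixed_iv
#' @param filled optional data frame of imputed studies (`log_or`, `se`),
#'   e.g. the `filled_estimates` component of a [trim_and_fill()] result.
#' @param center optional vertical reference line (pooled log OR).
#' @param file optional path; when given, the plot is written as a PNG.
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
funnel_plot <- function(estimates, filled = NULL, center = NULL,
                        file = NULL, main = "Funnel plot") {
  df <- as_estimates(estimates)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  xs <- c(df$log_or, if (!is.null(filled)) filled$log_or)
  ys <- c(df$se, if (!is.null(filled)) filled$se)
  graphics::plot(df$log_or, df$se, ylim = rev(range(c(0, ys))),
                 xlim = range(xs), pch = 19,
                 xlab = "log odds ratio", ylab = "standard error",
                 main = main)
  if (!is.null(filled) && nrow(filled) > 0) {
    graphics::points(filled$log_or, filled$se, pch = 1)
  }
  if (!is.null(center)) graphics::abline(v = center, lty = 2)
  invisible(NULL)
}
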