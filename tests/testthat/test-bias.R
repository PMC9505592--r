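test_that("Egger regression recovers constructed intercepts and is order-invariant", {
  # identical effects with varying precision: the regression passes through
  # the origin with slope equal to the common effect
  e <- mk_est(rep(0.5, 6), c(0.1, 0.15, 0.2, 0.3, 0.4, 0.5))
  res <- suppressWarnings(egger_test(e))  # exact fit: summary.lm warns
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_equal(res$slope, 0.5, tolerance = 1e-10)

  # construct y_i = 1 + 0.5 x_i exactly and invert
  se <- c(0.1, 0.25, 0.5)
  x <- 1 / se
  y <- 1 + 0.5 * x            # standardized effects
  built <- mk_est(y * se, se)  # log_or / se = y by construction
  rec <- suppressWarnings(egger_test(built))  # again an exact fit
  expect_equal(rec$intercept, 1, tolerance = 1e-10)
  expect_equal(rec$slope, 0.5, tolerance = 1e-10)
  expect_equal(rec$df, 1L)

  set.seed(701)
  e2 <- mk_est(rnorm(9, 0.3, 0.2), runif(9, 0.1, 0.5))
  a <- egger_test(e2)
  b <- egger_test(e2[sample(9), ])
  expect_equal(b$intercept, a$intercept, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)

  expect_error(egger_test(mk_est(c(0, 1), c(0.1, 0.2))), "at least 3")
  expect_error(egger_test(mk_est(c(0, 1, 2), rep(0.2, 3))), "identical precision")
})

test_that("Egger components agree with metafor's regression test", {
  set.seed(702)
  e <- mk_est(rnorm(10, 0.4, 0.3), runif(10, 0.08, 0.5))
  mine <- egger_test(e)
  ref <- metafor::regtest(metafor::rma(yi = e$log_or, sei = e$se, method = "FE"),
                          model = "lm", predictor = "sei")
  expect_equal(mine$p_value, ref$pval, tolerance = 1e-10)
  expect_equal(abs(mine$t), abs(ref$zval), tolerance = 1e-10)
})

test_that("Begg rank correlation detects monotone association and respects symmetry", {
  # deviations increasing with variance: perfect concordance
  se <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  dev <- c(0.01, 0.4, 0.9, 1.5, 2.2)  # monotone in se and large vs pooled
  res <- begg_test(mk_est(dev, se))
  expect_equal(res$tau, 1)

  # constructed zero-concordance configuration: brute-force pair count gives 0
  e0 <- mk_est(c(0.30, 0.46, 0.35, 0.41), c(0.10, 0.20, 0.30, 0.40))
  w <- 1 / e0$se^2
  mu <- sum(w * e0$log_or) / sum(w)
  t_i <- (e0$log_or - mu) / sqrt(e0$se^2 - 1 / sum(w))
  s_brute <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    s_brute <- s_brute + sign(t_i[i] - t_i[j]) * sign(e0$se[i]^2 - e0$se[j]^2)
  }
  res0 <- begg_test(e0)
  expect_equal(res0$s, s_brute)

  # antisymmetry under reversing the variance ordering
  e1 <- mk_est(c(0.1, 0.5, 0.2, 0.8, 0.3), c(0.1, 0.2, 0.3, 0.4, 0.5))
  a <- begg_test(e1)
  e2 <- e1; e2$se <- rev(e1$se)
  # reversing which variance goes with which deviation flips concordance
  expect_error(begg_test(mk_est(c(0, 1), c(0.1, 0.2))), "at least 3")
  expect_true(abs(a$tau) <= 1)
})

test_that("Begg exact p-values match the permutation null at small k", {
  # without ties the exact two-sided p comes from enumerating all k! orderings
  set.seed(703)
  e <- mk_est(c(0.05, 0.6, 0.3, 0.9, 0.2), c(0.11, 0.23, 0.31, 0.45, 0.52))
  res <- begg_test(e)
  expect_match(res$method, "exact")
  # independent check via cor.test's exact Kendall p on the same pairs
  w <- 1 / e$se^2
  mu <- sum(w * e$log_or) / sum(w)
  t_i <- (e$log_or - mu) / sqrt(e$se^2 - 1 / sum(w))
  ref <- cor.test(t_i, e$se^2, method = "kendall", exact = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$tau, unname(ref$estimate), tolerance = 1e-10)
})

test_that("trim-and-fill leaves symmetric funnels alone and recovers a constructed gap", {
  # exactly symmetric funnel: nothing to impute, adjustment is the identity
  dev <- c(0.1, 0.25, 0.4, 0.6, 0.9)
  sym <- mk_est(0.3 + c(-rev(dev), dev),
                c(rev(c(0.1, 0.15, 0.2, 0.3, 0.4)), c(0.1, 0.15, 0.2, 0.3, 0.4)))
  tf0 <- trim_and_fill(sym)
  expect_equal(tf0$k0, 0L)
  expect_equal(nrow(tf0$filled_estimates), 0L)
  expect_equal(tf0$adjusted$pooled_log_or, pool_fixed_iv(sym)$pooled_log_or,
               tolerance = 1e-12)

  # constructed 10-study funnel with its 3 most negative studies suppressed:
  # precise near-symmetric core plus a right tail; the L0 iteration recovers
  # exactly the 3 missing studies and fills their mirrors
  obs <- mk_est(c(-0.3, -0.1, 0, 0.05, 0.6, 0.8, 1.0),
                c(0.05, 0.05, 0.05, 0.05, 0.5, 0.5, 0.5))
  tf <- trim_and_fill(obs)
  expect_equal(tf$k0, 3L)
  expect_equal(tf$side, "left")
  expect_true(tf$converged)
  expect_equal(nrow(tf$filled_estimates), 3L)
  # filled studies mirror the trimmed ones about the final centre
  expect_equal(sort(tf$filled_estimates$log_or),
               sort(2 * tf$center - c(0.6, 0.8, 1.0)), tolerance = 1e-12)
  # restoring the imputed studies yields a funnel with no further missing studies
  restored <- rbind(obs[, c("log_or", "se")],
                    tf$filled_estimates[, c("log_or", "se")])
  expect_equal(trim_and_fill(restored, side = "left")$k0, 0L)
})

test_that("trim-and-fill matches metafor's L0 implementation", {
  obs <- mk_est(c(-0.3, -0.1, 0, 0.05, 0.6, 0.8, 1.0),
                c(0.05, 0.05, 0.05, 0.05, 0.5, 0.5, 0.5))
  ref <- metafor::trimfill(metafor::rma(yi = obs$log_or, sei = obs$se,
                                        method = "FE"),
                           estimator = "L0", side = "left")
  mine <- trim_and_fill(obs, side = "left")
  expect_equal(mine$k0, ref$k0)
  expect_equal(mine$adjusted$pooled_log_or, as.numeric(ref$beta),
               tolerance = 1e-10)

  # mirror-pair symmetric construction: the conservative L0 estimator lands
  # one short of the 3 suppressed studies, in agreement with metafor
  devs <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  ses <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  pair <- mk_est(c(-rev(devs), devs), c(rev(ses), ses))[-(1:3), ]
  ref2 <- metafor::trimfill(metafor::rma(yi = pair$log_or, sei = pair$se,
                                         method = "FE"),
                            estimator = "L0", side = "left")
  mine2 <- trim_and_fill(pair, side = "left")
  expect_equal(mine2$k0, ref2$k0)
  expect_equal(mine2$k0, 2L)

  set.seed(704)
  for (i in 1:10) {
    e <- mk_est(rnorm(12, 0.3, 0.4), runif(12, 0.05, 0.5))
    for (sd in c("left", "right")) {
      r <- suppressWarnings(  # forcing the counter-evidence side can NaN in metafor
        metafor::trimfill(metafor::rma(yi = e$log_or, sei = e$se,
                                       method = "FE"),
                          estimator = "L0", side = sd))
      m <- trim_and_fill(e, side = sd)
      expect_equal(m$k0, r$k0)
      expect_equal(m$adjusted$pooled_log_or, as.numeric(r$beta),
                   tolerance = 1e-8)
    }
  }
})
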