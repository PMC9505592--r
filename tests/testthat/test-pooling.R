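test_that("inverse-variance pooling matches closed forms", {
  one <- mk_est(0.7, 0.2)
  pooled <- pool_fixed_iv(one)
  expect_equal(pooled$pooled_log_or, 0.7)
  expect_equal(pooled$pooled_se, 0.2)
  expect_equal(pooled$k, 1L)

  mid <- pool_fixed_iv(mk_est(c(0, log(4)), c(0.3, 0.3)))
  expect_equal(mid$or_value, 2, tolerance = 1e-12)

  trip <- pool_fixed_iv(mk_est(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.3)))
  expect_equal(trip$pooled_se, 0.3 / sqrt(3), tolerance = 1e-12)

  expect_equal(sum(mid$per_study_weights), 1)
  expect_error(pool_fixed_iv(data.frame(log_or = numeric(0), se = numeric(0))),
               "at least one")

  # invariant to study order
  set.seed(501)
  e <- mk_est(rnorm(8), runif(8, 0.1, 0.5))
  p1 <- pool_fixed_iv(e)
  p2 <- pool_fixed_iv(e[sample(8), ])
  expect_equal(p2$pooled_log_or, p1$pooled_log_or, tolerance = 1e-14)
})

test_that("Mantel-Haenszel pooling is exact under homogeneity and matches metafor", {
  tb <- data.frame(case_risk = 20, case_other = 80,
                   control_risk = 10, control_other = 90)
  single <- pool_mantel_haenszel(tb)
  expect_equal(single$or_value, 2.25, tolerance = 1e-12)

  twice <- pool_mantel_haenszel(rbind(tb, tb))
  expect_equal(twice$or_value, 2.25, tolerance = 1e-12)

  strata <- data.frame(case_risk = c(20, 40), case_other = c(80, 160),
                       control_risk = c(10, 20), control_other = c(90, 180))
  expect_equal(pool_mantel_haenszel(strata)$or_value, 2.25, tolerance = 1e-12)

  s <- generate_studies(simulation_config(true_or = 1.4, tau2 = 0, k = 8, seed = 77))
  mine <- pool_mantel_haenszel(s)
  ref <- metafor::rma.mh(ai = s$case_risk, bi = s$case_other,
                         ci = s$control_risk, di = s$control_other,
                         measure = "OR", correct = FALSE)
  expect_equal(mine$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$pooled_se, ref$se, tolerance = 1e-10)  # RBG variance
})

test_that("MH and IV pooling agree on homogeneous well-filled collections", {
  set.seed(502)
  for (seed in 1:10) {
    s <- generate_studies(simulation_config(true_or = 1.5, tau2 = 0, k = 12,
                                            seed = seed))
    stopifnot(all(as.matrix(s[, 4:7]) >= 20))
    mh <- pool_mantel_haenszel(s)$pooled_log_or
    iv <- pool_fixed_iv(est_of(s))$pooled_log_or
    expect_lt(abs(mh - iv) / abs(iv), 0.01)
  }
})

test_that("DerSimonian-Laird moment estimator matches hand evaluation and metafor", {
  # identical estimates: Q = 0, truncation, equal to fixed effects bit-for-bit
  same <- mk_est(rep(0.4, 5), rep(0.2, 5))
  dl <- pool_random_dl(same)
  fe <- pool_fixed_iv(same)
  expect_identical(dl$tau2, 0)
  expect_identical(dl$pooled_log_or, fe$pooled_log_or)
  expect_identical(dl$pooled_se, fe$pooled_se)

  # hand case: Q = 50, S1 = 200, S2/S1 = 100 -> tau2 = 49/100
  hand <- pool_random_dl(mk_est(c(0, 1), c(0.1, 0.1)))
  expect_equal(hand$tau2, 0.49, tolerance = 1e-12)
  expect_equal(hand$pooled_log_or, 0.5, tolerance = 1e-12)

  # Q below its degrees of freedom truncates to zero
  near <- pool_random_dl(mk_est(c(0.50, 0.52, 0.48), c(0.3, 0.3, 0.3)))
  expect_equal(near$tau2, 0)

  set.seed(503)
  e <- mk_est(rnorm(12, 0.4, 0.3), runif(12, 0.1, 0.4))
  mine <- pool_random_dl(e)
  ref <- metafor::rma(yi = e$log_or, sei = e$se, method = "DL")
  expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(mine$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$pooled_se, ref$se, tolerance = 1e-10)
})

test_that("single-study random-effects pooling falls back to fixed with a warning", {
  expect_warning(res <- pool_random_dl(mk_est(0.3, 0.1)), "single study")
  expect_equal(res$pooled_log_or, 0.3)
  expect_equal(res$model, "random_dl")
})

test_that("random-effects intervals are never narrower than fixed-effects ones", {
  set.seed(504)
  for (i in 1:200) {
    k <- sample(3:15, 1)
    e <- mk_est(rnorm(k, 0.3, runif(1, 0, 0.6)), runif(k, 0.05, 0.5))
    fe <- pool_fixed_iv(e)
    re <- pool_random_dl(e)
    expect_gte(re$ci_high / re$ci_low, fe$ci_high / fe$ci_low * (1 - 1e-12))
    if (re$tau2 == 0) {
      expect_identical(re$pooled_log_or, fe$pooled_log_or)
      expect_identical(re$pooled_se, fe$pooled_se)
    }
  }
})

test_that("Z-test and Bonferroni behave as documented", {
  expect_equal(z_test(0, 0.2)$p_value, 1)
  expect_equal(z_test(1.959964 * 0.1, 0.1)$p_value, 0.05, tolerance = 1e-6)
  expect_equal(z_test(-0.5, 0.1)$p_value, z_test(0.5, 0.1)$p_value)
  expect_equal(z_test(-0.5, 0.1)$statistic, -z_test(0.5, 0.1)$statistic)
  expect_error(z_test(0.5, 0), "pooled_se")

  expect_equal(bonferroni(0.004, 10), 0.04)
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(c(0.01, 0.2), 2), c(0.02, 0.4))
  expect_identical(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("leave-one-out returns k labelled poolings with the right arithmetic", {
  e <- mk_est(c(0, 0, 0, log(9)), rep(0.2, 4))
  loo <- leave_one_out(e, model = "fixed_iv")
  expect_length(loo, 4L)
  expect_named(loo, e$study_id)
  # dropping the outlier pulls the pooled log OR from log(9)/4 to 0
  full <- pool_fixed_iv(e)
  expect_equal(full$pooled_log_or, log(9) / 4, tolerance = 1e-12)
  expect_equal(loo[["S4"]]$pooled_log_or, 0, tolerance = 1e-12)
  expect_equal(loo[["S1"]]$pooled_log_or, log(9) / 3, tolerance = 1e-12)
  expect_equal(loo[["S1"]]$omitted, "S1")

  ident <- leave_one_out(mk_est(rep(0.3, 3), rep(0.1, 3)))
  ors <- vapply(ident, function(p) p$or_value, numeric(1))
  expect_true(all(abs(ors - ors[1]) < 1e-14))
  expect_error(leave_one_out(mk_est(0.3, 0.1)), "at least 2")
})
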