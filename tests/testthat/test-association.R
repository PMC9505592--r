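test_that("study odds ratios match hand cross-products and correction policy", {
  expect_equal(study_odds_ratio(c(10, 10, 10, 10))$or_value, 1)
  expect_equal(study_odds_ratio(c(10, 10, 10, 10))$log_or, 0)
  expect_equal(study_odds_ratio(c(20, 80, 10, 90))$or_value, 2.25)

  # zero cell: Haldane-Anscombe 0.5 on all four cells, flagged
  est <- study_odds_ratio(c(5, 0, 5, 5))
  expect_true(est$corrected)
  expect_equal(est$or_value, (5.5 * 5.5) / (0.5 * 5.5))
  expect_equal(est$se, sqrt(1 / 5.5 + 1 / 0.5 + 1 / 5.5 + 1 / 5.5))

  # a column of zeros is undefined even under the correction policy
  expect_error(study_odds_ratio(c(0, 10, 0, 10)), "undefined")
})

test_that("transposing exposure yields the reciprocal OR with mirrored CI", {
  set.seed(401)
  for (i in 1:25) {
    cells <- rpois(4, 40) + 1
    a <- study_odds_ratio(cells)
    b <- study_odds_ratio(cells[c(2, 1, 4, 3)])
    expect_equal(b$or_value, 1 / a$or_value, tolerance = 1e-12)
    expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-12)
    expect_equal(b$ci_high, 1 / a$ci_low, tolerance = 1e-12)
    expect_true(a$ci_low <= a$or_value && a$or_value <= a$ci_high)
  }
})

test_that("Pearson chi-squared matches closed forms and rejects zero margins", {
  hom <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)

  res <- pearson_chi2(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # n(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(res$df, 1L)

  wide <- pearson_chi2(rbind(c(5, 10, 15), c(5, 10, 15)))
  expect_equal(wide$statistic, 0)
  expect_equal(wide$df, 2L)

  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("Fisher exact p-values agree with direct hypergeometric enumeration", {
  # independent oracle: point-probability rule over all margin-preserving tables
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(c(3, 1, 1, 3))$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p_value, 1)
  expect_equal(fisher_exact(c(10, 0, 0, 10))$p_value,
               fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)

  set.seed(402)
  for (i in 1:40) {
    cells <- rpois(4, 6) + c(1, 0, 0, 1)
    expect_equal(fisher_exact(cells)$p_value,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher and chi-squared p-values converge as cells scale up", {
  base <- c(12, 18, 20, 10)
  gap <- sapply(c(1, 5, 25), function(s) {
    cells <- base * s
    abs(fisher_exact(cells)$p_value -
          pearson_chi2(matrix(cells, 2, byrow = TRUE))$p_value)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-3)
})

test_that("Wilcoxon rank-sum handles exact, tied and permuted inputs", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # smallest attainable two-sided p with 3 vs 3: 2 of the 20 rank splits
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)

  a <- c(3, 1, 4, 1, 5); b <- c(9, 2, 6, 5, 3)
  expect_equal(wilcoxon_rank_sum(a, b)$statistic,
               wilcoxon_rank_sum(rev(a), sample(b))$statistic)
  expect_error(wilcoxon_rank_sum(numeric(0), b), "non-empty")
})

test_that("HWE test matches worked cases and is label-symmetric", {
  perfect <- hwe_test(c(25, 50, 25))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  dev <- hwe_test(c(30, 40, 30))
  expect_equal(dev$statistic, 4, tolerance = 1e-12)
  expect_equal(dev$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)

  extreme <- hwe_test(c(50, 0, 50))
  expect_equal(extreme$statistic, 100, tolerance = 1e-12)
  expect_lt(extreme$p_value, 1e-3)

  # swapping homozygote labels leaves the statistic unchanged
  set.seed(403)
  for (i in 1:20) {
    cts <- rmultinom(1, 200, c(0.3, 0.45, 0.25))[, 1]
    expect_equal(hwe_test(cts)$statistic, hwe_test(rev(cts))$statistic,
                 tolerance = 1e-12)
  }

  mono <- hwe_test(c(10, 0, 0))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p_value))
})

test_that("sparse genotype classes switch to the exact HWE test", {
  res <- hwe_test(c(2, 2, 96))  # expected hom-risk count well below 5
  expect_match(res$method, "exact")

  # independent oracle: Monte Carlo pairing of the alleles themselves — shuffle
  # the observed allele multiset into n random genotype pairs and read the
  # conditional null distribution of the heterozygote count off the draws
  mc_oracle <- function(obs, reps = 40000) {
    n <- sum(obs); na <- 2 * obs[1] + obs[2]
    alleles <- rep(c(1L, 0L), c(na, 2 * n - na))
    hets <- replicate(reps, {
      s <- sample(alleles)
      sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)])
    })
    prob <- table(factor(hets, levels = 0:n)) / reps
    obs_p <- prob[[obs[2] + 1L]]
    sum(prob[prob <= obs_p * (1 + 1e-7)])
  }
  set.seed(404)
  for (obs in list(c(2, 2, 96), c(1, 8, 11), c(3, 4, 13))) {
    expect_equal(hwe_test(obs)$p_value, mc_oracle(obs), tolerance = 0.02)
  }
})
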