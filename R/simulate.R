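#' Configuration for the synthetic study-collection generator
#'
#' Defines the ground truth of a simulated case-control literature for one
#' polymorphism: a true odds ratio, between-study variance of the log OR
#' (normal random effects), number of studies, baseline control risk-allele
#' frequency, per-study arm-size ranges (subjects per arm; each subject
#' contributes two alleles), and an optional publication-suppression
#' mechanism. Defaults describe a typical candidate-gene literature: OR
#' 1.5, moderate heterogeneity (tau2 0.05), 30 studies, control allele
#' frequency 0.30, arms of 500-2000 subjects, no suppression.
#'
#' @param true_or ground-truth odds ratio (> 0).
#' @param tau2 between-study variance of the log odds ratio (>= 0).
#' @param k number of studies generated before suppression (>= 1).
#' @param control_allele_freq risk-allele frequency in controls, in (0, 1).
#' @param case_n_range,control_n_range inclusive integer ranges for the
#'   number of subjects per arm.
#' @param suppression_p_threshold per-study significance threshold for the
#'   suppression rule.
#' @param suppression_prob probability that a non-significant study is
#'   discarded (the pool shrinks; suppressed studies are not regenerated).
#' @param suppression_side `"two_sided"` (suppress on the two-sided
#'   p-value) or `"right"`/`"left"` (one-sided selection favouring
#'   positive / negative effects, the mechanism that produces directional
#'   funnel asymmetry).
#' @param inbreeding_f inbreeding coefficient in [0, 1] for genotype
#'   generation (Hardy-Weinberg deviation).
#' @param gene,polymorphism labels stamped on the generated studies.
#' @param seed integer seed; every generator is a pure function of its
#'   configuration including the seed.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(true_or = 1.5, tau2 = 0.05, k = 30L,
                              control_allele_freq = 0.30,
                              case_n_range = c(500L, 2000L),
                              control_n_range = c(500L, 2000L),
                              suppression_p_threshold = 0.05,
                              suppression_prob = 0,
                              suppression_side = c("two_sided", "right", "left"),
                              inbreeding_f = 0,
                              gene = "GENE1", polymorphism = "rs0000001",
                              seed = 1L) {
  suppression_side <- match.arg(suppression_side)
  if (!is.numeric(true_or) || true_or <= 0) stopf("true_or must be > 0")
  if (!is.numeric(tau2) || tau2 < 0) stopf("tau2 must be >= 0")
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (!is_prob(control_allele_freq)) {
    stopf("control_allele_freq must lie strictly in (0, 1)")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2L || !all(r >= 1) || r[1] > r[2] ||
        any(r != round(r))) {
      stopf("%s must be an inclusive integer range c(min, max) with min >= 1", nm)
    }
  }
  check_range(case_n_range, "case_n_range")
  check_range(control_n_range, "control_n_range")
  if (!is_prob(suppression_p_threshold)) {
    stopf("suppression_p_threshold must lie strictly in (0, 1)")
  }
  if (!is_prob(suppression_prob, open = FALSE)) {
    stopf("suppression_prob must lie in [0, 1]")
  }
  if (!is_prob(inbreeding_f, open = FALSE)) {
    stopf("inbreeding_f must lie in [0, 1]")
  }
  structure(list(
    true_or = true_or, tau2 = tau2, k = as.integer(k),
    control_allele_freq = control_allele_freq,
    case_n_range = as.integer(case_n_range),
    control_n_range = as.integer(control_n_range),
    suppression_p_threshold = suppression_p_threshold,
    suppression_prob = suppression_prob,
    suppression_side = suppression_side,
    inbreeding_f = inbreeding_f,
    gene = gene, polymorphism = polymorphism,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic collection of case-control studies
#'
#' Draws, for each study, a true log odds ratio from
#' `Normal(log(true_or), tau2)`, converts the control allele frequency to
#' the case frequency through the odds relation
#' `odds(p1) = exp(theta) * odds(p0)`, draws arm sizes uniformly from the
#' configured ranges, and samples allele counts as `Binomial(2n, p)` per
#' arm (each subject contributes two alleles). If suppression is active,
#' each study whose per-study association p-value fails the significance
#' rule is discarded with the configured probability; the pool shrinks and
#' suppressed studies are not regenerated, mimicking publication bias.
#'
#' @param config a [simulation_config()].
#' @return A `study_table` data frame with one row per retained study and a
#'   `"truth"` attribute recording `true_or`, `tau2`, the number of
#'   suppressed studies, and the per-study true log ORs of the retained
#'   studies.
#' @export
generate_studies <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stopf("config must be a simulation_config object")
  }
  with_seed(config$seed, {
    k <- config$k
    theta <- stats::rnorm(k, log(config$true_or), sqrt(config$tau2))
    p0 <- config$control_allele_freq
    odds1 <- exp(theta) * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    draw_n <- function(r) {
      if (r[1] == r[2]) rep.int(r[1], k) else sample(seq(r[1], r[2]), k, replace = TRUE)
    }
    n_case <- draw_n(config$case_n_range)
    n_control <- draw_n(config$control_n_range)
    case_risk <- stats::rbinom(k, 2 * n_case, p1)
    control_risk <- stats::rbinom(k, 2 * n_control, p0)
    df <- data.frame(
      study_id = sprintf("%s_S%04d", config$gene, seq_len(k)),
      gene = config$gene,
      polymorphism = config$polymorphism,
      case_risk = case_risk,
      case_other = 2 * n_case - case_risk,
      control_risk = control_risk,
      control_other = 2 * n_control - control_risk,
      stringsAsFactors = FALSE
    )
    keep <- rep(TRUE, k)
    if (config$suppression_prob > 0) {
      cells <- df[c("case_risk", "case_other", "control_risk", "control_other")]
      zero <- apply(cells == 0, 1, any)
      cells <- cells + 0.5 * zero  # Haldane-Anscombe where needed
      lo <- log(cells$case_risk) + log(cells$control_other) -
        log(cells$case_other) - log(cells$control_risk)
      se <- sqrt(1 / cells$case_risk + 1 / cells$case_other +
                   1 / cells$control_risk + 1 / cells$control_other)
      z <- lo / se
      sig <- switch(config$suppression_side,
        two_sided = 2 * stats::pnorm(-abs(z)) <= config$suppression_p_threshold,
        right = stats::pnorm(z, lower.tail = FALSE) <= config$suppression_p_threshold,
        left = stats::pnorm(z) <= config$suppression_p_threshold
      )
      keep <- sig | (stats::runif(k) > config$suppression_prob)
      if (!any(keep)) {
        stopf("all %d studies were suppressed; lower suppression_prob or raise the effect/sample sizes", k)
      }
    }
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("study_table", "data.frame")
    attr(out, "truth") <- list(
      true_or = config$true_or,
      tau2 = config$tau2,
      n_generated = k,
      n_suppressed = sum(!keep),
      theta = theta[keep]
    )
    out
  })
}

#' Generate genotype counts with a controllable Hardy-Weinberg deviation
#'
#' Draws genotype counts from the inbreeding model: with risk-allele
#' frequency p, q = 1 - p and inbreeding coefficient f, the genotype
#' probabilities are (p^2 + f p q, 2 p q (1 - f), q^2 + f p q). At f = 0
#' the sample is in Hardy-Weinberg equilibrium; at f = 1 heterozygotes are
#' absent.
#'
#' @param n number of subjects (> 0).
#' @param allele_freq risk-allele frequency in (0, 1).
#' @param inbreeding_f inbreeding coefficient in [0, 1].
#' @param seed integer seed.
#' @return A [genotype_counts()] object.
#' @export
generate_genotypes <- function(n, allele_freq, inbreeding_f = 0, seed = 1L) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (!is_prob(allele_freq)) stopf("allele_freq must lie strictly in (0, 1)")
  if (!is_prob(inbreeding_f, open = FALSE)) {
    stopf("inbreeding_f must lie in [0, 1]")
  }
  p <- allele_freq; q <- 1 - p; f <- inbreeding_f
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, probs))
    genotype_counts(counts[1], counts[2], counts[3])
  })
}

#' Generate per-subject panel dosages
#'
#' Independent `Binomial(2, freq)` risk-allele dosages per panel allele per
#' subject.
#'
#' @param n number of subjects.
#' @param allele_freqs numeric vector of 11 allele frequencies in (0, 1)
#'   (or in [0, 1] for degenerate fixtures).
#' @param seed integer seed.
#' @param panel panel definition supplying the column names.
#' @return A `subject_genotypes` data frame (`subject_id` plus 11 dosage
#'   columns).
#' @export
generate_panel_subjects <- function(n, allele_freqs, seed = 1L,
                                    panel = gars_panel()) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (length(allele_freqs) != 11L ||
      any(allele_freqs < 0 | allele_freqs > 1)) {
    stopf("allele_freqs must be 11 probabilities in [0, 1]")
  }
  with_seed(seed, {
    m <- vapply(allele_freqs, function(f) stats::rbinom(n, 2L, f),
                integer(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    df <- as.data.frame(m)
    names(df) <- panel$column
    df <- cbind(subject_id = sprintf("P%05d", seq_len(n)), df,
                stringsAsFactors = FALSE)
    class(df) <- c("subject_genotypes", "data.frame")
    df
  })
}
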