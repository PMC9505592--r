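#' Pre-test to post-test risk conversion
#'
#' Converts a baseline (pre-test) disease probability into the post-test
#' probability implied by a pooled odds ratio, through odds space:
#' pre-test odds = risk / (1 - risk); post-test odds = OR x pre-test odds;
#' post-test risk = post-test odds / (1 + post-test odds). All arithmetic is
#' kept in full precision; rounding happens only at report time.
#'
#' @param pre_test_risk baseline probability strictly in (0, 1); the
#'   conventional default is 0.08, an assumed 8% population prevalence.
#' @param or_value pooled odds ratio (> 0) for the polymorphism.
#' @return A `risk_conversion` object with fields `pre_test_risk`,
#'   `pre_test_odds`, `or_value`, `post_test_odds`, `post_test_risk`, and
#'   `gain` (post minus pre).
#' @examples
#' pre_to_post(0.08, 1.23)$post_test_risk  # 0.0966..., i.e. 0.10 at 2 dp
#' @export
pre_to_post <- function(pre_test_risk, or_value) {
  if (!is_prob(pre_test_risk)) {
    stopf("pre_test_risk must lie strictly in (0, 1)")
  }
  if (!is.numeric(or_value) || length(or_value) != 1L ||
      !is.finite(or_value) || or_value <= 0) {
    stopf("or_value must be a finite positive number")
  }
  pre_odds <- pre_test_risk / (1 - pre_test_risk)
  post_odds <- or_value * pre_odds
  post_risk <- post_odds / (1 + post_odds)
  structure(list(
    pre_test_risk = pre_test_risk,
    pre_test_odds = pre_odds,
    or_value = or_value,
    post_test_odds = post_odds,
    post_test_risk = post_risk,
    gain = post_risk - pre_test_risk
  ), class = "risk_conversion")
}

#' Score subjects against the risk-allele panel
#'
#' Sums each subject's risk-allele dosages across the eleven panel alleles
#' and dichotomizes the total against two cutoffs: a count reaching the drug
#' threshold (default 4) flags risk for drug use, and a count reaching the
#' AUD threshold (default 7) flags risk for alcohol use disorder. In
#' `"carrier"` mode each allele contributes at most 1 (carrier status)
#' instead of the 0/1/2 dosage.
#'
#' @param dosages either a numeric vector of 11 allele dosages (values 0, 1
#'   or 2) for one subject, or a `subject_genotypes` data frame from
#'   [read_subject_genotypes()] / [generate_panel_subjects()].
#' @param config a [run_config()] supplying the thresholds.
#' @param mode `"dosage"` (sum of 0/1/2 dosages, maximum 22) or `"carrier"`
#'   (sum of carrier indicators, maximum 11).
#' @return For a single vector, a `panel_score` object (`allele_count`,
#'   `drug_risk_flag`, `aud_risk_flag`); for a data frame, a data frame with
#'   one scored row per subject.
#' @export
score_panel <- function(dosages, config = run_config(),
                        mode = c("dosage", "carrier")) {
  mode <- match.arg(mode)
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (is.data.frame(dosages)) {
    cols <- setdiff(names(dosages), "subject_id")
    if (length(cols) != 11L) {
      stopf("expected 11 allele dosage columns, found %d", length(cols))
    }
    m <- as.matrix(dosages[cols])
    if (any(!(m %in% c(0, 1, 2)))) stopf("dosages must be 0, 1 or 2")
    if (mode == "carrier") m <- pmin(m, 1)
    count <- as.integer(rowSums(m))
    return(data.frame(
      subject_id = if ("subject_id" %in% names(dosages)) {
        as.character(dosages$subject_id)
      } else {
        paste0("subject_", seq_len(nrow(dosages)))
      },
      allele_count = count,
      drug_risk_flag = count >= config$drug_threshold,
      aud_risk_flag = count >= config$aud_threshold,
      stringsAsFactors = FALSE
    ))
  }
  if (!is.numeric(dosages) || length(dosages) != 11L) {
    stopf("dosage vector must have exactly 11 entries (got %d)",
          length(dosages))
  }
  if (any(!(dosages %in% c(0, 1, 2)))) stopf("dosages must be 0, 1 or 2")
  d <- if (mode == "carrier") pmin(dosages, 1) else dosages
  count <- as.integer(sum(d))
  structure(list(
    allele_count = count,
    drug_risk_flag = count >= config$drug_threshold,
    aud_risk_flag = count >= config$aud_threshold
  ), class = "panel_score")
}

#' @export
print.risk_conversion <- function(x, ...) {
  cat(sprintf("Pre-test risk %.3f (odds %.4f) x OR %.4f -> post-test risk %.4f (gain %+.4f)\n",
              x$pre_test_risk, x$pre_test_odds, x$or_value,
              x$post_test_risk, x$gain))
  invisible(x)
}

#' @export
print.panel_score <- function(x, ...) {
  cat(sprintf("Panel risk-allele count: %d  drug risk: %s  AUD risk: %s\n",
              x$allele_count, x$drug_risk_flag, x$aud_risk_flag))
  invisible(x)
}
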