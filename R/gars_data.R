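#' The reward-pathway risk-allele panel
#'
#' The ten reward-pathway genes and eleven risk alleles scored by the
#' genetic addiction risk panel: dopamine receptors D1-D4, the dopamine
#' transporter, COMT, the mu-opioid receptor, GABRB3, MAO-A and the
#' serotonin transporter promoter variant. DRD4 contributes two alleles
#' (the promoter SNP and the exon-3 48 bp VNTR 7-repeat), which is how the
#' panel reaches eleven alleles across ten genes.
#'
#' @return A data frame with columns `gene`, `polymorphism`, `risk_allele`,
#'   and `column` (the dosage column name used in subject genotype tables).
#' @export
gars_panel <- function() {
  data.frame(
    gene = c("DRD1", "DRD2", "DRD3", "DRD4", "DRD4", "DAT1", "COMT",
             "OPRM1", "GABRB3", "MAOA", "HTTLPR"),
    polymorphism = c("rs4532", "rs1800497", "rs6280", "rs1800955",
                     "48bp_VNTR", "SLC6A3_3UTR_VNTR", "rs4680", "rs1799971",
                     "CA_repeat", "30bp_VNTR", "rs25531"),
    risk_allele = c("G", "A1", "C", "C", "7R", "A9", "G", "G",
                    "181", "4R", "S'"),
    column = c("DRD1_G", "DRD2_A1", "DRD3_C", "DRD4_C", "DRD4_7R",
               "DAT1_A9", "COMT_G", "OPRM1_G", "GABRB3_181", "MAOA_4R",
               "HTTLPR_S"),
    stringsAsFactors = FALSE
  )
}

#' Literature-scale presets for the panel genes
#'
#' Per-gene study counts and total case/control sample sizes of the
#' published case-control literature behind each panel polymorphism (e.g.
#' DRD2 rs1800497: 18,290 cases vs. 19,809 controls across 118 sources).
#' Useful for parameterizing the synthetic study generator at realistic
#' per-gene scale: small-literature genes (DRD1, DRD3, GABRB3, MAOA)
#' reproduce the insufficient-data and non-significance behaviour seen for
#' those genes.
#'
#' @return A data frame with columns `gene`, `polymorphism`, `risk_allele`,
#'   `n_studies`, `cases_total`, `controls_total`.
#' @export
gars_study_presets <- function() {
  data.frame(
    gene = c("DRD1", "DRD2", "DRD3", "DRD4", "DAT1", "COMT", "OPRM1",
             "GABRB3", "MAOA", "HTTLPR"),
    polymorphism = c("rs4532", "rs1800497", "rs6280", "rs1800955",
                     "SLC6A3_3UTR_VNTR", "rs4680", "rs1799971",
                     "CA_repeat", "30bp_VNTR", "rs25531"),
    risk_allele = c("G", "A1", "C", "C", "A9", "G", "G", "181", "4R", "S'"),
    n_studies = c(3L, 118L, 3L, 35L, 43L, 13L, 28L, 6L, 6L, 20L),
    cases_total = c(90L, 18290L, 243L, 2997L, 3790L, 1212L, 3096L,
                    171L, 170L, 9996L),
    controls_total = c(122L, 19809L, 130L, 2588L, 3446L, 933L, 2896L,
                       45L, 177L, 9950L),
    stringsAsFactors = FALSE
  )
}

#' Reported pooled odds ratios for the panel polymorphisms
#'
#' The published pooled odds ratios and 95% confidence intervals for each
#' panel polymorphism's association with alcohol use disorder, as reported
#' in the source meta-analytic summary, together with the post-test risk
#' value printed there (at an assumed 8% pre-test risk). These are inputs
#' for risk conversion and worked examples, not values this package
#' recomputes (the underlying primary studies are not distributed).
#'
#' Note that for several genes the printed post-test risk is not consistent
#' with applying the odds-conversion formula to the printed OR at pre-test
#' risk 0.08; [pre_to_post()] implements the formula as stated, and the
#' printed values are carried verbatim for reference only.
#'
#' @return A data frame with columns `gene`, `or`, `ci_low`, `ci_high`,
#'   `post_risk_printed` (`NA` where the source prints a dash for
#'   insufficient data).
#' @export
gars_pooled_or <- function() {
  data.frame(
    gene = c("DRD1", "DRD2", "DRD3", "DRD4", "DAT1", "COMT", "OPRM1",
             "GABRB3", "MAOA", "HTTLPR"),
    or = c(1.77, 1.45, 3.37, 1.56, 1.18, 1.43, 1.47, 0.33, 0.62, 1.23),
    ci_low = c(1.01, 1.15, 1.54, 1.04, 1.00, 0.98, 1.00, 0.14, 0.15, 1.07),
    ci_high = c(3.10, 1.90, 7.40, 2.36, 1.45, 2.10, 2.18, 0.79, 2.63, 1.40),
    post_risk_printed = c(NA, 0.12, 0.20, 0.10, 0.10, 0.083, 0.13,
                          0.06, 0.05, 0.10),
    stringsAsFactors = FALSE
  )
}
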