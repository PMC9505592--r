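#' Construct a 2x2 allele-count contingency table for one study
#'
#' One case-control study's exposure table: counts of risk alleles (or risk
#' carriers) and other alleles among cases and controls. All four counts must
#' be non-negative integers and both the case and the control margin must be
#' positive.
#'
#' @param case_risk,case_other risk- and other-allele counts among cases.
#' @param control_risk,control_other risk- and other-allele counts among
#'   controls.
#' @return An object of class `contingency_table` (a named list of the four
#'   cells).
#' @examples
#' contingency_table(20, 80, 10, 90)
#' @export
contingency_table <- function(case_risk, case_other, control_risk, control_other) {
  cells <- list(
    case_risk = case_risk, case_other = case_other,
    control_risk = control_risk, control_other = control_other
  )
  for (nm in names(cells)) {
    if (!is_count(cells[[nm]])) {
      stopf("cell '%s' must be a non-negative integer count (got %s)",
            nm, format(cells[[nm]]))
    }
  }
  if (case_risk + case_other <= 0) stopf("case margin must be positive")
  if (control_risk + control_other <= 0) stopf("control margin must be positive")
  structure(lapply(cells, as.numeric), class = "contingency_table")
}

#' Construct genotype counts for one sample
#'
#' Genotype counts at a biallelic polymorphism: risk-allele homozygotes,
#' heterozygotes, other-allele homozygotes. Used for Hardy-Weinberg
#' equilibrium assessment.
#'
#' @param n_hom_risk,n_het,n_hom_other non-negative integer genotype counts;
#'   their total must be positive.
#' @return An object of class `genotype_counts`.
#' @examples
#' genotype_counts(30, 40, 30)
#' @export
genotype_counts <- function(n_hom_risk, n_het, n_hom_other) {
  cells <- list(n_hom_risk = n_hom_risk, n_het = n_het, n_hom_other = n_hom_other)
  for (nm in names(cells)) {
    if (!is_count(cells[[nm]])) {
      stopf("genotype count '%s' must be a non-negative integer (got %s)",
            nm, format(cells[[nm]]))
    }
  }
  n <- n_hom_risk + n_het + n_hom_other
  if (n <= 0) stopf("total genotype count must be positive")
  structure(lapply(cells, as.numeric), class = "genotype_counts")
}

study_table_required <- c(
  "study_id", "gene", "polymorphism",
  "case_risk", "case_other", "control_risk", "control_other"
)

study_table_genotype_cols <- c(
  "case_AA", "case_Aa", "case_aa", "control_AA", "control_Aa", "control_aa"
)

validate_study_table <- function(df, source = "study table") {
  missing <- setdiff(study_table_required, names(df))
  if (length(missing) > 0) {
    stopf("%s is missing required column(s): %s",
          source, paste(missing, collapse = ", "))
  }
  df$study_id <- as.character(df$study_id)
  df$gene <- as.character(df$gene)
  df$polymorphism <- as.character(df$polymorphism)
  if (nrow(df) == 0L) return(df)
  count_cols <- intersect(
    c(study_table_required[4:7], study_table_genotype_cols), names(df)
  )
  for (cl in count_cols) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which((!is.na(df[[cl]]) & is.na(vals)) |
                   (!is.na(vals) & (vals < 0 | vals != round(vals))))
    if (length(bad) > 0) {
      stopf("%s row %d: field '%s' is not a non-negative integer (value '%s')",
            source, bad[1], cl, as.character(df[[cl]][bad[1]]))
    }
    df[[cl]] <- vals
  }
  dup <- duplicated(df$study_id)
  if (any(dup)) {
    stopf("%s: duplicate study_id '%s' (row %d)",
          source, df$study_id[which(dup)[1]], which(dup)[1])
  }
  empty <- which(is.na(df$gene) | df$gene == "" |
                   is.na(df$polymorphism) | df$polymorphism == "")
  if (length(empty) > 0) {
    stopf("%s row %d: gene and polymorphism must be non-empty", source, empty[1])
  }
  zero_margin <- which(df$case_risk + df$case_other <= 0 |
                         df$control_risk + df$control_other <= 0)
  if (length(zero_margin) > 0) {
    stopf("%s row %d (study '%s'): case and control margins must be positive",
          source, zero_margin[1], df$study_id[zero_margin[1]])
  }
  class(df) <- c("study_table", "data.frame")
  df
}

#' Read a tab-separated study-collection table
#'
#' Reads a UTF-8 tab-separated file with one case-control study per row.
#' Required columns (any order): `study_id`, `gene`, `polymorphism`,
#' `case_risk`, `case_other`, `control_risk`, `control_other`. Optional
#' genotype-count columns `case_AA case_Aa case_aa control_AA control_Aa
#' control_aa` enable Hardy-Weinberg checks, and any further columns are
#' carried through verbatim as study metadata (ethnicity, publication year,
#' ...), so stratified analyses remain possible.
#'
#' @param path path to the TSV file.
#' @return A `study_table` data frame (one row per study).
#' @seealso [write_study_table()], [run_analysis()]
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stopf("study table file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  df <- validate_study_table(df, source = sprintf("'%s'", path))
  if (nrow(df) == 0L) {
    warnf("'%s' contains a header but no study rows", path)
  }
  df
}

#' Write a study-collection table to TSV
#'
#' Inverse of [read_study_table()]: a written collection reads back with all
#' counts intact.
#'
#' @param studies a `study_table` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  studies <- validate_study_table(as.data.frame(studies))
  utils::write.table(studies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-subject panel genotype dosages
#'
#' Reads a tab-separated table with a `subject_id` column plus one dosage
#' column per panel risk allele (named `<GENE>_<allele>`, values 0, 1 or 2
#' copies of the risk allele).
#'
#' @param path path to the TSV file.
#' @param panel a panel definition as returned by [gars_panel()]; its
#'   `column` field lists the required dosage columns.
#' @return A `subject_genotypes` data frame: `subject_id` plus one integer
#'   dosage column per panel allele.
#' @seealso [score_panel()]
#' @export
read_subject_genotypes <- function(path, panel = gars_panel()) {
  if (!file.exists(path)) stopf("subject genotype file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(df)) stopf("'%s' lacks a subject_id column", path)
  missing <- setdiff(panel$column, names(df))
  if (length(missing) > 0) {
    stopf("'%s' is missing panel allele column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  for (cl in panel$column) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(vals) | !(vals %in% c(0, 1, 2)))
    if (length(bad) > 0) {
      stopf("subject '%s', column '%s': dosage must be 0, 1 or 2 (value '%s')",
            df$subject_id[bad[1]], cl, as.character(df[[cl]][bad[1]]))
    }
    df[[cl]] <- as.integer(vals)
  }
  df <- df[c("subject_id", panel$column)]
  class(df) <- c("subject_genotypes", "data.frame")
  df
}

#' Validate and complete a run configuration
#'
#' Fills defaults and enforces invariants on the analysis configuration. The
#' defaults encode the analysis conventions: an assumed pre-test (baseline
#' population) risk of 8%, a 5% significance level, random-effects selection
#' when the heterogeneity Q-test p-value falls below 0.10, and panel score
#' cutoffs of 4 (drug risk) and 7 (alcohol-use-disorder risk).
#'
#' @param raw a named list (e.g. parsed from a JSON config document) of
#'   configuration overrides; unknown keys produce a warning and are ignored.
#' @return A `run_config` object.
#' @examples
#' validate_config(list(alpha = 0.05, seed = 42))
#' @export
validate_config <- function(raw = list()) {
  if (inherits(raw, "run_config")) raw <- unclass(raw)
  if (!is.list(raw)) stopf("configuration must be a named list")
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warnf("ignoring unknown configuration key(s): %s",
          paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(run_config, raw)
}

#' @rdname validate_config
#' @param pre_test_risk assumed baseline disease probability in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param heterogeneity_p_threshold Cochran Q-test p-value below which the
#'   random-effects model is used for the headline pooled estimate.
#' @param bonferroni_m number of simultaneous comparisons for the Bonferroni
#'   correction; `NULL` means "the number of polymorphisms analysed in the
#'   run".
#' @param drug_threshold,aud_threshold panel-score cutoffs; a subject whose
#'   risk-allele count reaches the threshold is flagged.
#' @param power_delta assumed true log odds ratio for the power
#'   approximation; `NULL` disables the power column.
#' @param seed integer seed for any stochastic step.
#' @export
run_config <- function(pre_test_risk = 0.08, alpha = 0.05,
                       heterogeneity_p_threshold = 0.10,
                       bonferroni_m = NULL,
                       drug_threshold = 4L, aud_threshold = 7L,
                       power_delta = NULL, seed = 1L) {
  if (!is_prob(pre_test_risk)) stopf("pre_test_risk must lie strictly in (0, 1)")
  if (!is_prob(alpha)) stopf("alpha must lie strictly in (0, 1)")
  if (!is_prob(heterogeneity_p_threshold)) {
    stopf("heterogeneity_p_threshold must lie strictly in (0, 1)")
  }
  if (!is.null(bonferroni_m) && !(is_count(bonferroni_m) && bonferroni_m >= 1)) {
    stopf("bonferroni_m must be a positive integer (or NULL)")
  }
  if (!is_count(drug_threshold) || drug_threshold < 1) {
    stopf("drug_threshold must be a positive integer")
  }
  if (!is_count(aud_threshold) || aud_threshold < 1) {
    stopf("aud_threshold must be a positive integer")
  }
  if (drug_threshold > aud_threshold) {
    stopf("drug_threshold must not exceed aud_threshold")
  }
  if (!is.null(power_delta) &&
      !(is.numeric(power_delta) && length(power_delta) == 1L && is.finite(power_delta))) {
    stopf("power_delta must be a finite number (or NULL)")
  }
  if (!is_count(abs(seed))) stopf("seed must be an integer")
  structure(list(
    pre_test_risk = pre_test_risk, alpha = alpha,
    heterogeneity_p_threshold = heterogeneity_p_threshold,
    bonferroni_m = if (is.null(bonferroni_m)) NULL else as.integer(bonferroni_m),
    drug_threshold = as.integer(drug_threshold),
    aud_threshold = as.integer(aud_threshold),
    power_delta = power_delta,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a JSON run configuration
#'
#' @param path path to a JSON document whose keys match [run_config()]
#'   arguments.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  pre-test risk: %g   alpha: %g   heterogeneity p threshold: %g\n",
              x$pre_test_risk, x$alpha, x$heterogeneity_p_threshold))
  cat(sprintf("  panel thresholds: drug >= %d, AUD >= %d   seed: %d\n",
              x$drug_threshold, x$aud_threshold, x$seed))
  if (!is.null(x$bonferroni_m)) {
    cat(sprintf("  Bonferroni m: %d\n", x$bonferroni_m))
  }
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$case_risk, x$case_other, x$control_risk, x$control_other),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"), c("risk", "other")))
  cat("2x2 allele-count table\n")
  print(m)
  invisible(x)
}
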