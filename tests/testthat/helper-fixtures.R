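# Shared helpers: build small estimate/table fixtures in code.

mk_est <- function(log_or, se) {
  data.frame(study_id = paste0("S", seq_along(log_or)),
             log_or = log_or, se = se, stringsAsFactors = FALSE)
}

# Per-study log-OR estimates from a generated study table.
est_of <- function(studies, alpha = 0.05) {
  do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    e <- study_odds_ratio(studies[i, ], alpha)
    data.frame(study_id = studies$study_id[i], log_or = e$log_or, se = e$se,
               stringsAsFactors = FALSE)
  }))
}

# A small well-formed study collection for IO and pipeline tests.
example_studies <- function() {
  data.frame(
    study_id = c("A1", "A2", "A3"),
    gene = "DRD2",
    polymorphism = "rs1800497",
    case_risk = c(120, 80, 200),
    case_other = c(280, 220, 300),
    control_risk = c(90, 70, 150),
    control_other = c(310, 230, 350),
    ethnicity = c("european", "asian", "european"),
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
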