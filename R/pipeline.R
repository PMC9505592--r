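#' Run the full per-gene meta-analytic validation procedure
#'
#' For each gene in the study collection: per-study odds ratios (with
#' continuity corrections logged), Hardy-Weinberg flags where genotype
#' counts are present, Cochran's Q and I-squared, model selection (random
#' effects when the Q-test p-value falls below the configured threshold,
#' otherwise fixed-effects Mantel-Haenszel on the count tables), the pooled
#' OR with CI, Z-test and Bonferroni-adjusted p-value, a leave-one-out
#' sensitivity table, Egger and Begg publication-bias tests (k >= 3), a
#' trim-and-fill adjustment when either bias test is significant at alpha,
#' and the pre-test to post-test risk conversion. Genes with fewer than two
#' usable studies are flagged as insufficient rather than dropped; no study
#' is ever excluded silently.
#'
#' @param studies a `study_table` data frame ([read_study_table()] or
#'   [generate_studies()]).
#' @param config a [run_config()].
#' @return An `analysis_run` object: `config`, `per_gene` (a named list
#'   with, per gene, the per-study estimate table, pooled result,
#'   heterogeneity, bias assessment, leave-one-out results, risk conversion,
#'   power, and flags) and `warnings` (every correction, exclusion and
#'   degenerate case encountered).
#' @seealso [build_report()], [stratified_analysis()]
#' @export
run_analysis <- function(studies, config = run_config()) {
  studies <- validate_study_table(as.data.frame(studies))
  if (nrow(studies) == 0L) stopf("the study collection is empty")
  if (!inherits(config, "run_config")) config <- validate_config(config)
  genes <- unique(studies$gene)
  m <- config$bonferroni_m %||% length(genes)
  warnings <- character(0)
  note <- function(...) warnings[[length(warnings) + 1L]] <<- sprintf(...)
  have_geno <- all(study_table_genotype_cols %in% names(studies))

  per_gene <- list()
  for (g in genes) {
    sub <- studies[studies$gene == g, , drop = FALSE]
    poly <- sub$polymorphism[1]

    est_rows <- list()
    usable <- logical(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      est <- tryCatch(study_odds_ratio(sub[i, ], config$alpha),
                      error = function(e) e)
      if (inherits(est, "error")) {
        note("gene %s, study %s: excluded (%s)", g, sub$study_id[i],
             conditionMessage(est))
        next
      }
      if (est$corrected) {
        note("gene %s, study %s: continuity correction applied", g,
             sub$study_id[i])
      }
      usable[i] <- TRUE
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        study_id = sub$study_id[i], log_or = est$log_or, se = est$se,
        or_value = est$or_value, ci_low = est$ci_low, ci_high = est$ci_high,
        corrected = est$corrected, stringsAsFactors = FALSE
      )
    }

    hwe_flags <- character(0)
    if (have_geno) {
      for (i in seq_len(nrow(sub))) {
        for (arm in c("case", "control")) {
          cts <- as.numeric(sub[i, paste0(arm, c("_AA", "_Aa", "_aa"))])
          if (any(is.na(cts)) || sum(cts) == 0) next
          ht <- hwe_test(cts)
          if (isTRUE(ht$monomorphic)) {
            note("gene %s, study %s: HWE undefined in %ss (monomorphic)",
                 g, sub$study_id[i], arm)
          } else if (ht$p_value < config$alpha) {
            flag <- sprintf("HWE deviation in %ss of %s (p = %.3g)",
                            arm, sub$study_id[i], ht$p_value)
            hwe_flags <- c(hwe_flags, flag)
            note("gene %s: %s", g, flag)
          }
        }
      }
    }

    if (length(est_rows) == 0L) {
      note("gene %s: no usable studies", g)
      next
    }
    est_df <- do.call(rbind, est_rows)
    k <- nrow(est_df)
    flags <- character(0)
    if (length(hwe_flags) > 0) flags <- c(flags, "hwe_deviation")
    if (any(est_df$corrected)) flags <- c(flags, "continuity_corrected")

    if (k < 2L) {
      note("gene %s: only %d usable study; insufficient for pooling", g, k)
      pooled <- pool_fixed_iv(est_df, config$alpha)
      per_gene[[g]] <- list(
        gene = g, polymorphism = poly, k = k, estimates = est_df,
        pooled = pooled, p_bonferroni = NA_real_,
        heterogeneity = NULL, leave_one_out = NULL, bias = NULL,
        risk = NULL, power = NA_real_, hwe_flags = hwe_flags,
        flags = c(flags, "insufficient_data")
      )
      next
    }

    het <- cochran_q(est_df)
    random <- het$p_value < config$heterogeneity_p_threshold
    pooled <- if (random) {
      pool_random_dl(est_df, config$alpha)
    } else {
      pool_mantel_haenszel(sub[usable, , drop = FALSE], config$alpha)
    }
    p_bonf <- bonferroni(pooled$p_value, m)
    loo <- withCallingHandlers(
      leave_one_out(est_df, model = if (random) "random_dl" else "fixed_iv",
                    alpha = config$alpha),
      warning = function(w) {
        note("gene %s (leave-one-out): %s", g, conditionMessage(w))
        invokeRestart("muffleWarning")
      })

    bias <- NULL
    if (k >= 3L) {
      egger <- tryCatch(egger_test(est_df), error = function(e) {
        note("gene %s: Egger test unavailable (%s)", g, conditionMessage(e))
        NULL
      })
      begg <- begg_test(est_df)
      tf <- NULL
      bias_sig <- (!is.null(egger) && egger$p_value < config$alpha) ||
        begg$p_value < config$alpha
      if (bias_sig) {
        note("gene %s: publication bias suspected; trim-and-fill applied", g)
        tf <- trim_and_fill(est_df, side = "auto", alpha = config$alpha,
                            model = if (random) "random_dl" else "fixed_iv")
        if (!tf$converged) {
          note("gene %s: trim-and-fill did not converge", g)
          flags <- c(flags, "trim_fill_nonconvergence")
        }
        flags <- c(flags, "publication_bias")
      }
      bias <- structure(list(egger = egger, begg = begg, trim_fill = tf),
                        class = "bias_assessment")
    } else {
      note("gene %s: k = %d too small for publication-bias diagnostics", g, k)
    }

    risk <- pre_to_post(config$pre_test_risk, pooled$or_value)
    power <- if (is.null(config$power_delta)) NA_real_ else {
      power_approximation(config$power_delta, pooled$pooled_se, config$alpha)
    }

    per_gene[[g]] <- list(
      gene = g, polymorphism = poly, k = k, estimates = est_df,
      pooled = pooled, p_bonferroni = p_bonf, heterogeneity = het,
      leave_one_out = loo, bias = bias, risk = risk, power = power,
      hwe_flags = hwe_flags, flags = flags
    )
  }

  structure(list(config = config, per_gene = per_gene, warnings = warnings),
            class = "analysis_run")
}

#' Stratified analysis over a metadata column
#'
#' Splits the collection by the values of a metadata column and runs
#' [run_analysis()] per stratum. Studies lacking the key are grouped under
#' an explicit `"unknown"` stratum.
#'
#' @inheritParams run_analysis
#' @param stratify_by name of a metadata column present in the collection.
#' @return A named list of `analysis_run` objects, one per stratum.
#' @export
stratified_analysis <- function(studies, stratify_by, config = run_config()) {
  studies <- validate_study_table(as.data.frame(studies))
  if (!stratify_by %in% names(studies)) {
    stopf("stratification key '%s' is present in no study", stratify_by)
  }
  vals <- as.character(studies[[stratify_by]])
  vals[is.na(vals) | vals == ""] <- "unknown"
  lapply(split(studies, vals), run_analysis, config = config)
}

#' Build the per-polymorphism report table
#'
#' One row per analysed gene: pooled OR and CI (two decimals, matching
#' conventional summary-table presentation), Z and p, Bonferroni-adjusted
#' p, heterogeneity (Q, I-squared, tau-squared), bias diagnostics (Egger
#' and Begg p-values, trim-and-fill k0), power, and the post-test risk at
#' the configured pre-test risk. Genes with insufficient data keep their
#' OR row but carry `NA` post-test risk and an `insufficient_data` flag,
#' mirroring the dash convention of published summary tables. Full
#' precision is retained in the `analysis_run` object and its JSON sidecar;
#' this table is the rounded presentation surface.
#'
#' @param run an `analysis_run` from [run_analysis()].
#' @return A data frame with columns `gene polymorphism k model OR ci_low
#'   ci_high z p p_bonferroni Q I2 tau2 egger_p begg_p k0 power post_risk
#'   flags`.
#' @export
build_report <- function(run) {
  if (!inherits(run, "analysis_run")) stopf("run must be an analysis_run")
  if (length(run$per_gene) == 0L) stopf("the analysis contains no gene results")
  rows <- lapply(run$per_gene, function(gr) {
    pooled <- gr$pooled
    insufficient <- "insufficient_data" %in% gr$flags
    data.frame(
      gene = gr$gene,
      polymorphism = gr$polymorphism,
      k = gr$k,
      model = pooled$model,
      OR = round_half_up(pooled$or_value, 2),
      ci_low = round_half_up(pooled$ci_low, 2),
      ci_high = round_half_up(pooled$ci_high, 2),
      z = if (insufficient) NA_real_ else round_half_up(pooled$z, 3),
      p = if (insufficient) NA_real_ else pooled$p_value,
      p_bonferroni = gr$p_bonferroni,
      Q = if (is.null(gr$heterogeneity)) NA_real_ else gr$heterogeneity$q,
      I2 = if (is.null(gr$heterogeneity)) NA_real_ else gr$heterogeneity$i2,
      tau2 = if (insufficient) NA_real_ else pooled$tau2,
      egger_p = if (is.null(gr$bias) || is.null(gr$bias$egger)) NA_real_
                else gr$bias$egger$p_value,
      begg_p = if (is.null(gr$bias)) NA_real_ else gr$bias$begg$p_value,
      k0 = if (is.null(gr$bias) || is.null(gr$bias$trim_fill)) NA_integer_
           else gr$bias$trim_fill$k0,
      power = gr$power,
      post_risk = if (is.null(gr$risk)) NA_real_
                  else round_half_up(gr$risk$post_test_risk, 2),
      flags = paste(gr$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the analysis report to disk
#'
#' Writes the rounded report table as TSV plus a full-precision JSON
#' sidecar (per-gene pooled estimates, heterogeneity, bias diagnostics,
#' risk conversion and warnings).
#'
#' @param run an `analysis_run`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "report.tsv")
  json <- file.path(dir, "report.json")
  utils::write.table(build_report(run), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    config = unclass(run$config),
    per_gene = lapply(run$per_gene, function(gr) {
      list(
        gene = gr$gene, polymorphism = gr$polymorphism, k = gr$k,
        estimates = gr$estimates,
        pooled = unclass(gr$pooled),
        p_bonferroni = gr$p_bonferroni,
        heterogeneity = if (is.null(gr$heterogeneity)) NULL
                        else unclass(gr$heterogeneity),
        bias = if (is.null(gr$bias)) NULL else list(
          egger = if (is.null(gr$bias$egger)) NULL else unclass(gr$bias$egger),
          begg = unclass(gr$bias$begg),
          trim_fill = if (is.null(gr$bias$trim_fill)) NULL else list(
            k0 = gr$bias$trim_fill$k0,
            side = gr$bias$trim_fill$side,
            converged = gr$bias$trim_fill$converged,
            adjusted = unclass(gr$bias$trim_fill$adjusted)
          )
        ),
        risk = if (is.null(gr$risk)) NULL else unclass(gr$risk),
        power = gr$power,
        flags = gr$flags
      )
    }),
    warnings = run$warnings
  )
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' @export
print.analysis_run <- function(x, ...) {
  cat(sprintf("Meta-analytic validation run: %d gene(s), %d warning(s)\n",
              length(x$per_gene), length(x$warnings)))
  print(build_report(x))
  invisible(x)
}
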