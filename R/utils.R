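`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x, open = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
}

# Run `code` under `seed`, restoring the caller's RNG state afterwards so
# generators are pure functions of their configuration.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce the accepted effect-estimate representations (a single
# effect_estimate, a list of them, or a data frame with log_or/se columns)
# to a plain data frame with columns study_id, log_or, se.
as_estimates <- function(estimates) {
  if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    if (!all(c("log_or", "se") %in% names(estimates))) {
      stopf("estimate data frame must have columns 'log_or' and 'se'")
    }
    if (nrow(estimates) == 0L) stopf("at least one effect estimate is required")
    df <- data.frame(
      study_id = if ("study_id" %in% names(estimates)) {
        as.character(estimates$study_id)
      } else {
        paste0("study_", seq_len(nrow(estimates)))
      },
      log_or = as.numeric(estimates$log_or),
      se = as.numeric(estimates$se),
      stringsAsFactors = FALSE
    )
  } else if (is.list(estimates)) {
    if (!all(vapply(estimates, inherits, logical(1), "effect_estimate"))) {
      stopf("expected effect_estimate objects or a data frame of estimates")
    }
    df <- data.frame(
      study_id = names(estimates) %||% paste0("study_", seq_along(estimates)),
      log_or = vapply(estimates, function(e) e$log_or, numeric(1)),
      se = vapply(estimates, function(e) e$se, numeric(1)),
      stringsAsFactors = FALSE
    )
    if (any(df$study_id == "")) {
      df$study_id <- paste0("study_", seq_along(estimates))
    }
  } else {
    stopf("unsupported estimate input of class '%s'", class(estimates)[1])
  }
  if (nrow(df) == 0L) stopf("at least one effect estimate is required")
  if (any(!is.finite(df$log_or))) stopf("non-finite log odds ratio in estimates")
  if (any(!is.finite(df$se)) || any(df$se <= 0)) {
    stopf("all standard errors must be finite and > 0")
  }
  df
}

# Coerce contingency-table representations (contingency_table, list of them,
# numeric length-4 vector, or a data frame / study table with the four count
# columns) to a data frame of a/b/c/d cells.
as_tables <- function(tables) {
  cols <- c("case_risk", "case_other", "control_risk", "control_other")
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  if (is.numeric(tables) && length(tables) == 4L) {
    tables <- list(do.call(contingency_table, as.list(tables)))
  }
  if (is.data.frame(tables)) {
    if (!all(cols %in% names(tables))) {
      stopf("table data frame must have columns %s", paste(cols, collapse = ", "))
    }
    df <- as.data.frame(tables[cols])
  } else if (is.list(tables)) {
    if (!all(vapply(tables, inherits, logical(1), "contingency_table"))) {
      stopf("expected contingency_table objects or a data frame of counts")
    }
    df <- do.call(rbind, lapply(tables, function(tb) as.data.frame(tb[cols])))
  } else {
    stopf("unsupported table input of class '%s'", class(tables)[1])
  }
  if (nrow(df) == 0L) stopf("at least one contingency table is required")
  for (cl in cols) {
    if (any(!is.finite(df[[cl]]) | df[[cl]] < 0 | df[[cl]] != round(df[[cl]]))) {
      stopf("column '%s' must contain non-negative integer counts", cl)
    }
  }
  df
}

round_half_up <- function(x, digits = 2L) {
  # report-time rounding: conventional half-up, as printed summary tables use
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
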