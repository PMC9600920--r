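#' @importFrom stats quantile rbeta rbinom rexp rnbinom runif setNames var
#' @importFrom utils read.csv write.csv
NULL

T_STAGES <- c("T1", "T2", "T3", "T4")

#' Default CSV column mapping for cohort tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names in an input CSV.  Override individual entries to ingest files with
#' different headers.
#'
#' @return named character vector (canonical name -> column name).
#' @export
cohort_schema <- function() {
  c(patient_id = "patient_id", t_stage = "t_stage",
    nodes_examined = "nodes_examined", nodes_positive = "nodes_positive",
    survival_months = "survival_months", event = "event")
}

new_cohort <- function(records, exclusion_log, provenance = "") {
  structure(list(records = records, exclusion_log = exclusion_log,
                 provenance = provenance), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d patients (%d excluded at ingest)%s\n",
              nrow(x$records), nrow(x$exclusion_log),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  if (nrow(x$records)) {
    tab <- table(factor(x$records$t_stage, levels = T_STAGES))
    cat("  T stage:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a patient-level cohort CSV
#'
#' Reads one row per patient with T stage, examined/positive node counts and
#' survival outcome.  Rows violating basic invariants (unparseable stage,
#' negative counts, `nodes_positive > nodes_examined`, bad event code) are
#' routed to the exclusion log with a named rule — never silently dropped.
#'
#' @param path CSV file path (header required).
#' @param schema column mapping as produced by [cohort_schema()].
#' @param provenance free-text source tag stored on the table.
#' @return a `cohort_table`: list with `records` (data.frame),
#'   `exclusion_log` (data.frame of patient_id, rule), `provenance`.
#' @export
read_cohort <- function(path, schema = cohort_schema(), provenance = path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(schema, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(
    patient_id = as.character(raw[[schema[["patient_id"]]]]),
    t_stage = toupper(trimws(as.character(raw[[schema[["t_stage"]]]]))),
    nodes_examined = suppressWarnings(as.integer(raw[[schema[["nodes_examined"]]]])),
    nodes_positive = suppressWarnings(as.integer(raw[[schema[["nodes_positive"]]]])),
    survival_months = suppressWarnings(as.numeric(raw[[schema[["survival_months"]]]])),
    event = suppressWarnings(as.integer(raw[[schema[["event"]]]])),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), schema)
  for (cl in extra) df[[cl]] <- as.character(raw[[cl]])
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id values in cohort file", call. = FALSE)

  rule <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    hit <- is.na(rule) & cond
    rule[hit] <<- why
  }
  bad(!(df$t_stage %in% T_STAGES), "unstageable")
  bad(is.na(df$nodes_examined) | df$nodes_examined < 0, "bad_nodes_examined")
  bad(is.na(df$nodes_positive) | df$nodes_positive < 0, "bad_nodes_positive")
  bad(!is.na(df$nodes_positive) & !is.na(df$nodes_examined) &
        df$nodes_positive > df$nodes_examined, "positive>examined")
  bad(is.na(df$survival_months) | df$survival_months < 0, "bad_survival")
  bad(!(df$event %in% c(0L, 1L)), "bad_event")

  keep <- is.na(rule)
  excl <- data.frame(patient_id = df$patient_id[!keep], rule = rule[!keep],
                     stringsAsFactors = FALSE)
  new_cohort(df[keep, , drop = FALSE], excl, provenance)
}

#' Validate a cohort for nodal-staging analysis
#'
#' Retains only records with a known T stage, at least one examined lymph
#' node, and a non-missing survival outcome.  Patients with zero examined
#' nodes carry no information about nodal status (the miss probability is 1
#' and the false-negative imputation is undefined there), so they are
#' excluded up front.
#'
#' @param cohort a `cohort_table`.
#' @return a filtered `cohort_table`; exclusions appended to the log with
#'   rule names.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$records
  rule <- rep(NA_character_, nrow(df))
  mark <- function(cond, why) { hit <- is.na(rule) & cond; rule[hit] <<- why }
  mark(!(df$t_stage %in% T_STAGES), "unstageable")
  mark(df$nodes_examined < 1, "no_nodes_examined")
  mark(is.na(df$survival_months) | is.na(df$event), "no_followup")
  keep <- is.na(rule)
  excl <- rbind(cohort$exclusion_log,
                data.frame(patient_id = df$patient_id[!keep],
                           rule = rule[!keep], stringsAsFactors = FALSE))
  if (!any(keep)) stop("no analyzable records after validation", call. = FALSE)
  new_cohort(df[keep, , drop = FALSE], excl, cohort$provenance)
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()] under the default schema (round-trip identity).
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tally node-positive / node-negative patients per (stage, examined-count)
#'
#' Builds the strata consumed by the false-negative imputation: for every
#' observed combination of T stage and examined-node count, the number of
#' patients with at least one positive node and the number with none.
#'
#' @param cohort a validated `cohort_table`.
#' @return data.frame with columns `t_stage`, `nodes_examined`, `n_positive`,
#'   `n_negative`; rows partition the cohort.
#' @export
stratify_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$records
  pos <- df$nodes_positive >= 1
  agg <- stats::aggregate(cbind(n_positive = pos, n_negative = !pos),
                          by = list(t_stage = df$t_stage,
                                    nodes_examined = df$nodes_examined),
                          FUN = sum)
  agg <- agg[order(agg$t_stage, agg$nodes_examined), , drop = FALSE]
  rownames(agg) <- NULL
  agg$n_positive <- as.integer(agg$n_positive)
  agg$n_negative <- as.integer(agg$n_negative)
  agg
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cross-tabulate cohort characteristics by nodal status
#'
#' Produces a characteristics table split into LN-negative and LN-positive
#' columns: counts with within-column percentages (rounded half-up to one
#' decimal) for T stage and any additional categorical columns carried on the
#' records.
#'
#' @param cohort a validated `cohort_table`.
#' @param variables character vector of record columns to tabulate
#'   (default: `t_stage` plus any extra character columns present).
#' @return data.frame with columns `variable`, `level`, `ln_negative`,
#'   `ln_positive` (counts), `pct_negative`, `pct_positive`, and formatted
#'   `cell_negative`, `cell_positive` like `"98 (50.8)"`.
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$records
  core <- names(cohort_schema())
  if (is.null(variables)) {
    extras <- setdiff(names(df), core)
    extras <- extras[vapply(df[extras], is.character, TRUE)]
    variables <- c("t_stage", extras)
  }
  pos <- df$nodes_positive >= 1
  n_neg <- sum(!pos); n_pos <- sum(pos)
  rows <- lapply(variables, function(v) {
    lv <- sort(unique(df[[v]]))
    if (v == "t_stage") lv <- intersect(T_STAGES, lv)
    cn <- vapply(lv, function(l) sum(!pos & df[[v]] == l), 0L)
    cp <- vapply(lv, function(l) sum(pos & df[[v]] == l), 0L)
    data.frame(variable = v, level = lv, ln_negative = cn, ln_positive = cp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_negative <- round_half_up(100 * out$ln_negative / max(n_neg, 1), 1)
  out$pct_positive <- round_half_up(100 * out$ln_positive / max(n_pos, 1), 1)
  out$cell_negative <- sprintf("%d (%.1f)", out$ln_negative, out$pct_negative)
  out$cell_positive <- sprintf("%d (%.1f)", out$ln_positive, out$pct_positive)
  attr(out, "n_negative") <- n_neg
  attr(out, "n_positive") <- n_pos
  attr(out, "n_total") <- n_neg + n_pos
  rownames(out) <- NULL
  out
}
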