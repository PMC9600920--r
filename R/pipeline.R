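#' Pipeline configuration
#'
#' Single configuration list governing every stage of [run_pipeline()].
#'
#' @param truncated zero-truncated likelihood for fitting (default TRUE).
#' @param prevalence_source prevalence entering the NSS: `"adjusted"`
#'   (default) or `"apparent"`.
#' @param quantile_mode `"empirical"` (stage-specific quartile cutoffs,
#'   default) or `"fixed"` (0.25/0.5/0.75).
#' @param n_max NSS curve length (default 90).
#' @param nss_target score threshold for the minimal-node lookup.
#' @param n_boot bootstrap replicates (0 disables the bootstrap stage).
#' @param seed integer seed for the bootstrap.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(truncated = TRUE,
                            prevalence_source = c("adjusted", "apparent"),
                            quantile_mode = c("empirical", "fixed"),
                            n_max = 90, nss_target = 0.8,
                            n_boot = 1000, seed = 1L) {
  structure(list(truncated = truncated,
                 prevalence_source = match.arg(prevalence_source),
                 quantile_mode = match.arg(quantile_mode),
                 n_max = as.integer(n_max), nss_target = nss_target,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full nodal-staging pipeline
#'
#' validate -> stratify -> fit (per stage) -> prevalence adjustment -> NSS
#' curves -> minimal-node lookup -> quantile-group assignment -> survival by
#' group -> (optional) bootstrap CIs.  Stages that cannot be fitted (no
#' node-positive patients, degenerate fit) are skipped with a warning and
#' the rest complete.  Deterministic given (input, config).
#'
#' @param cohort a `cohort_table` (raw or validated) or a CSV path.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all artifacts plus a run
#'   manifest are written there (see [export_tables()]).
#' @return list with `cohort`, `strata`, `params` (per stage), `prevalence`,
#'   `curves`, `min_nodes`, `assignments`, `survival`, `warnings`, and
#'   `manifest` when `out_dir` is given.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  warnings_seen <- character()
  note <- function(...) warnings_seen <<- c(warnings_seen, sprintf(...))

  cohort <- validate_cohort(cohort)
  strata <- stratify_counts(cohort)

  params <- list()
  for (s in intersect(T_STAGES, unique(cohort$records$t_stage))) {
    sub <- cohort$records[cohort$records$t_stage == s, ]
    pos <- sub[sub$nodes_positive >= 1, ]
    if (nrow(pos) < 2) {
      note("stage %s skipped: fewer than 2 node-positive patients", s)
      next
    }
    ft <- tryCatch(
      fit_beta_binomial(pos$nodes_examined, pos$nodes_positive, t_stage = s,
                        truncated = config$truncated),
      error = function(e) NULL)
    if (is.null(ft) || ft$degenerate) {
      note("stage %s skipped: degenerate or failed fit", s)
      next
    }
    params[[s]] <- ft
  }
  if (!length(params)) stop("no stage could be fitted", call. = FALSE)

  prevalence <- withCallingHandlers(
    adjusted_prevalence(strata[strata$t_stage %in% names(params), ], params),
    warning = function(w) { note("%s", conditionMessage(w))
      invokeRestart("muffleWarning") })

  curves <- lapply(setNames(names(params), names(params)), function(s) {
    pv <- prevalence[prevalence$t_stage == s,
                     if (config$prevalence_source == "adjusted") "adjusted"
                     else "apparent"]
    nss_curve(params[[s]], pv, n_max = config$n_max)
  })
  min_nodes <- vapply(curves, min_nodes_for_score,
                      integer(1), target = config$nss_target)

  assignments <- assign_quantile_groups(cohort, curves,
                                        mode = config$quantile_mode)
  surv <- withCallingHandlers(
    survival_by_nss_group(cohort, assignments),
    warning = function(w) { note("%s", conditionMessage(w))
      invokeRestart("muffleWarning") })

  if (config$n_boot > 0) {
    for (s in names(params)) {
      params[[s]] <- tryCatch(
        bootstrap_params(cohort, s, n_boot = config$n_boot,
                         seed = config$seed),
        error = function(e) { note("bootstrap failed for stage %s: %s", s,
                                   conditionMessage(e)); params[[s]] })
    }
  }

  res <- list(cohort = cohort, strata = strata, params = params,
              prevalence = prevalence, curves = curves,
              min_nodes = min_nodes, assignments = assignments,
              survival = surv, config = config, warnings = warnings_seen)
  if (!is.null(out_dir)) res$manifest <- export_tables(res, out_dir)
  res
}

#' Export pipeline results as plain-text tables with a run manifest
#'
#' Writes a parameter table (stage, alpha and beta with 95% CIs, 7
#' significant digits), a prevalence table (stage, apparent, adjusted,
#' rounded to 3 decimals), the NSS curves, the per-patient assignments, the
#' per-stage survival exports, and a JSON manifest listing every artifact
#' with an md5 content digest.
#'
#' @param results a [run_pipeline()] result list.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a list, invisibly written to `manifest.json`.
#' @export
export_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(name) { p <- file.path(out_dir, name); paths <<- c(paths, p); p }

  fmt7 <- function(x) signif(x, 7)
  par_tab <- do.call(rbind, lapply(results$params, function(p) data.frame(
    t_stage = p$t_stage, alpha = fmt7(p$alpha),
    alpha_low = if (is.null(p$alpha_ci)) NA else fmt7(p$alpha_ci[1]),
    alpha_high = if (is.null(p$alpha_ci)) NA else fmt7(p$alpha_ci[2]),
    beta = fmt7(p$beta),
    beta_low = if (is.null(p$beta_ci)) NA else fmt7(p$beta_ci[1]),
    beta_high = if (is.null(p$beta_ci)) NA else fmt7(p$beta_ci[2]),
    n_used = p$n_used, stringsAsFactors = FALSE)))
  write.csv(par_tab, put("parameters.csv"), row.names = FALSE)
  write_bb_params(results$params, put("parameters.json"))

  prev <- results$prevalence
  prev$apparent <- round(prev$apparent, 3)
  prev$adjusted <- round(prev$adjusted, 3)
  write.csv(prev, put("prevalence.csv"), row.names = FALSE)

  curve_tab <- do.call(rbind, lapply(results$curves, as.data.frame))
  write.csv(curve_tab, put("nss_curves.csv"), row.names = FALSE)

  mn <- data.frame(t_stage = names(results$min_nodes),
                   target = results$config$nss_target,
                   min_nodes = unname(results$min_nodes))
  write.csv(mn, put("min_nodes.csv"), row.names = FALSE)

  asn <- results$assignments
  cuts <- attr(asn, "cutoffs")
  asn$q25 <- vapply(asn$t_stage, function(s) cuts[[s]][1], 0)
  asn$q50 <- vapply(asn$t_stage, function(s) cuts[[s]][2], 0)
  asn$q75 <- vapply(asn$t_stage, function(s) cuts[[s]][3], 0)
  write.csv(asn, put("nss_assignments.csv"), row.names = FALSE)

  surv_rows <- list()
  tests <- list()
  for (s in names(results$survival)) {
    st <- results$survival[[s]]
    for (g in names(st$curves)) {
      cv <- st$curves[[g]]
      cv$t_stage <- s; cv$group <- g
      surv_rows[[paste(s, g)]] <- cv
    }
    if (!is.null(st$test))
      tests[[s]] <- list(statistic = st$test$statistic, df = st$test$df,
                         p_value = st$test$p_value)
  }
  write.csv(do.call(rbind, surv_rows), put("survival_curves.csv"),
            row.names = FALSE)
  jsonlite::write_json(tests, put("logrank_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    provenance = results$cohort$provenance,
    n_patients = nrow(results$cohort$records),
    config = unclass(results$config),
    warnings = results$warnings,
    artifacts = lapply(setNames(paths, basename(paths)),
                       function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
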