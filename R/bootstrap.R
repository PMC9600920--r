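#' Bootstrap confidence intervals for the stage parameters
#'
#' Resamples the stage's patients with replacement (stratified: sample sizes
#' are preserved within the stage), refits the zero-truncated beta-binomial
#' on the node-positive records of each replicate, and returns percentile
#' CIs.  CI endpoints are order statistics of the replicate vector
#' (type-1 quantiles).  Replicates whose fit fails or is degenerate are
#' dropped and logged; more than 20% failures aborts.
#'
#' @param cohort a validated `cohort_table`.
#' @param t_stage stage to bootstrap.
#' @param n_boot number of bootstrap replicates (study default 1000).
#' @param seed integer seed; results are a deterministic function of
#'   (cohort, t_stage, n_boot, seed).
#' @param level confidence level (default 0.95).
#' @return a `bb_params` with `alpha_ci`/`beta_ci` filled, plus attributes
#'   `replicates` (data.frame of alpha, beta per replicate) and `n_failed`.
#' @export
bootstrap_params <- function(cohort, t_stage, n_boot = 1000, seed = 1L,
                             level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"), t_stage %in% T_STAGES,
            n_boot >= 1)
  sub <- cohort$records[cohort$records$t_stage == t_stage, ]
  pos <- sub[sub$nodes_positive >= 1, ]
  if (nrow(pos) < 2)
    stop("stage ", t_stage, " has too few node-positive patients to fit",
         call. = FALSE)
  point <- fit_beta_binomial(pos$nodes_examined, pos$nodes_positive,
                             t_stage = t_stage)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(sub), replace = TRUE)
    rb <- sub[idx, ]
    pb <- rb[rb$nodes_positive >= 1, ]
    if (nrow(pb) < 2 || all(pb$nodes_positive == pb$nodes_examined)) next
    ft <- tryCatch(
      fit_beta_binomial(pb$nodes_examined, pb$nodes_positive,
                        t_stage = t_stage, n_starts = 1),
      error = function(e) NULL)
    if (!is.null(ft) && !ft$degenerate) reps[b, ] <- c(ft$alpha, ft$beta)
  }
  ok <- stats::complete.cases(reps)
  if (mean(!ok) > 0.20)
    stop("unstable bootstrap: ", sum(!ok), " of ", n_boot,
         " replicate fits failed", call. = FALSE)
  point$alpha_ci <- .percentile_ci(reps[ok, 1], level)
  point$beta_ci <- .percentile_ci(reps[ok, 2], level)
  attr(point, "replicates") <- data.frame(alpha = reps[ok, 1],
                                          beta = reps[ok, 2])
  attr(point, "n_failed") <- sum(!ok)
  attr(point, "seed") <- seed
  point
}

# percentile CI endpoints as order statistics: x_(ceil(p*m)), with a small
# fuzz so that exact multiples of 1/m are not pushed to the next index
.percentile_ci <- function(x, level) {
  x <- sort(x)
  m <- length(x)
  idx <- function(p) min(m, max(1L, as.integer(ceiling(p * m - 1e-9))))
  c(x[idx((1 - level) / 2)], x[idx((1 + level) / 2)])
}

#' Pointwise bootstrap confidence band for an NSS curve
#'
#' Per replicate, resamples the stage's patients, refits the beta-binomial,
#' recomputes the FN-adjusted prevalence and the NSS curve; the band is the
#' pointwise percentile interval across replicates.
#'
#' @inheritParams bootstrap_params
#' @param n_max curve length.
#' @param prevalence_source `"adjusted"` (default) or `"apparent"`.
#' @return an `nss_curve` with extra columns `ci_low`, `ci_high`; attribute
#'   `n_failed`.
#' @export
bootstrap_curve_ci <- function(cohort, t_stage, n_boot = 1000, seed = 1L,
                               n_max = 90, level = 0.95,
                               prevalence_source = c("adjusted", "apparent")) {
  prevalence_source <- match.arg(prevalence_source)
  stopifnot(inherits(cohort, "cohort_table"), t_stage %in% T_STAGES)
  sub_cohort <- function(df) new_cohort(df, data.frame(
    patient_id = character(), rule = character(), stringsAsFactors = FALSE))
  one_curve <- function(df, n_starts) {
    pos <- df[df$nodes_positive >= 1, ]
    if (nrow(pos) < 2 || all(pos$nodes_positive == pos$nodes_examined))
      return(NULL)
    ft <- tryCatch(fit_beta_binomial(pos$nodes_examined, pos$nodes_positive,
                                     t_stage = t_stage, n_starts = n_starts),
                   error = function(e) NULL)
    if (is.null(ft) || ft$degenerate) return(NULL)
    strata <- stratify_counts(sub_cohort(df))
    prev <- suppressWarnings(
      adjusted_prevalence(strata, setNames(list(ft), t_stage)))
    pv <- if (prevalence_source == "adjusted") prev$adjusted else prev$apparent
    nss_curve(ft, pv, n_max = n_max)
  }
  sub <- cohort$records[cohort$records$t_stage == t_stage, ]
  point <- one_curve(sub, n_starts = 5)
  if (is.null(point))
    stop("stage ", t_stage, " cannot be fitted", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mat <- matrix(NA_real_, n_boot, n_max)
  for (b in seq_len(n_boot)) {
    cv <- one_curve(sub[sample.int(nrow(sub), replace = TRUE), ], n_starts = 1)
    if (!is.null(cv)) mat[b, ] <- cv$score
  }
  ok <- stats::complete.cases(mat)
  if (mean(!ok) > 0.20)
    stop("unstable bootstrap: ", sum(!ok), " of ", n_boot,
         " replicate fits failed", call. = FALSE)
  band <- apply(mat[ok, , drop = FALSE], 2, .percentile_ci, level = level)
  point$ci_low <- band[1, ]
  point$ci_high <- band[2, ]
  attr(point, "n_failed") <- sum(!ok)
  attr(point, "seed") <- seed
  point
}
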