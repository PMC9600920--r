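#' Impute the false-negative case count for one stratum
#'
#' Given the miss probability `p = Prob(FN | n examined, stage)` and the
#' observed node-positive count `#TP` in a (stage, examined-count) stratum,
#' the expected number of truly diseased patients hiding among the observed
#' negatives is `p * #TP / (1 - p)`.  Because imputed false negatives must
#' physically exist among the stratum's observed negatives, the value is
#' capped at `n_negative` (with a warning when the cap binds).
#'
#' @param fn_prob miss probability for the stratum (in [0, 1)).
#' @param n_positive observed node-positive patient count (#TP).
#' @param n_negative observed node-negative patient count (cap).
#' @return non-negative real, the imputed #FN.
#' @export
impute_false_negatives <- function(fn_prob, n_positive, n_negative) {
  stopifnot(fn_prob >= 0, n_positive >= 0, n_negative >= 0)
  if (fn_prob >= 1)
    stop("fn_prob must be < 1 (requires nodes_examined >= 1)", call. = FALSE)
  if (n_positive == 0) return(0)
  fn <- fn_prob * n_positive / (1 - fn_prob)
  if (fn > n_negative) {
    warning(sprintf(
      "imputed FN (%.2f) exceeds observed negatives (%d); capped", fn,
      as.integer(n_negative)), call. = FALSE)
    fn <- n_negative
  }
  fn
}

#' Apparent prevalence of nodal disease per T stage
#'
#' The observed fraction of node-positive patients among all patients of the
#' stage, before any false-negative correction.
#'
#' @param strata stratified counts from [stratify_counts()] (one or more
#'   stages).
#' @return named numeric vector, one proportion per stage present.
#' @export
apparent_prevalence <- function(strata) {
  stopifnot(all(c("t_stage", "n_positive", "n_negative") %in% names(strata)))
  stages <- intersect(T_STAGES, unique(strata$t_stage))
  out <- vapply(stages, function(s) {
    st <- strata[strata$t_stage == s, ]
    tot <- sum(st$n_positive) + sum(st$n_negative)
    if (tot == 0) stop("no patients in stage ", s, call. = FALSE)
    sum(st$n_positive) / tot
  }, 0)
  setNames(out, stages)
}

#' False-negative-adjusted prevalence of nodal disease
#'
#' For each (stage, examined-count) stratum, imputes the expected number of
#' false-negative patients from the fitted beta-binomial miss probability,
#' re-labels that many observed negatives as diseased, and recomputes the
#' stage prevalence as `sum(#TP + #FN) / sum(#TP + #TN + #FN)`.  The
#' denominator is the total patient count of the stage: false negatives are
#' re-labelled, never added, so `#TN = observed negatives - #FN` per stratum
#' and the adjusted prevalence can only exceed the apparent one.
#'
#' @param strata stratified counts from [stratify_counts()].
#' @param params a `bb_params` object (single stage) or named list of them
#'   keyed by stage.
#' @return data.frame with one row per stage: `t_stage`, `apparent`,
#'   `adjusted`, `fn_total`, `n_patients`.
#' @export
adjusted_prevalence <- function(strata, params) {
  if (inherits(params, "bb_params")) {
    params <- setNames(list(params),
                       if (is.na(params$t_stage)) unique(strata$t_stage)[1]
                       else params$t_stage)
  }
  stages <- intersect(T_STAGES, unique(strata$t_stage))
  stages <- intersect(stages, names(params))
  app <- apparent_prevalence(strata)
  rows <- lapply(stages, function(s) {
    st <- strata[strata$t_stage == s, ]
    if (any(st$nodes_examined < 1))
      stop("stratum with nodes_examined = 0 in stage ", s, call. = FALSE)
    p <- params[[s]]
    fnp <- fn_probability(p$alpha, p$beta, st$nodes_examined)
    n_capped <- 0L
    fn <- withCallingHandlers(
      mapply(impute_false_negatives, fnp, st$n_positive, st$n_negative),
      warning = function(w) { n_capped <<- n_capped + 1L
        invokeRestart("muffleWarning") })
    if (n_capped > 0)
      warning(sprintf(
        "stage %s: imputed FN capped at observed negatives in %d of %d strata",
        s, n_capped, nrow(st)), call. = FALSE)
    tot <- sum(st$n_positive) + sum(st$n_negative)
    data.frame(t_stage = s,
               apparent = app[[s]],
               adjusted = sum(st$n_positive + fn) / tot,
               fn_total = sum(fn),
               n_patients = tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
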