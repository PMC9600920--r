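#' Nodal staging score
#'
#' Probability that a patient whose examined nodes are all negative is truly
#' free of nodal disease, by Bayes' rule over the stage prevalence and the
#' miss probability:
#' `NSS = (1 - Prev) / ((1 - Prev) + Prev * ProbFN)`.
#'
#' When `fn_prob = 0` the score is defined as 1 for every prevalence
#' (perfect sensitivity: a negative exam is conclusive), which also resolves
#' the 0/0 corner at `prevalence = 1`.
#'
#' @param prevalence stage prevalence of nodal disease, in [0, 1].
#' @param fn_prob miss probability `Prob(FN | n examined, stage)`, in [0, 1].
#' @return score in (0, 1]; vectorized over both arguments.
#' @examples
#' nss_value(0.895, 1)   # n = 0: reduces to 1 - prevalence
#' nss_value(0.5, 0)     # perfect sensitivity: 1
#' @export
nss_value <- function(prevalence, fn_prob) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            all(fn_prob >= 0 & fn_prob <= 1))
  ifelse(fn_prob == 0, 1,
         (1 - prevalence) / ((1 - prevalence) + prevalence * fn_prob))
}

#' Nodal staging score curve over examined-node counts
#'
#' Evaluates the NSS at every examined-node count `n = 1..n_max` for one
#' stage.  The curve is non-decreasing in `n` and approaches 1 as the miss
#' probability vanishes.
#'
#' @param params a `bb_params` object for the stage.
#' @param prevalence stage prevalence entering the score (normally the
#'   FN-adjusted value).
#' @param n_max largest examined-node count (default 90, the registry field
#'   ceiling).
#' @return object of class `nss_curve`: data.frame with columns `t_stage`,
#'   `nodes_examined`, `fn_prob`, `score`; attributes `prevalence` and
#'   `params`.
#' @export
nss_curve <- function(params, prevalence, n_max = 90) {
  stopifnot(inherits(params, "bb_params"), n_max >= 1)
  n <- seq_len(n_max)
  fnp <- fn_probability(params$alpha, params$beta, n)
  out <- data.frame(t_stage = params$t_stage, nodes_examined = n,
                    fn_prob = fnp, score = nss_value(prevalence, fnp),
                    stringsAsFactors = FALSE)
  attr(out, "prevalence") <- prevalence
  attr(out, "params") <- params
  class(out) <- c("nss_curve", "data.frame")
  out
}

#' Minimal examined-node count attaining a target score
#'
#' Smallest `n` on the curve whose score reaches `target`; `NA_integer_`
#' when no point on the curve does (the "unreached" sentinel — extend
#' `n_max` to look further).
#'
#' @param curve an `nss_curve`.
#' @param target score threshold in (0, 1].
#' @return integer node count or `NA_integer_`.
#' @export
min_nodes_for_score <- function(curve, target) {
  stopifnot(inherits(curve, "nss_curve"), target > 0, target <= 1)
  hit <- which(curve$score >= target)
  if (!length(hit)) NA_integer_ else curve$nodes_examined[hit[1]]
}

#' Assign within-stage NSS quantile groups
#'
#' Scores every patient of a stage by (stage, examined-node count) and bins
#' the scores into four groups.  With `mode = "empirical"` (default) the
#' cutoffs are the stage's own 25/50/75 percentiles (type-7 linear
#' interpolation); with `mode = "fixed"` they are 0.25/0.5/0.75.  Intervals
#' are half-open `[low, high)` with the top group closed above, so tied
#' degenerate cutoffs send all patients to Q4 (with a warning).
#'
#' @param cohort a validated `cohort_table` (one or more stages).
#' @param curves named list of `nss_curve` keyed by stage (each covering the
#'   stage's largest examined-node count).
#' @param mode `"empirical"` or `"fixed"` cutoffs.
#' @return data.frame: `patient_id`, `t_stage`, `nodes_examined`, `score`,
#'   `group` (factor Q1-Q4); attribute `cutoffs` is a per-stage list of the
#'   (q25, q50, q75) used.
#' @export
assign_quantile_groups <- function(cohort, curves, mode = c("empirical", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$records
  stages <- intersect(T_STAGES, unique(df$t_stage))
  stages <- intersect(stages, names(curves))
  cutlist <- list()
  rows <- lapply(stages, function(s) {
    sub <- df[df$t_stage == s, ]
    if (nrow(sub) < 4)
      stop("insufficient for quartiles: stage ", s, " has ", nrow(sub),
           " patients", call. = FALSE)
    cv <- curves[[s]]
    if (max(sub$nodes_examined) > max(cv$nodes_examined))
      stop("curve for stage ", s, " does not cover nodes_examined = ",
           max(sub$nodes_examined), call. = FALSE)
    sc <- cv$score[match(sub$nodes_examined, cv$nodes_examined)]
    cuts <- if (mode == "empirical")
      unname(quantile(sc, c(0.25, 0.5, 0.75), type = 7))
    else c(0.25, 0.5, 0.75)
    if (anyDuplicated(cuts))
      warning("degenerate quantile cutoffs in stage ", s,
              "; tied scores collapse groups", call. = FALSE)
    grp <- factor(paste0("Q", findInterval(sc, cuts) + 1L),
                  levels = paste0("Q", 1:4))
    cutlist[[s]] <<- cuts
    data.frame(patient_id = sub$patient_id, t_stage = s,
               nodes_examined = sub$nodes_examined, score = sc, group = grp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cutoffs") <- cutlist
  attr(out, "mode") <- mode
  out
}
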