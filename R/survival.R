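#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator over distinct event times, computed through
#' [survival::survfit()].  Ties between deaths and censorings at the same
#' time follow the standard convention (deaths processed first).
#'
#' @param time survival times in months (>= 0).
#' @param event 1 = death, 0 = censored.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (step-function values at the listed times; S = 1 before the
#'   first listed time).
#' @examples
#' km_estimate(c(5, 10, 15), c(0, 1, 1))
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square on `k - 1` degrees of freedom via
#' [survival::survdiff()], with the p-value from the upper chi-square tail.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p_value`, `n` (per-group sizes).
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2)
    stop("log-rank test requires at least 2 non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(group))
}

#' Survival curves and log-rank test by NSS quantile group, per stage
#'
#' Joins NSS group assignments back to the cohort and, within each T stage,
#' estimates one Kaplan-Meier curve per non-empty quantile group and runs the
#' k-group log-rank test.  Groups with zero patients are dropped with a
#' warning; stages with a single non-empty group return curves but no test.
#'
#' @param cohort a validated `cohort_table`.
#' @param assignments output of [assign_quantile_groups()].
#' @return named list per stage, each a list with `curves` (named list of
#'   [km_estimate()] data.frames keyed by group), `test` (list or NULL), and
#'   `n` (per-group counts).
#' @export
survival_by_nss_group <- function(cohort, assignments) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- merge(cohort$records[, c("patient_id", "survival_months", "event")],
              assignments, by = "patient_id")
  out <- list()
  for (s in intersect(T_STAGES, unique(df$t_stage))) {
    sub <- df[df$t_stage == s, ]
    tab <- table(factor(sub$group, levels = paste0("Q", 1:4)))
    empty <- names(tab)[tab == 0]
    if (length(empty))
      warning("stage ", s, ": dropping empty NSS group(s) ",
              paste(empty, collapse = ", "), call. = FALSE)
    present <- names(tab)[tab > 0]
    curves <- lapply(setNames(present, present), function(g) {
      gg <- sub[sub$group == g, ]
      km_estimate(gg$survival_months, gg$event)
    })
    test <- if (length(present) >= 2)
      logrank_test(sub$survival_months, sub$event, sub$group)
    else NULL
    out[[s]] <- list(curves = curves, test = test, n = tab[present])
  }
  out
}
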