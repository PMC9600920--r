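#' Configuration for the synthetic GSRCC cohort generator
#'
#' Defaults emulate a SEER-scale gastric signet ring cell carcinoma cohort:
#' stage mix 116/60/176/209 (of 561), stage-specific nodal-disease prevalence
#' 0.155/0.583/0.727/0.895, beta-binomial intensity parameters on the scale
#' of published stage-specific fits, examined-node counts distributed as
#' 1 + NegBinomial(mean 14, dispersion 1.2) capped at 90, and exponential
#' survival with a hazard ratio of 2 for truly node-diseased patients plus
#' independent exponential censoring and an administrative cutoff.
#'
#' @param n_patients cohort size.
#' @param stage_mix probabilities of T1-T4 (sum to 1).
#' @param prevalence per-stage true nodal-disease prevalence.
#' @param alpha,beta per-stage beta-binomial parameters.
#' @param nodes_mu,nodes_size mean and dispersion of the negative-binomial
#'   part of the examined-node distribution.
#' @param nodes_max cap on examined nodes.
#' @param base_hazard monthly death hazard for truly node-negative patients.
#' @param hazard_ratio multiplicative hazard for truly diseased patients.
#' @param censor_rate monthly hazard of independent censoring.
#' @param cutoff_months administrative censoring time.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_patients = 561,
                       stage_mix = c(116, 60, 176, 209) / 561,
                       prevalence = c(T1 = 0.155, T2 = 0.583,
                                      T3 = 0.727, T4 = 0.895),
                       alpha = c(T1 = 0.06938207, T2 = 0.42578161,
                                 T3 = 0.48686973, T4 = 0.80543434),
                       beta = c(T1 = 1.8877199, T2 = 2.2180490,
                                T3 = 1.2430379, T4 = 0.8710085),
                       nodes_mu = 14, nodes_size = 1.2, nodes_max = 90,
                       base_hazard = 0.010, hazard_ratio = 2,
                       censor_rate = 0.006, cutoff_months = 120) {
  cfg <- list(n_patients = as.integer(n_patients),
              stage_mix = unname(stage_mix),
              prevalence = setNames(unname(prevalence), T_STAGES),
              alpha = setNames(unname(alpha), T_STAGES),
              beta = setNames(unname(beta), T_STAGES),
              nodes_mu = nodes_mu, nodes_size = nodes_size,
              nodes_max = as.integer(nodes_max),
              base_hazard = base_hazard, hazard_ratio = hazard_ratio,
              censor_rate = censor_rate, cutoff_months = cutoff_months)
  stopifnot(cfg$n_patients >= 1,
            length(cfg$stage_mix) == 4,
            abs(sum(cfg$stage_mix) - 1) < 1e-9,
            all(cfg$stage_mix >= 0),
            all(cfg$prevalence >= 0 & cfg$prevalence <= 1),
            all(cfg$alpha > 0), all(cfg$beta > 0),
            cfg$nodes_mu > 0, cfg$nodes_size > 0, cfg$nodes_max >= 1,
            cfg$base_hazard > 0, cfg$hazard_ratio > 0, cfg$censor_rate > 0,
            cfg$cutoff_months > 0)
  structure(cfg, class = "sim_config")
}

# pmf of the examined-node distribution 1 + NB(mu, size) capped at nodes_max
.nodes_pmf <- function(config) {
  n <- seq_len(config$nodes_max)
  w <- stats::dnbinom(n - 1L, size = config$nodes_size, mu = config$nodes_mu)
  w[config$nodes_max] <- w[config$nodes_max] +
    stats::pnbinom(config$nodes_max - 1L, size = config$nodes_size,
                   mu = config$nodes_mu, lower.tail = FALSE)
  setNames(w, n)
}

#' Simulate a synthetic GSRCC cohort with ground truth
#'
#' For each patient: draw a T stage from the mix; draw an examined-node
#' count; draw true nodal disease Bernoulli(stage prevalence); if diseased,
#' draw a latent node-positivity propensity p ~ Beta(alpha, beta) and the
#' positive-node count Binomial(n, p) — a diseased patient with zero observed
#' positives is a false negative; non-diseased patients always observe zero
#' positives (no false positives).  Survival is exponential with the
#' stage-independent base hazard, doubled (by default) for truly diseased
#' patients, censored at the minimum of an independent exponential draw and
#' the administrative cutoff.
#'
#' Each patient draws from a private RNG substream derived from `seed` and
#' the patient index, so enlarging the cohort never reshuffles earlier
#' patients.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the cohort is a deterministic function of
#'   (config, seed).
#' @return list with `cohort` (a `cohort_table`) and `truth` (data.frame:
#'   `patient_id`, `t_stage`, `diseased`, `propensity`, `false_negative`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  stage <- character(n); nodes <- integer(n); kpos <- integer(n)
  diseased <- logical(n); prop <- rep(NA_real_, n)
  stime <- numeric(n); event <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n)) {
    set.seed((as.numeric(seed) * 48271 + i * 1013904223) %% 2147483647)
    stage[i] <- sample(T_STAGES, 1L, prob = config$stage_mix)
    nodes[i] <- min(1L + stats::rnbinom(1L, size = config$nodes_size,
                                        mu = config$nodes_mu), config$nodes_max)
    diseased[i] <- stats::runif(1L) < config$prevalence[[stage[i]]]
    if (diseased[i]) {
      prop[i] <- stats::rbeta(1L, config$alpha[[stage[i]]],
                              config$beta[[stage[i]]])
      kpos[i] <- stats::rbinom(1L, nodes[i], prop[i])
    }
    rate <- config$base_hazard * if (diseased[i]) config$hazard_ratio else 1
    t_death <- stats::rexp(1L, rate)
    t_cens <- min(stats::rexp(1L, config$censor_rate), config$cutoff_months)
    event[i] <- as.integer(t_death <= t_cens)
    stime[i] <- round(min(t_death, t_cens), 3)
  }
  ids <- sprintf("P%06d", seq_len(n))
  cohort <- new_cohort(
    data.frame(patient_id = ids, t_stage = stage, nodes_examined = nodes,
               nodes_positive = kpos, survival_months = stime, event = event,
               stringsAsFactors = FALSE),
    data.frame(patient_id = character(), rule = character(),
               stringsAsFactors = FALSE),
    provenance = sprintf("synthetic (seed %d)", seed))
  truth <- data.frame(patient_id = ids, t_stage = stage, diseased = diseased,
                      propensity = prop, false_negative = diseased & kpos == 0L,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Expected observed node-positive fraction under a generator configuration
#'
#' Closed-form expectation combining the miss probability with the
#' examined-node distribution:
#' `Prev_true * (1 - sum_n w(n) * B(alpha, beta+n)/B(alpha, beta))`, the
#' exact expected fraction of patients observed node-positive in a simulated
#' stage.  Serves as the analytic oracle for the generator.
#'
#' @param config a `sim_config`.
#' @param t_stage stage label.
#' @return proportion in [0, 1].
#' @export
expected_observed_prevalence <- function(config, t_stage) {
  stopifnot(inherits(config, "sim_config"), t_stage %in% T_STAGES)
  w <- .nodes_pmf(config)
  n <- as.integer(names(w))
  miss <- fn_probability(config$alpha[[t_stage]], config$beta[[t_stage]], n)
  config$prevalence[[t_stage]] * (1 - sum(w * miss))
}
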