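# Reference stage-specific beta-binomial parameters and LN-status stage
# counts from a published SEER GSRCC cohort (n = 561), shipped as fixtures.

ref_params <- function() {
  read_bb_params(system.file("extdata", "gsrcc_reference_params.json",
                             package = "nodalstaging"))
}

ref_stage_counts <- function() {
  read.csv(system.file("extdata", "gsrcc_stage_counts.csv",
                       package = "nodalstaging"), stringsAsFactors = FALSE)
}

# Table-1-derived prevalence per stage (positive / total)
ref_prevalence <- function() {
  sc <- ref_stage_counts()
  setNames(sc$ln_positive / (sc$ln_negative + sc$ln_positive), sc$t_stage)
}

# build a cohort_table by round-tripping a data.frame through the CSV reader
cohort_from_df <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  read_cohort(path)
}

# minimal well-formed patient rows
patient_rows <- function(n, t_stage = "T3", nodes_examined = 10,
                         nodes_positive = 0, survival_months = 24, event = 0,
                         id_offset = 0) {
  data.frame(patient_id = sprintf("id%04d", id_offset + seq_len(n)),
             t_stage = t_stage, nodes_examined = nodes_examined,
             nodes_positive = nodes_positive,
             survival_months = survival_months, event = event,
             stringsAsFactors = FALSE)
}

# strata table from per-stage (positive, negative) totals, one stratum each
strata_from_counts <- function(counts, nodes_examined = 10) {
  data.frame(t_stage = counts$t_stage, nodes_examined = nodes_examined,
             n_positive = counts$ln_positive, n_negative = counts$ln_negative,
             stringsAsFactors = FALSE)
}

# draw node-positive beta-binomial observations by rejection
draw_node_positive <- function(n_obs, alpha, beta, n_range = 5:40) {
  n <- integer(0); k <- integer(0)
  while (length(n) < n_obs) {
    m <- 2L * (n_obs - length(n)) + 10L
    nn <- sample(n_range, m, replace = TRUE)
    kk <- rbinom(m, nn, rbeta(m, alpha, beta))
    keep <- kk >= 1
    n <- c(n, nn[keep]); k <- c(k, kk[keep])
  }
  list(n = n[seq_len(n_obs)], k = k[seq_len(n_obs)])
}
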