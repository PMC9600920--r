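test_that("score corner cases follow the Bayes form", {
  expect_equal(nss_value(0.3, 0), 1)
  expect_equal(nss_value(1, 0), 1)           # perfect-sensitivity guard
  expect_equal(nss_value(0.895, 1), 0.105)   # n = 0 reduces to 1 - Prev
  p <- ref_params()$T1
  expect_equal(nss_value(18 / 116, fn_probability(p$alpha, p$beta, 1)),
               0.8495008, tolerance = 1e-6)
})

test_that("score decreases in miss probability and in prevalence", {
  prevs <- seq(0.05, 0.95, by = 0.15)
  fns <- seq(0.05, 0.95, by = 0.15)
  for (pv in prevs) expect_true(all(diff(nss_value(pv, fns)) < 0))
  for (f in fns) expect_true(all(diff(nss_value(prevs, f)) < 0))
})

test_that("curves rise monotonically for all stages and both prevalence readings", {
  p <- ref_params()
  prev_tab1 <- ref_prevalence()
  prev_alt <- c(T1 = 0.173, T2 = 0.690, T3 = 0.807, T4 = 0.941)
  for (s in names(p)) for (pv in c(prev_tab1[s], prev_alt[s])) {
    cv <- nss_curve(p[[s]], pv, n_max = 90)
    expect_true(all(diff(cv$score) > 0))
    expect_true(all(cv$score > 0 & cv$score <= 1))
  }
})

test_that("minimal-node lookup agrees with a linear scan", {
  p <- ref_params()
  cv <- nss_curve(p$T2, 0.583, n_max = 90)
  expect_equal(min_nodes_for_score(cv, cv$score[1] / 2), 1L)
  expect_true(is.na(min_nodes_for_score(cv, 1.0)))
  t1 <- nss_curve(p$T1, 18 / 116, n_max = 90)
  expect_equal(min_nodes_for_score(t1, 0.8), 1L)  # whole T1 curve above 0.8
  set.seed(8)
  for (tg in runif(100, 0.2, 1)) {
    scan <- which(cv$score >= tg)
    want <- if (length(scan)) cv$nodes_examined[scan[1]] else NA_integer_
    expect_identical(min_nodes_for_score(cv, tg), want)
  }
})

test_that("quantile groups partition patients with recorded cutoffs", {
  # eight distinct examined-node counts give eight distinct scores
  df <- patient_rows(8, "T2", nodes_examined = c(1, 2, 4, 6, 9, 13, 20, 30),
                     nodes_positive = 0)
  ch <- validate_cohort(cohort_from_df(df))
  cv <- nss_curve(ref_params()$T2, 0.583, n_max = 30)
  asn <- assign_quantile_groups(ch, list(T2 = cv))
  expect_equal(as.vector(table(asn$group)), c(2, 2, 2, 2))
  cuts <- attr(asn, "cutoffs")$T2
  expect_equal(cuts, unname(quantile(asn$score, c(.25, .5, .75), type = 7)))
  # groups consistent with the half-open interval rule
  expect_true(all((asn$score < cuts[1]) == (asn$group == "Q1")))
  expect_true(all((asn$score >= cuts[3]) == (asn$group == "Q4")))
})

test_that("tied scores collapse to Q4 with a warning; <4 patients errors", {
  df <- patient_rows(5, "T3", nodes_examined = 12, nodes_positive = 0)
  ch <- validate_cohort(cohort_from_df(df))
  cv <- nss_curve(ref_params()$T3, 0.727, n_max = 20)
  expect_warning(asn <- assign_quantile_groups(ch, list(T3 = cv)),
                 "degenerate")
  expect_true(all(asn$group == "Q4"))
  ch3 <- validate_cohort(cohort_from_df(patient_rows(3, "T3")))
  expect_error(assign_quantile_groups(ch3, list(T3 = cv)), "insufficient")
})

test_that("group sizes differ by at most 1 from n/4 when scores are distinct", {
  cv <- nss_curve(ref_params()$T2, 0.583, n_max = 90)
  for (n in c(60, 61, 63)) {
    # distinct examined-node counts guarantee distinct (strictly increasing)
    # scores, so the empirical quartiles should split nearly evenly
    df <- patient_rows(n, "T2", nodes_examined = seq_len(n), nodes_positive = 0)
    ch <- validate_cohort(cohort_from_df(df))
    asn <- assign_quantile_groups(ch, list(T2 = cv))
    sizes <- table(asn$group)
    expect_lte(max(abs(sizes - n / 4)), 1)
  }
})

test_that("fixed-mode cutoffs use the 0.25/0.5/0.75 grid", {
  df <- patient_rows(6, "T4", nodes_examined = c(1, 2, 3, 10, 30, 60),
                     nodes_positive = 0)
  ch <- validate_cohort(cohort_from_df(df))
  cv <- nss_curve(ref_params()$T4, 0.895, n_max = 60)
  asn <- assign_quantile_groups(ch, list(T4 = cv), mode = "fixed")
  expect_equal(attr(asn, "cutoffs")$T4, c(0.25, 0.5, 0.75))
  expect_true(all(asn$group == ifelse(asn$score < 0.25, "Q1",
                             ifelse(asn$score < 0.5, "Q2",
                             ifelse(asn$score < 0.75, "Q3", "Q4")))))
})
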