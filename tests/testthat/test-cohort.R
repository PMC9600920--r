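test_that("well-formed rows ingest unchanged; bad rows go to the exclusion log", {
  df <- patient_rows(3, nodes_positive = c(0, 2, 1))
  ch <- cohort_from_df(df)
  expect_s3_class(ch, "cohort_table")
  expect_equal(nrow(ch$records), 3)
  expect_equal(nrow(ch$exclusion_log), 0)

  bad <- rbind(df,
               data.frame(patient_id = "bad1", t_stage = "T2",
                          nodes_examined = 4, nodes_positive = 7,
                          survival_months = 10, event = 1),
               data.frame(patient_id = "bad2", t_stage = "TX",
                          nodes_examined = 4, nodes_positive = 1,
                          survival_months = 10, event = 1))
  ch2 <- cohort_from_df(bad)
  expect_equal(nrow(ch2$records), 3)
  expect_setequal(ch2$exclusion_log$rule, c("positive>examined", "unstageable"))
  # exclusions + retained = raw rows
  expect_equal(nrow(ch2$records) + nrow(ch2$exclusion_log), nrow(bad))
})

test_that("missing mandatory column names the column", {
  path <- tempfile(fileext = ".csv")
  write.csv(patient_rows(2)[, -3], path, row.names = FALSE)
  expect_error(read_cohort(path), "nodes_examined")
})

test_that("validation filters zero-node patients and errors on empty result", {
  df <- patient_rows(5, nodes_examined = c(0, 10, 12, 8, 15))
  ch <- validate_cohort(cohort_from_df(df))
  expect_equal(nrow(ch$records), 4)
  expect_equal(sum(ch$exclusion_log$rule == "no_nodes_examined"), 1)

  ok <- validate_cohort(cohort_from_df(patient_rows(4)))
  expect_equal(nrow(ok$records), 4)
  expect_error(
    validate_cohort(cohort_from_df(patient_rows(2, nodes_examined = 0))),
    "no analyzable records")
})

test_that("a defect-free synthetic cohort of the study size passes whole", {
  sim <- simulate_cohort(sim_config(n_patients = 561), seed = 3)
  ch <- validate_cohort(sim$cohort)
  expect_equal(nrow(ch$records), 561)
  expect_equal(nrow(ch$exclusion_log), 0)
})

test_that("strata tally node status and partition the cohort", {
  df <- rbind(patient_rows(1, "T1", 15, 1),
              patient_rows(1, "T1", 15, 0, id_offset = 1))
  st <- stratify_counts(validate_cohort(cohort_from_df(df)))
  expect_equal(nrow(st), 1)
  expect_equal(st$n_positive, 1L)
  expect_equal(st$n_negative, 1L)

  sim <- simulate_cohort(sim_config(n_patients = 400), seed = 5)
  ch <- validate_cohort(sim$cohort)
  st <- stratify_counts(ch)
  expect_equal(sum(st$n_positive + st$n_negative), nrow(ch$records))
  # tallies equal the generator's own bookkeeping
  rec <- ch$records
  for (i in sample(nrow(st), 10)) {
    sel <- rec$t_stage == st$t_stage[i] &
      rec$nodes_examined == st$nodes_examined[i]
    expect_equal(st$n_positive[i], sum(rec$nodes_positive[sel] >= 1))
    expect_equal(st$n_negative[i], sum(rec$nodes_positive[sel] == 0))
  }
})

test_that("cohort CSV round-trips identically", {
  sim <- simulate_cohort(sim_config(n_patients = 50), seed = 9)
  path <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$records, sim$cohort$records)
})

test_that("characteristics table reproduces known percentage cells", {
  # cohort matching the reference stage-by-LN-status counts, with a tumor
  # size label distributed as in the reference LN-negative column
  sc <- ref_stage_counts()
  rows <- list()
  off <- 0
  for (i in seq_len(nrow(sc))) {
    rows[[2 * i - 1]] <- patient_rows(sc$ln_negative[i], sc$t_stage[i],
                                      nodes_positive = 0, id_offset = off)
    off <- off + sc$ln_negative[i]
    rows[[2 * i]] <- patient_rows(sc$ln_positive[i], sc$t_stage[i],
                                  nodes_positive = 1, id_offset = off)
    off <- off + sc$ln_positive[i]
  }
  df <- do.call(rbind, rows)
  size_neg <- rep(c("<3cm", "3-6cm", ">=6cm", "unknown"), c(89, 16, 39, 49))
  size_pos <- rep(c("<3cm", "3-6cm", ">=6cm", "unknown"), c(42, 152, 125, 49))
  df$tumor_size <- NA_character_
  df$tumor_size[df$nodes_positive == 0] <- size_neg
  df$tumor_size[df$nodes_positive == 1] <- size_pos
  ch <- validate_cohort(cohort_from_df(df))
  tab <- summarize_cohort(ch, variables = c("t_stage", "tumor_size"))

  expect_equal(attr(tab, "n_negative"), 193)
  expect_equal(attr(tab, "n_positive"), 368)
  expect_equal(attr(tab, "n_total"), 561)
  t1 <- tab[tab$variable == "t_stage" & tab$level == "T1", ]
  expect_equal(t1$cell_negative, "98 (50.8)")
  expect_equal(t1$cell_positive, "18 (4.9)")
  small <- tab[tab$variable == "tumor_size" & tab$level == "<3cm", ]
  expect_equal(small$pct_negative, 46.1)
  t4 <- tab[tab$variable == "t_stage" & tab$level == "T4", ]
  expect_equal(t4$pct_positive, 50.8)
})

test_that("single-patient cohort normalizes to 100%", {
  ch <- validate_cohort(cohort_from_df(patient_rows(1, "T2", 8, 1)))
  tab <- summarize_cohort(ch)
  expect_equal(tab$pct_positive[tab$level == "T2"], 100.0)
})
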