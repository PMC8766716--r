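test_that("the packaged retrospective cohort table ingests with 14 patients", {
  pts <- read_patient_table(retrospective_cohort_path())
  expect_equal(nrow(pts), 14L)
  expect_equal(sum(pts$sex == "Male"), 10L)
  expect_equal(sum(pts$sex == "Female"), 4L)
  # n.d / n.a parse to missing for the one never-detected patient
  nd <- pts[pts$patient_id == "Pat#5", ]
  expect_true(is.na(nd$ctdna_day))
  expect_true(is.na(nd$delta))
  expect_equal(sum(!is.na(pts$ctdna_day)), 13L)
})

test_that("malformed patient tables report the offending row or file", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("patient_id\tsex\tage\tgene\thgvs_c\timaging_day\tctdna_day\tdelta",
             empty)
  expect_error(read_patient_table(empty), class = "mrdcall_input_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tsex\tage\tgene\thgvs_c\timaging_day\tctdna_day\tdelta",
               "P1\tMale\tseventy\tKRAS\tc.35G>A\t100\t50\t50"), bad)
  expect_error(read_patient_table(bad), class = "mrdcall_format_error")
})

test_that("lead times reproduce the per-patient imaging-minus-ctDNA deltas", {
  lt <- lead_time(c(764, 962, 268), c(647, 962, 42))
  expect_equal(lt$delta_days, c(117, 0, 226))
  nd <- lead_time(305, NA)
  expect_true(is.na(nd$delta_days))
  expect_warning(lead_time(100, 150), "Negative lead")
  expect_error(lead_time(NA, 50), class = "mrdcall_input_error")
})

test_that("fixture deltas equal the lead-time recomputation from day columns", {
  pts <- read_patient_table(retrospective_cohort_path())
  lt <- lead_time(pts$imaging_day, pts$ctdna_day)
  expect_equal(lt$delta_days, pts$delta)
})

test_that("cohort summary reproduces the printed cohort statistics", {
  s <- cohort_summary(read_patient_table(retrospective_cohort_path()))
  expect_equal(s$n_patients, 14L)
  expect_equal(s$n_detected, 13L)
  expect_equal(s$age$median, 68)
  expect_equal(s$age$min, 50L)
  expect_equal(s$age$max, 81L)
  expect_equal(s$delta_days$median, 112)
  expect_equal(s$delta_days$min, 0L)
  expect_equal(s$delta_days$max, 226L)
  # follow-up over the 13 patients contributing a delta
  expect_equal(s$followup_days$median, 381)
  expect_equal(s$followup_days$min, 163L)
  expect_equal(s$followup_days$max, 962L)
  gc <- s$gene_counts
  expect_equal(gc$n_markers[gc$gene == "KRAS"], 9L)
  expect_equal(gc$n_markers[gc$gene == "NRAS"], 2L)
  expect_equal(gc$n_markers[gc$gene == "TP53"], 3L)
  expect_error(cohort_summary(read_patient_table(retrospective_cohort_path())[0, ]),
               class = "mrdcall_input_error")
})

test_that("cohort summary serialises to JSON and back", {
  s <- cohort_summary(read_patient_table(retrospective_cohort_path()))
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_patients, 14L)
  expect_equal(back$age$median, 68)
  expect_equal(back$delta_days$median, 112)
})

test_that("accumulation rate is the least-squares slope over positive samples", {
  expect_equal(accumulation_rate(c(0, 100), c(0.01, 1.21)), 0.012)
  expect_equal(accumulation_rate(c(0, 100), c(0.01, 0.31)), 0.003)
  expect_true(is.na(accumulation_rate(c(50), c(0.2))))
  expect_true(is.na(accumulation_rate(c(10, 50), c(0, 0.2))))  # one positive
  # slope matches lm on a longer noisy series
  set.seed(9)
  days <- seq(40, 200, by = 20)
  vaf <- 0.005 * (days - 30) + rnorm(length(days), 0, 0.01)
  expect_equal(accumulation_rate(days, vaf, positive = rep(TRUE, length(days))),
               unname(coef(lm(vaf ~ days))[2]))
})

test_that("first positive day is found on a simulated relapse trajectory", {
  cfg <- sim_config(coverage_target = 150000, replicates = 3)
  series <- simulate_patient_series(relapse_day = 220, daily_rate_pct = 0.012,
                                    clearance_until_day = 30,
                                    sampling_days = c(14, 45, 80, 140, 200),
                                    cfg = cfg, seed = 101)
  series$patient_id <- "P1"
  fp <- first_positive_day(series)
  # true VAF crosses the 0.01% cutoff between day 30 and day 45
  expect_false(is.na(fp$first_positive_day))
  expect_lt(fp$first_positive_day, 220)
  expect_gt(fp$first_positive_day, 14)

  flat <- simulate_patient_series(relapse_day = 220, daily_rate_pct = 0,
                                  sampling_days = c(14, 100, 200),
                                  cfg = sim_config(
                                    error_rate_by_class = c(transition = 0)),
                                  seed = 5)
  expect_true(is.na(first_positive_day(flat)$first_positive_day))
  expect_error(first_positive_day(flat[0, ]), class = "mrdcall_input_error")
})

test_that("simulated cohorts recover configured accumulation rates and lead times", {
  cfg <- sim_config(coverage_target = 150000, replicates = 3)
  rates <- c(0.003, 0.006, 0.012)
  for (i in seq_along(rates)) {
    days <- seq(15, 255, by = 30)
    series <- simulate_patient_series(relapse_day = 255,
                                      daily_rate_pct = rates[i],
                                      clearance_until_day = 30,
                                      sampling_days = days,
                                      cfg = cfg, seed = 300 + i)
    fp <- first_positive_day(series)
    expect_lte(fp$first_positive_day, 255)  # molecular lead vs imaging day
    calls <- call_marker(pool_replicates(
      dplyr::mutate(series, sample_id = as.character(day))))
    pos <- calls$status == "positive"
    rate_hat <- accumulation_rate(as.integer(calls$sample_id)[pos],
                                  calls$vaf_pct[pos],
                                  positive = rep(TRUE, sum(pos)))
    expect_lt(abs(rate_hat - rates[i]) / rates[i], 0.2)
  }
})
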