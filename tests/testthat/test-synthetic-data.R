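test_that("template sampling conserves copies and respects degenerate VAFs", {
  t0 <- sample_templates(rep(5000L, 50), 0, seed = 1)
  expect_true(all(t0$mutant_copies == 0))
  t100 <- sample_templates(rep(5000L, 50), 100, seed = 1)
  expect_true(all(t100$wt_copies == 0))
  tt <- sample_templates(sample.int(10000, 200), runif(200, 0, 100), seed = 2)
  expect_identical(tt$mutant_copies + tt$wt_copies, tt$copies)
  expect_true(all(tt$mutant_copies >= 0))
})

test_that("at 1666 copies and 0.01% VAF the mutant-presence rate matches the closed form", {
  # closed form 1 - (1 - 1e-4)^1666 = 0.1535; Monte-Carlo check at n = 1e5
  p_closed <- 1 - (1 - 1e-4)^1666
  draws <- sample_templates(rep(1666L, 1e5), 0.01, seed = 42)
  p_mc <- mean(draws$mutant_copies >= 1)
  se <- sqrt(p_closed * (1 - p_closed) / 1e5)
  expect_lt(abs(p_mc - p_closed), 4 * se)
})

test_that("mean mutant copies at 50% VAF sit within 3 SE of the binomial mean", {
  draws <- sample_templates(rep(8333L, 200), 50, seed = 7)
  se <- sqrt(8333 * 0.25) / sqrt(200)
  expect_lt(abs(mean(draws$mutant_copies) - 4166.5), 3 * se)
  expect_true(all(abs(draws$mutant_copies - 4166.5) < 6 * sqrt(8333 * 0.25)))
})

test_that("sequencing reads follow the error-mixed binomial and flag empty libraries", {
  cfg0 <- sim_config(error_rate_by_class = c(transition = 0),
                     coverage_target = 150000)
  r <- sequence_reads(rep(0L, 20), rep(10000L, 20), cfg = cfg0, seed = 1)
  expect_true(all(r$alt_reads == 0))
  expect_true(all(r$total_reads >= 120000 & r$total_reads <= 180000))

  # expectation coverage * e with no mutants: 115000 * 1.6e-5 = 1.84
  cfg <- sim_config(coverage_target = 115000)
  r2 <- sequence_reads(rep(0L, 5000), rep(10000L, 5000), cfg = cfg, seed = 2)
  expect_equal(mean(r2$alt_reads), 1.84, tolerance = 0.05)

  # proportional representation with zero error
  r3 <- sequence_reads(rep(5L, 2000), rep(9995L, 2000), cfg = cfg0, seed = 3)
  expect_equal(mean(100 * r3$alt_reads / r3$total_reads), 0.05,
               tolerance = 0.02)

  expect_error(sequence_reads(0L, 0L, cfg = cfg0),
               class = "mrdcall_library_failure")
  expect_error(sequence_reads(5L, 5L, cfg = sim_config(dropout = 0), seed = 1),
               class = "mrdcall_library_failure")
})

test_that("control cohorts are wild type with error-rate-driven alt reads", {
  cfg0 <- sim_config(error_rate_by_class = c(transition = 0))
  ctrl0 <- simulate_control_cohort(9, cfg = cfg0, seed = 1)
  expect_equal(nrow(ctrl0), 9L)
  expect_true(all(ctrl0$alt_reads == 0))
  expect_error(simulate_control_cohort(1), class = "mrdcall_config_error")

  # empirical mean FP% near 100 * 1.6e-5 = 0.0016 over a large cohort
  ctrl <- simulate_control_cohort(2000, cfg = sim_config(coverage_target = 115000),
                                  seed = 2)
  fp <- 100 * ctrl$alt_reads / ctrl$total_reads
  expect_lt(abs(mean(fp) - 0.0016), 3 * sd(fp) / sqrt(2000))
})

test_that("dilution series form the expected geometric ladder", {
  d <- simulate_dilution_series(45, 10, 5, cfg = sim_config(), seed = 1)
  expect_equal(d$expected_vaf_pct, c(45, 4.5, 0.45, 0.045, 0.0045))
  expect_true(all(diff(d$expected_vaf_pct) < 0))
  d1 <- simulate_dilution_series(45, 10, 1, cfg = sim_config(), seed = 1)
  expect_equal(d1$expected_vaf_pct, 45)
})

test_that("patient series clear early, then accrue linearly at the daily rate", {
  s <- simulate_patient_series(relapse_day = 200, daily_rate_pct = 0.003,
                               sampling_days = c(14, 60, 120, 200),
                               cfg = sim_config(), seed = 1)
  expect_equal(s$true_vaf_pct[s$day == 14], 0)
  expect_equal(s$true_vaf_pct[s$day == 200], 0.003 * 170)

  s2 <- simulate_patient_series(relapse_day = 130, daily_rate_pct = 0.012,
                                clearance_until_day = 30,
                                sampling_days = c(10, 130),
                                cfg = sim_config(), seed = 1)
  expect_equal(s2$true_vaf_pct[s2$day == 130], 1.2)

  s0 <- simulate_patient_series(relapse_day = 300, daily_rate_pct = 0,
                                sampling_days = c(10, 100, 300),
                                cfg = sim_config(), seed = 1)
  expect_true(all(s0$true_vaf_pct == 0))

  expect_error(simulate_patient_series(relapse_day = 100, daily_rate_pct = 0.01,
                                       sampling_days = c(50, 20),
                                       cfg = sim_config()),
               class = "mrdcall_input_error")
})

test_that("identical seeds give bit-identical simulator output", {
  cfg <- sim_config(coverage_target = 120000, replicates = 3)
  a <- simulate_patient_series(relapse_day = 200, daily_rate_pct = 0.01,
                               sampling_days = c(30, 90, 150, 200),
                               cfg = cfg, seed = 99)
  b <- simulate_patient_series(relapse_day = 200, daily_rate_pct = 0.01,
                               sampling_days = c(30, 90, 150, 200),
                               cfg = cfg, seed = 99)
  expect_identical(a, b)
  expect_identical(simulate_dilution_series(cfg = cfg, seed = 5),
                   simulate_dilution_series(cfg = cfg, seed = 5))
})

test_that("with no dropout and no error, expected VAF equals the template fraction", {
  cfg0 <- sim_config(error_rate_by_class = c(transition = 0),
                     coverage_target = 150000)
  for (frac in c(0.001, 0.01, 0.1)) {
    m <- as.integer(10000 * frac)
    r <- sequence_reads(rep(m, 2000), rep(10000L - m, 2000),
                        cfg = cfg0, seed = m)
    vaf <- r$alt_reads / r$total_reads
    se <- sd(vaf) / sqrt(2000)
    expect_lt(abs(mean(vaf) - frac), 4 * se + 1e-6)
  }
})

test_that("detection probability rises with mass, VAF and coverage", {
  p_at <- function(mass, vaf) p_template_present(mass, vaf)
  expect_true(all(diff(p_at(c(5, 10, 20, 40), 0.01)) > 0))
  expect_true(all(diff(p_at(20, c(0.001, 0.01, 0.1, 1))) > 0))
  # simulated: detection fraction at higher coverage >= lower, same seed
  cfg_lo <- sim_config(coverage_target = 20000)
  cfg_hi <- sim_config(coverage_target = 200000)
  p_lo <- detection_power(20, 0.01, cfg = cfg_lo, n_sims = 300, seed = 4)$p_detect
  p_hi <- detection_power(20, 0.01, cfg = cfg_hi, n_sims = 300, seed = 4)$p_detect
  expect_gte(p_hi, p_lo - 0.05)
})
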