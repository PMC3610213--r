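test_that("scenario presets reproduce the stated hazard table exactly", {
  a <- scenario_preset("A")
  expect_equal(unname(a$hazard_lr), c(0.02, 0.02))
  expect_equal(unname(a$hazard_mr), c(0.02, 0.03))
  expect_equal(unname(a$hazard_dt), c(0.02, 0.04))
  b <- scenario_preset("B")
  expect_equal(unname(b$hazard_lr), c(0.03, 0.02))
  expect_equal(unname(b$hazard_mr), c(0.03, 0.02))
  expect_equal(unname(b$hazard_dt), c(0.04, 0.02))
  expect_equal(a$rho_l_d1, 0.2)
  expect_equal(a$rho_m_d2, 0.6)
  expect_equal(a$censor_fraction, 0.40)
})

test_that("scenario_spec validates its inputs", {
  expect_error(scenario_spec(hazard_lr = c(0, 0.02), hazard_mr = c(1, 1),
                             hazard_dt = c(1, 1)), "rates")
  expect_error(scenario_spec(hazard_lr = c(1, 1), hazard_mr = c(1, 1),
                             hazard_dt = c(1, 1), rho_l_d1 = 1), "correlations")
  expect_error(scenario_spec(hazard_lr = c(1, 1), hazard_mr = c(1, 1),
                             hazard_dt = c(1, 1), censor_fraction = 1),
               "censor_fraction")
  expect_error(scenario_spec(hazard_lr = c(1, 1), hazard_mr = c(1, 1),
                             hazard_dt = c(1, 1), n_per_arm = 0), "n_per_arm")
})

test_that("bivariate exponential sampler: independence case and support", {
  set.seed(101)
  p <- sample_bivariate_exponential(1e5, 1, 1, 0)
  expect_lt(abs(cor(p[, 1], p[, 2])), 0.02)
  expect_lt(abs(mean(p[, 1]) - 1), 0.02)
  expect_lt(abs(mean(p[, 2]) - 1), 0.02)
  expect_true(all(p > 0))
  expect_error(sample_bivariate_exponential(10, -1, 1, 0.2), "rates")
  expect_error(sample_bivariate_exponential(10, 1, 1, 1), "rho")
})

test_that("copula calibration attains the target Pearson correlation", {
  # Monte-Carlo validation of the quadrature-calibrated NORTA map
  set.seed(202)
  for (rho in c(0.2, 0.6)) {
    p <- sample_bivariate_exponential(1e6, 0.02, 0.04, rho)
    expect_lt(abs(cor(p[, 1], p[, 2]) - rho), 0.01)
  }
  # margins keep their rates
  set.seed(203)
  p <- sample_bivariate_exponential(2e5, 0.02, 0.04, 0.6)
  expect_lt(abs(mean(p[, 1]) - 50), 1)
  expect_lt(abs(mean(p[, 2]) - 25), 0.5)
})

test_that("latent margins pass a Kolmogorov-Smirnov check", {
  set.seed(42)
  p <- sample_bivariate_exponential(1e4, 0.02, 0.04, 0.6)
  expect_gt(stats::ks.test(p[, 1], "pexp", 0.02)$p.value, 0.01)
  expect_gt(stats::ks.test(p[, 2], "pexp", 0.04)$p.value, 0.01)
})

test_that("assemble_subject applies the death-linking rule", {
  # death first: no recurrences, death at the linked time
  s <- assemble_subject(5, 1, 4, 3, 10, arm = 1L)
  expect_equal(s$t_followup_end, 1)
  expect_equal(s$died, 1L)
  expect_equal(s$local_event, 0L)
  expect_equal(s$distant_event, 0L)

  # min is l, so death links to d1; both recurrences observed
  s <- assemble_subject(1, 5, 2, 4, 10, arm = 0L)
  expect_equal(s$t_local, 1)
  expect_equal(s$t_distant, 2)
  expect_equal(s$t_followup_end, 5)
  expect_equal(s$died, 1L)

  # min is m, death links to d2; local never observed
  s <- assemble_subject(2, 3, 1, 4, 10, arm = 1L)
  expect_equal(s$local_event, 0L)
  expect_true(is.na(s$t_local))
  expect_equal(s$t_distant, 1)
  expect_equal(s$t_followup_end, 4)

  # censoring after a recurrence keeps the recurrence
  s <- assemble_subject(1, 5, 6, 7, 3, arm = 1L)
  expect_equal(s$t_local, 1)
  expect_equal(s$died, 0L)
  expect_equal(s$t_followup_end, 3)

  # early censoring wipes everything
  s <- assemble_subject(1, 5, 6, 7, 0.5, arm = 1L)
  expect_equal(s$local_event, 0L)
  expect_equal(s$distant_event, 0L)
  expect_equal(s$t_followup_end, 0.5)
  expect_equal(s$died, 0L)

  expect_error(assemble_subject(-1, 1, 1, 1, 1, arm = 1L), "positive")
})

test_that("simulate_trial is deterministic and respects invariants", {
  spec <- scenario_preset("A", n_per_arm = 300)
  c1 <- simulate_trial(spec, seed = 5, censor_rate = 0.03)
  c2 <- simulate_trial(spec, seed = 5, censor_rate = 0.03)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 600)
  expect_equal(sum(c1$arm == 1), 300)
  expect_equal(sum(c1$arm == 0), 300)

  # ordering invariants
  both <- !is.na(c1$t_local) & !is.na(c1$t_distant)
  expect_true(all(c1$t_local[both] < c1$t_distant[both]))
  rec <- pmax(ifelse(is.na(c1$t_local), -Inf, c1$t_local),
              ifelse(is.na(c1$t_distant), -Inf, c1$t_distant))
  died <- c1$died == 1
  expect_true(all(rec[died & rec > -Inf] < c1$t_followup_end[died & rec > -Inf]))
  expect_true(all(rec[!died & rec > -Inf] <= c1$t_followup_end[!died & rec > -Inf]))
  expect_true(all(c1$t_followup_end > 0))
  expect_true(all(c1$died %in% 0:1))
})

test_that("censoring calibration hits the target fraction", {
  spec <- scenario_preset("A")
  rate <- calibrate_censoring_rate(spec, seed = 77)
  # fresh large cohort, different seed
  big <- scenario_preset("A", n_per_arm = 50000L)
  coh <- simulate_trial(big, seed = 1234, censor_rate = rate)
  frac <- mean(coh$died == 0)
  expect_gt(frac, 0.39)
  expect_lt(frac, 0.41)

  # monotonicity: doubling the rate censors strictly more
  coh2 <- simulate_trial(big, seed = 1234, censor_rate = 2 * rate)
  expect_gt(mean(coh2$died == 0), frac)

  # zero target disables censoring entirely
  spec0 <- scenario_preset("A", censor_fraction = 0)
  expect_identical(calibrate_censoring_rate(spec0), 0)
  c0 <- simulate_trial(scenario_preset("A", n_per_arm = 200,
                                       censor_fraction = 0), seed = 3)
  expect_true(all(c0$died == 1))
})

test_that("death outcome recovers the marginal death hazard ratio", {
  # death is fully observed, so the cause-specific Cox fit on the death
  # outcome recovers the stated marginal death hazard ratio (A: 0.02/0.04)
  spec <- scenario_preset("A", n_per_arm = 500)
  rate <- calibrate_censoring_rate(spec, seed = 7)
  betas <- vapply(1:60, function(r) {
    coh <- simulate_trial(spec, seed = 1000 + r, censor_rate = rate)
    cox_fit(to_cause_specific(coh, "death"))$beta
  }, numeric(1))
  expect_lt(abs(exp(mean(betas)) - 0.5), 0.05)
})

test_that("cohorts round-trip through the delimited format", {
  coh <- simulate_trial(scenario_preset("A", n_per_arm = 50), seed = 9,
                        censor_rate = 0.03)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  # ingest validation: zero/negative times rejected
  bad <- coh
  bad$t_followup_end[1] <- 0
  f2 <- tempfile(fileext = ".csv")
  write_cohort(bad, f2)
  expect_error(read_cohort(f2), "non-positive")
  unlink(c(f, f2))
})
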