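test_that("censoring Kaplan-Meier matches hand-computed product limits", {
  # 4 subjects, censoring at 2 and 4, events at 1 and 3
  g <- km_censoring(time = c(1, 2, 3, 4), status = c(1, 0, 1, 0))
  # at t=2: 3 at risk, 1 censored -> 2/3; at t=4: 1 at risk -> 0
  expect_equal(g$g(c(0, 1, 1.9)), c(1, 1, 1))
  expect_equal(g$g(c(2, 3.9)), c(2 / 3, 2 / 3))
  expect_equal(g$g(4), 0)

  # no censored subjects -> G identically 1
  g1 <- km_censoring(time = 1:5, status = rep(1, 5))
  expect_equal(g1$g(c(0, 2, 5)), c(1, 1, 1))

  # non-increasing on arbitrary data
  set.seed(3)
  tm <- rexp(200); st <- rbinom(200, 1, 0.6)
  gg <- km_censoring(tm, st)$g(sort(tm))
  expect_true(all(diff(gg) <= 1e-12))
})

test_that("Fine-Gray equals Cox when no competing events exist", {
  d <- sim_exp_cohort(120, 0.5, cens_rate = 0.05, seed = 29)
  d$subject_id <- seq_len(nrow(d))
  fg <- fine_gray_fit(d[, c("subject_id", "arm", "time", "status")])
  cx <- cox_fit(d, ties = "breslow")
  expect_equal(fg$beta, cx$beta, tolerance = 1e-12)
  expect_equal(fg$se_model, cx$se_model, tolerance = 1e-12)
})

test_that("Fine-Gray matches brute-force weighted likelihood on a toy", {
  # 8 subjects, two competing events, censoring away from event times
  d <- data.frame(subject_id = 1:8,
                  arm = c(1, 0, 1, 0, 1, 0, 1, 0),
                  time = c(1.1, 1.7, 2.4, 3.2, 3.9, 4.6, 5.3, 6.8),
                  status = c(1, 2, 0, 1, 2, 1, 0, 1))
  fit <- fine_gray_fit(d)
  oracle <- oracle_fg_beta(d$time, d$status, d$arm)
  expect_lt(abs(fit$beta - oracle), 1e-4)

  # engine loglik equals the explicitly-coded weighted partial likelihood
  expect_equal(fit$loglik, oracle_fg_loglik(fit$beta, d$time, d$status,
                                            d$arm),
               tolerance = 1e-8)
})

test_that("Fine-Gray agrees with survival::finegray + coxph", {
  skip_if_not_installed("survival")
  coh <- simulate_trial(scenario_preset("A", n_per_arm = 250), seed = 47,
                        censor_rate = 0.033)
  cr <- to_competing(coh, "local")
  fit <- fine_gray_fit(cr)
  fgd <- survival::finegray(
    survival::Surv(time, factor(status, 0:2, c("cens", "ev", "cmp"))) ~ .,
    data = cr, etype = "ev")
  o <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ arm, data = fgd,
    weights = fgwt, ties = "breslow", cluster = subject_id)
  expect_equal(fit$beta, unname(coef(o)), tolerance = 1e-6)
  expect_equal(fit$se_robust, sqrt(unname(diag(o$var))), tolerance = 1e-4)
})

test_that("CIF reduces to 1 - KM without competing events", {
  d <- sim_exp_cohort(100, 0.2, cens_rate = 0.08, seed = 31)
  cif <- estimate_cif(d)
  expect_equal(cif$cif[, 1], 1 - cif$surv, tolerance = 1e-12)
})

test_that("CIF conservation identity holds at every jump", {
  coh <- simulate_trial(scenario_preset("B", n_per_arm = 200), seed = 53,
                        censor_rate = 0.03)
  cr <- to_competing(coh, "local")
  cif <- estimate_cif(cr)
  total <- rowSums(cif$cif) + cif$surv
  expect_equal(total, rep(1, length(cif$time)), tolerance = 1e-10)
})

test_that("CIF steps match the hand-computed Aalen-Johansen toy", {
  d <- data.frame(time = c(1, 2, 3, 4, 5),
                  status = c(1, 2, 0, 1, 2))
  cif <- estimate_cif(d)
  o1 <- oracle_cif(d$time, d$status, 1)
  o2 <- oracle_cif(d$time, d$status, 2)
  expect_equal(cif$time, o1$time)
  expect_equal(cif$cif[, "cause_1"], o1$cif, tolerance = 1e-12)
  expect_equal(cif$cif[, "cause_2"], o2$cif, tolerance = 1e-12)
  # explicit first steps: S(1-) = 1, 5 at risk
  expect_equal(unname(cif$cif[1, "cause_1"]), 1 / 5)
  expect_equal(unname(cif$cif[2, "cause_2"]), (4 / 5) * (1 / 4))
})
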