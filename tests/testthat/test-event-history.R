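test_that("WLW long format reproduces the reshaping table", {
  coh <- toy_cohort()
  long <- to_wlw_long(coh)
  expect_equal(nrow(long), 3 * nrow(coh))
  expect_equal(as.integer(table(long$stratum)), rep(nrow(coh), 3))

  grab <- function(id, st) {
    r <- long[long$subject_id == id & long$stratum == st, ]
    c(r$time, r$status)
  }
  # L, M, D: all three events at their own times
  expect_equal(grab(1, "local"), c(2, 1))
  expect_equal(grab(1, "distant"), c(5, 1))
  expect_equal(grab(1, "death"), c(9, 1))
  # M, D: local censored at the distant-recurrence time
  expect_equal(grab(4, "local"), c(4.5, 0))
  expect_equal(grab(4, "distant"), c(4.5, 1))
  expect_equal(grab(4, "death"), c(7.5, 1))
  # D only: recurrences censored at the death time
  expect_equal(grab(7, "local"), c(3, 0))
  expect_equal(grab(7, "distant"), c(3, 0))
  expect_equal(grab(7, "death"), c(3, 1))
  # L only (alive, censored): distant and death censored at follow-up end
  expect_equal(grab(5, "local"), c(1, 1))
  expect_equal(grab(5, "distant"), c(6, 0))
  expect_equal(grab(5, "death"), c(6, 0))
  # M then censored: local censored at M, death censored at E
  expect_equal(grab(6, "local"), c(3, 0))
  expect_equal(grab(6, "distant"), c(3, 1))
  expect_equal(grab(6, "death"), c(10, 0))
  # L, D: distant censored at death
  expect_equal(grab(3, "distant"), c(7, 0))
})

test_that("round-trip: observed event times equal WLW status-1 times", {
  coh <- simulate_trial(scenario_preset("A", n_per_arm = 150), seed = 21,
                        censor_rate = 0.033)
  long <- to_wlw_long(coh)
  got <- sort(long$time[long$status == 1])
  want <- sort(c(coh$t_local[coh$local_event == 1],
                 coh$t_distant[coh$distant_event == 1],
                 coh$t_followup_end[coh$died == 1]))
  expect_equal(got, want)
})

test_that("competing-risk coding follows the first-event rule", {
  coh <- toy_cohort()
  cl <- to_competing(coh, "local")
  # local observed first -> status 1 at t_local
  expect_equal(cl$status[cl$subject_id == 1], 1L)
  expect_equal(cl$time[cl$subject_id == 1], 2)
  # distant first -> competing at the distant time
  expect_equal(cl$status[cl$subject_id == 4], 2L)
  expect_equal(cl$time[cl$subject_id == 4], 4.5)
  # death only -> competing at death
  expect_equal(cl$status[cl$subject_id == 7], 2L)
  expect_equal(cl$time[cl$subject_id == 7], 3)

  # distant model: death competes, local recurrence ignored
  cd <- to_competing(coh, "distant")
  expect_equal(cd$status[cd$subject_id == 3], 2L)  # L then death, L ignored
  expect_equal(cd$time[cd$subject_id == 3], 7)
  expect_equal(cd$status[cd$subject_id == 5], 0L)  # L then censored
  expect_equal(cd$time[cd$subject_id == 5], 6)

  # censored with no events, any event of interest
  none <- data.frame(subject_id = 99L, arm = 0L, t_local = NA_real_,
                     local_event = 0L, t_distant = NA_real_,
                     distant_event = 0L, t_followup_end = 6, died = 0L)
  for (ev in c("local", "distant", "death")) {
    cn <- to_competing(none, ev)
    expect_equal(cn$status, 0L)
    expect_equal(cn$time, 6)
  }
})

test_that("competing coding for death equals plain survival coding", {
  coh <- simulate_trial(scenario_preset("B", n_per_arm = 200), seed = 31,
                        censor_rate = 0.03)
  cd <- to_competing(coh, "death")
  expect_true(all(cd$status %in% 0:1))
  expect_equal(cd$time, coh$t_followup_end)
  expect_equal(cd$status, coh$died)
})

test_that("counting records carry one vital-status row per subject", {
  coh <- toy_cohort()
  cr <- to_counting(coh)
  vs <- cr[cr$record_role == "vital_status", ]
  expect_equal(sort(vs$subject_id), sort(coh$subject_id))
  expect_equal(vs$time[order(vs$subject_id)],
               coh$t_followup_end[order(coh$subject_id)])
  # subject 1: local at 2, distant at 5, death at 9 -> three rows
  r1 <- cr[cr$subject_id == 1, ]
  expect_equal(r1$time, c(2, 5, 9))
  expect_equal(r1$status, c(1L, 1L, 1L))
  # subject 5: local at 1, censored at 6 -> (1,1), (6,0)
  r5 <- cr[cr$subject_id == 5, ]
  expect_equal(r5$time, c(1, 6))
  expect_equal(r5$status, c(1L, 0L))
  # expected total rows: n + observed recurrences
  expect_equal(nrow(cr),
               nrow(coh) + sum(coh$local_event) + sum(coh$distant_event))
})
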