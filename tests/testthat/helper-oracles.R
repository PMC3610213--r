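# Independent oracles used across the estimator tests. These are written
# from the likelihood definitions directly (loops, no risk-set tricks) and
# maximized with generic one-dimensional optimization, so they share no
# code path with the package's Newton-Raphson engine.

# Breslow log partial likelihood for right-censored rows, by explicit loop.
oracle_breslow_loglik <- function(beta, time, status, x, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] != 1) next
    at_risk <- time >= time[i]
    ll <- ll + weights[i] *
      (beta * x[i] - log(sum(weights[at_risk] * exp(beta * x[at_risk]))))
  }
  ll
}

oracle_breslow_beta <- function(time, status, x, weights = NULL) {
  stats::optimize(function(b) oracle_breslow_loglik(b, time, status, x,
                                                    weights),
                  interval = c(-8, 8), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Fine-Gray weighted partial likelihood written out explicitly: subjects
# with a competing event stay at risk for ever with weight G(t)/G(T_i);
# censored subjects leave at censoring; G is the censoring Kaplan-Meier of
# the pooled sample computed by a direct product loop.
oracle_censoring_km <- function(time, status) {
  jumps <- sort(unique(time[status == 0]))
  function(t) {
    g <- 1
    for (u in jumps) {
      if (u > t) break
      g <- g * (1 - sum(time == u & status == 0) / sum(time >= u))
    }
    g
  }
}

oracle_fg_loglik <- function(beta, time, status, x) {
  G <- oracle_censoring_km(time, status)
  ll <- 0
  for (i in which(status == 1)) {
    ti <- time[i]
    denom <- 0
    for (j in seq_along(time)) {
      w <- if (status[j] == 2 && time[j] < ti) {
        G(ti) / G(time[j])
      } else if (time[j] >= ti) 1 else 0
      denom <- denom + w * exp(beta * x[j])
    }
    ll <- ll + beta * x[i] - log(denom)
  }
  ll
}

oracle_fg_beta <- function(time, status, x) {
  stats::optimize(function(b) oracle_fg_loglik(b, time, status, x),
                  interval = c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# Aalen-Johansen CIF by explicit loop over event times.
oracle_cif <- function(time, status, cause) {
  ut <- sort(unique(time[status != 0]))
  surv <- 1
  cif <- numeric(length(ut))
  acc <- 0
  for (k in seq_along(ut)) {
    u <- ut[k]
    y <- sum(time >= u)
    acc <- acc + surv * sum(time == u & status == cause) / y
    surv <- surv * (1 - sum(time == u & status != 0) / y)
    cif[k] <- acc
  }
  list(time = ut, cif = cif)
}

# A small deterministic cohort exercising every event pattern of the WLW
# reshaping table.
toy_cohort <- function() {
  coh <- data.frame(
    subject_id = 1:7,
    arm = c(1L, 0L, 1L, 0L, 1L, 0L, 1L),
    t_local = c(2, 1.5, 2.5, NA, 1, NA, NA),
    local_event = c(1L, 1L, 1L, 0L, 1L, 0L, 0L),
    t_distant = c(5, 4, NA, 4.5, NA, 3, NA),
    distant_event = c(1L, 1L, 0L, 1L, 0L, 1L, 0L),
    t_followup_end = c(9, 8, 7, 7.5, 6, 10, 3),
    died = c(1L, 1L, 1L, 1L, 0L, 0L, 1L)
  )
  class(coh) <- c("ni_cohort", "data.frame")
  coh
}

# Tie-free two-arm exponential survival data for consistency checks.
sim_exp_cohort <- function(n, beta, base_rate = 0.1, cens_rate = 0,
                           seed = 1) {
  set.seed(seed)
  arm <- rep(0:1, each = n %/% 2)
  t_event <- stats::rexp(length(arm), base_rate * exp(beta * arm))
  cens <- if (cens_rate > 0) stats::rexp(length(arm), cens_rate) else Inf
  data.frame(time = pmin(t_event, cens),
             status = as.integer(t_event <= cens),
             arm = arm)
}
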