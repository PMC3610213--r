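# Simulation scenarios: latent-failure-time generator for semi-competing
# risks (local recurrence, distant recurrence, death) with correlated
# exponential margins and independent exponential censoring.

#' Define a simulation scenario
#'
#' A scenario fixes the per-arm exponential hazards for the three latent
#' event processes (local recurrence, distant recurrence, death), the
#' Pearson correlations between each recurrence time and its linked latent
#' death time, the target censoring fraction, and the cohort size per arm.
#'
#' @param name Label for the scenario.
#' @param n_per_arm Number of subjects per treatment arm.
#' @param hazard_lr Length-2 numeric, local-recurrence hazard as
#'   `c(experimental, control)` (events per unit time).
#' @param hazard_mr Length-2 numeric, distant-recurrence hazard,
#'   `c(experimental, control)`.
#' @param hazard_dt Length-2 numeric, death hazard, `c(experimental,
#'   control)`; both latent death times share this rate.
#' @param rho_l_d1 Target Pearson correlation between the latent
#'   local-recurrence time and its linked death time (default 0.2).
#' @param rho_m_d2 Target Pearson correlation between the latent
#'   distant-recurrence time and its linked death time (default 0.6).
#' @param censor_fraction Target proportion of subjects whose follow-up
#'   ends in censoring (default 0.40).
#' @return An object of class `scenario_spec`.
#' @seealso [scenario_preset()] for the two built-in scenarios,
#'   [simulate_trial()] to generate a cohort.
#' @export
scenario_spec <- function(name = "custom",
                          n_per_arm = 1000L,
                          hazard_lr,
                          hazard_mr,
                          hazard_dt,
                          rho_l_d1 = 0.2,
                          rho_m_d2 = 0.6,
                          censor_fraction = 0.40) {
  stopifnot(length(hazard_lr) == 2L, length(hazard_mr) == 2L,
            length(hazard_dt) == 2L)
  hazard_lr <- as.numeric(hazard_lr)
  hazard_mr <- as.numeric(hazard_mr)
  hazard_dt <- as.numeric(hazard_dt)
  if (any(c(hazard_lr, hazard_mr, hazard_dt) <= 0)) {
    stop("all hazard rates must be > 0", call. = FALSE)
  }
  if (rho_l_d1 < 0 || rho_l_d1 >= 1 || rho_m_d2 < 0 || rho_m_d2 >= 1) {
    stop("correlations must lie in [0, 1)", call. = FALSE)
  }
  if (censor_fraction < 0 || censor_fraction >= 1) {
    stop("censor_fraction must lie in [0, 1)", call. = FALSE)
  }
  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 1L) {
    stop("n_per_arm must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name, n_per_arm = n_per_arm,
         hazard_lr = stats::setNames(hazard_lr, c("experimental", "control")),
         hazard_mr = stats::setNames(hazard_mr, c("experimental", "control")),
         hazard_dt = stats::setNames(hazard_dt, c("experimental", "control")),
         rho_l_d1 = rho_l_d1, rho_m_d2 = rho_m_d2,
         censor_fraction = censor_fraction),
    class = "scenario_spec"
  )
}

#' Built-in simulation scenarios A and B
#'
#' Scenario A: recurrence hazards equal across arms for local recurrence but
#' the control arm carries higher distant-recurrence and death hazards
#' (experimental 0.02/0.02/0.02 vs control 0.02/0.03/0.04 for local
#' recurrence / distant recurrence / death). Scenario B reverses the
#' imbalance: the experimental arm is worse on every event (0.03/0.03/0.04
#' vs control 0.02/0.02/0.02).
#'
#' @param which `"A"` or `"B"`.
#' @param n_per_arm Cohort size per arm (default 1000).
#' @param censor_fraction Target censored proportion (default 0.40).
#' @return A `scenario_spec`.
#' @export
scenario_preset <- function(which = c("A", "B"), n_per_arm = 1000L,
                            censor_fraction = 0.40) {
  which <- match.arg(which)
  if (which == "A") {
    scenario_spec(name = "scenario_A", n_per_arm = n_per_arm,
                  hazard_lr = c(0.02, 0.02),
                  hazard_mr = c(0.02, 0.03),
                  hazard_dt = c(0.02, 0.04),
                  censor_fraction = censor_fraction)
  } else {
    scenario_spec(name = "scenario_B", n_per_arm = n_per_arm,
                  hazard_lr = c(0.03, 0.02),
                  hazard_mr = c(0.03, 0.02),
                  hazard_dt = c(0.04, 0.02),
                  censor_fraction = censor_fraction)
  }
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Simulation scenario:", x$name, "\n")
  cat("  n per arm:", x$n_per_arm, "\n")
  h <- rbind(local = x$hazard_lr, distant = x$hazard_mr, death = x$hazard_dt)
  print(h)
  cat("  rho(local, death):", x$rho_l_d1,
      " rho(distant, death):", x$rho_m_d2, "\n")
  cat("  target censored fraction:", x$censor_fraction, "\n")
  invisible(x)
}

# Gauss-Hermite nodes/weights for the N(0,1) weight function, via
# Golub-Welsch on the Jacobi matrix of the (probabilists') Hermite
# polynomials. Weights sum to 1.
gauss_hermite_norm <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

# Inverse-CDF map from a standard normal deviate to a unit exponential,
# computed on the log scale so extreme quadrature nodes do not underflow.
.norm_to_exp1 <- function(z) {
  -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
}

# Pearson correlation of a unit-exponential pair induced by a Gaussian
# copula with normal-scale correlation rho_z (rate-invariant), by 2-D
# Gauss-Hermite quadrature: corr = E[X1 X2] - 1 since Exp(1) has unit
# mean and variance.
exp_pair_correlation <- function(rho_z, n_nodes = 64L) {
  gh <- gauss_hermite_norm(n_nodes)
  z <- gh$nodes
  w <- gh$weights
  g <- .norm_to_exp1(z)
  s <- sqrt(1 - rho_z^2)
  inner <- vapply(z, function(zi) {
    sum(w * .norm_to_exp1(rho_z * zi + s * z))
  }, numeric(1))
  sum(w * g * inner) - 1
}

#' Calibrate the Gaussian-copula correlation for an exponential pair
#'
#' Finds the normal-scale (copula) correlation such that a pair of
#' exponential variables generated by the NORTA construction attains a
#' target Pearson correlation on the time scale. The map does not depend
#' on the exponential rates.
#'
#' @param rho Target Pearson correlation in `[0, 1)`.
#' @return The copula correlation, a scalar in `[0, 1)`.
#' @export
norta_z_correlation <- function(rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (rho == 0) return(0)
  stats::uniroot(function(r) exp_pair_correlation(r) - rho,
                 lower = 0, upper = 0.99999, tol = 1e-10)$root
}

#' Sample correlated exponential pairs
#'
#' Draws `n` pairs with exponential margins at the given rates and a target
#' Pearson correlation between the two coordinates, using a Gaussian copula
#' whose normal-scale correlation is calibrated numerically
#' (see [norta_z_correlation()]).
#'
#' @param n Number of pairs.
#' @param rate_a,rate_b Exponential rates of the two margins (> 0).
#' @param rho Target Pearson correlation in `[0, 1)`.
#' @return A two-column matrix with columns `a` and `b`, all entries > 0.
#' @export
sample_bivariate_exponential <- function(n, rate_a, rate_b, rho) {
  if (rate_a <= 0 || rate_b <= 0) {
    stop("rates must be > 0", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  rz <- norta_z_correlation(rho)
  z1 <- stats::rnorm(n)
  z2 <- rz * z1 + sqrt(1 - rz^2) * stats::rnorm(n)
  cbind(a = .norm_to_exp1(z1) / rate_a,
        b = .norm_to_exp1(z2) / rate_b)
}

#' Assemble observed subject records from latent times
#'
#' Applies the first-event death-linking rule and the observation ordering
#' to latent times, then truncates by independent censoring. The observed
#' death time is `d1` when the smallest latent time is `l` or `d1`, and
#' `d2` when it is `m` or `d2`. A local recurrence is observed when it
#' precedes both the distant recurrence and death; a distant recurrence is
#' observed when it precedes death. Events after the censoring time are
#' dropped and follow-up ends at `min(death, censoring)`.
#'
#' All arguments are vectorized over subjects.
#'
#' @param l,d1,m,d2 Latent times: local recurrence, death linked to local
#'   recurrence, distant recurrence, death linked to distant recurrence.
#' @param cens Censoring time (may be `Inf` when censoring is disabled).
#' @param arm Treatment arm, 0 = control, 1 = experimental.
#' @param subject_id Subject identifiers (default `seq_along(l)`).
#' @return A data frame (class `ni_cohort`) with one row per subject:
#'   `subject_id`, `arm`, `t_local`, `local_event`, `t_distant`,
#'   `distant_event`, `t_followup_end`, `died`.
#' @export
assemble_subject <- function(l, d1, m, d2, cens, arm,
                             subject_id = seq_along(l)) {
  n <- length(l)
  stopifnot(length(d1) == n, length(m) == n, length(d2) == n,
            length(cens) == n || length(cens) == 1L,
            length(arm) == n || length(arm) == 1L)
  if (any(c(l, d1, m, d2) <= 0) || any(!is.finite(c(l, d1, m, d2)))) {
    stop("latent event times must be strictly positive and finite",
         call. = FALSE)
  }
  cens <- rep_len(cens, n)
  arm <- rep_len(as.integer(arm), n)
  if (any(cens <= 0)) stop("censoring times must be > 0", call. = FALSE)

  first <- pmin(l, d1, m, d2)
  d <- ifelse(first == d1 | first == l, d1, d2)

  local_obs <- l < pmin(m, d)
  distant_obs <- m < d

  died <- d <= cens
  t_end <- pmin(d, cens)
  local_obs <- local_obs & l <= cens
  distant_obs <- distant_obs & m <= cens

  out <- data.frame(
    subject_id = subject_id,
    arm = arm,
    t_local = ifelse(local_obs, l, NA_real_),
    local_event = as.integer(local_obs),
    t_distant = ifelse(distant_obs, m, NA_real_),
    distant_event = as.integer(distant_obs),
    t_followup_end = t_end,
    died = as.integer(died)
  )
  class(out) <- c("ni_cohort", "data.frame")
  out
}

# Draw the latent times for n subjects of one arm. `arm_idx` selects the
# column of the per-arm hazard vectors (1 experimental, 2 control).
#
# The scenario's death hazard is the hazard of the *observed* death time.
# Because each subject carries two racing latent death clocks (one linked
# to each recurrence type), each clock gets half the scenario rate: before
# the first recurrence the observed death hazard is then
# h/2 + h/2 = h, matching the stated per-arm death hazard. Giving each
# clock the full rate would double the effective death hazard of the
# generated world.
.draw_latents <- function(spec, n, arm_idx) {
  hd <- spec$hazard_dt[arm_idx] / 2
  p1 <- sample_bivariate_exponential(n, spec$hazard_lr[arm_idx],
                                     hd, spec$rho_l_d1)
  p2 <- sample_bivariate_exponential(n, spec$hazard_mr[arm_idx],
                                     hd, spec$rho_m_d2)
  list(l = p1[, "a"], d1 = p1[, "b"], m = p2[, "a"], d2 = p2[, "b"])
}

# Observed death times for a latent draw, used for censoring calibration:
# censoring is independent of the event process, so given the latent death
# time d the probability of ending in censoring is 1 - exp(-rate * d).
.draw_death_times <- function(spec, n_total, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n_e <- n_total %/% 2L
  n_c <- n_total - n_e
  d <- numeric(0)
  for (a in c(1L, 2L)) {
    n_a <- if (a == 1L) n_e else n_c
    lt <- .draw_latents(spec, n_a, a)
    first <- pmin(lt$l, lt$d1, lt$m, lt$d2)
    d <- c(d, ifelse(first == lt$d1 | first == lt$l, lt$d1, lt$d2))
  }
  d
}

#' Calibrate the exponential censoring rate for a scenario
#'
#' Solves for the exponential censoring rate under which the expected
#' proportion of subjects whose follow-up ends in censoring equals the
#' scenario's `censor_fraction`. A large latent cohort is simulated once;
#' because censoring is independent, the censored probability of a subject
#' with latent death time `d` is `1 - exp(-rate * d)` exactly, so the rate
#' is found by root search on the cohort average of that expression
#' (a Monte-Carlo-in-`d`, exact-in-`c` bisection).
#'
#' @param spec A `scenario_spec`.
#' @param seed Seed for the calibration cohort.
#' @param n Calibration cohort size (default 1e5).
#' @return The censoring rate (0 when `censor_fraction` is 0).
#' @export
calibrate_censoring_rate <- function(spec, seed = 1L, n = 1e5) {
  stopifnot(inherits(spec, "scenario_spec"))
  target <- spec$censor_fraction
  if (target == 0) return(0)
  d <- .draw_death_times(spec, as.integer(n), seed)
  f <- function(rate) mean(1 - exp(-rate * d)) - target
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 4
    if (upper > 1e6) {
      stop("censoring calibration failed to bracket the target; ",
           "f(1e6) = ", signif(f(1e6) + target, 4), call. = FALSE)
    }
  }
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-10)$root
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic substream seed for replicate r of a master seed; keeps the
# derived seed in the 32-bit signed range so replicate r is reproducible
# independently of how many replicates are requested.
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(r)) %% 2147483647)
}

#' Simulate one trial cohort under a scenario
#'
#' Draws `n_per_arm` subjects per arm from the scenario's latent
#' bivariate-exponential model, applies the death-linking and observation
#' rules, and censors with an independent exponential censoring time whose
#' rate is calibrated to the scenario's target censored fraction (unless
#' supplied).
#'
#' @param spec A `scenario_spec`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param censor_rate Optional pre-calibrated censoring rate; when `NULL`
#'   and `censor_fraction > 0` the rate is calibrated first (see
#'   [calibrate_censoring_rate()]).
#' @return An `ni_cohort` data frame with `2 * n_per_arm` rows; arm 1
#'   (experimental) first, then arm 0 (control).
#' @export
simulate_trial <- function(spec, seed = 1L, censor_rate = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(censor_rate)) {
    censor_rate <- calibrate_censoring_rate(spec, seed = replicate_seed(seed, 0))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- spec$n_per_arm
  cohorts <- lapply(c(1L, 2L), function(a) {
    lt <- .draw_latents(spec, n, a)
    cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
    arm <- if (a == 1L) 1L else 0L
    offset <- if (a == 1L) 0L else n
    assemble_subject(lt$l, lt$d1, lt$m, lt$d2, cens, arm,
                     subject_id = offset + seq_len(n))
  })
  out <- rbind(cohorts[[1L]], cohorts[[2L]])
  rownames(out) <- NULL
  class(out) <- c("ni_cohort", "data.frame")
  out
}

#' Write / read a cohort as a delimited table
#'
#' One row per subject with header `subject_id, arm, t_local, local_event,
#' t_distant, distant_event, t_followup_end, died`; missing times are empty
#' fields. `read_cohort` validates the invariants (positive times, event
#' ordering) and rejects non-positive times.
#'
#' @param cohort An `ni_cohort` data frame.
#' @param file Path to a CSV file.
#' @return `read_cohort` returns an `ni_cohort`; `write_cohort` returns
#'   `file` invisibly.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  x <- utils::read.csv(file, na.strings = "")
  needed <- c("subject_id", "arm", "t_local", "local_event", "t_distant",
              "distant_event", "t_followup_end", "died")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[needed]
  x$t_local <- as.numeric(x$t_local)
  x$t_distant <- as.numeric(x$t_distant)
  for (col in c("t_local", "t_distant", "t_followup_end")) {
    bad <- !is.na(x[[col]]) & x[[col]] <= 0
    if (any(bad)) {
      stop("non-positive time in column ", col, " (row ",
           which(bad)[1L], ")", call. = FALSE)
    }
  }
  if (!all(x$arm %in% c(0L, 1L))) stop("arm must be 0/1", call. = FALSE)
  both <- !is.na(x$t_local) & !is.na(x$t_distant)
  if (any(both & x$t_local >= x$t_distant)) {
    stop("t_local must precede t_distant when both observed", call. = FALSE)
  }
  class(x) <- c("ni_cohort", "data.frame")
  x
}
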