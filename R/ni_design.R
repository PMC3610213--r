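# Non-inferiority margin arithmetic, decision rule, and sample size.

#' Convert landmark event rates to a hazard-ratio margin
#'
#' Under proportional hazards with (approximately) exponential event
#' times, a control-arm event probability `p_c` at a landmark time and a
#' maximum tolerable experimental-arm probability `p_e` translate into the
#' hazard-ratio margin `ln(1 - p_e) / ln(1 - p_c)`. For example, 7% vs 12%
#' five-year local recurrence gives a margin of 1.76.
#'
#' @param rate_control Control-arm event probability in (0, 1).
#' @param rate_experimental Maximum tolerable experimental-arm event
#'   probability in (0, 1).
#' @return The hazard-ratio margin.
#' @export
margin_hr_from_rates <- function(rate_control, rate_experimental) {
  if (rate_control <= 0 || rate_control >= 1 ||
      rate_experimental <= 0 || rate_experimental >= 1) {
    stop("event rates must lie strictly in (0, 1)", call. = FALSE)
  }
  log(1 - rate_experimental) / log(1 - rate_control)
}

#' Maximum tolerable event rate implied by a hazard-ratio margin
#'
#' Exact inverse of [margin_hr_from_rates()]:
#' `1 - (1 - rate_control)^margin_hr`. For example, a 10% control rate and
#' margin 1.50 give 14.6%.
#'
#' @param rate_control Control-arm event probability in (0, 1).
#' @param margin_hr Hazard-ratio margin (> 0).
#' @return The experimental-arm event probability.
#' @export
max_rate_from_margin <- function(rate_control, margin_hr) {
  if (rate_control <= 0 || rate_control >= 1) {
    stop("rate_control must lie strictly in (0, 1)", call. = FALSE)
  }
  if (margin_hr <= 0) stop("margin_hr must be > 0", call. = FALSE)
  1 - (1 - rate_control)^margin_hr
}

#' Non-inferiority verdict for a fitted hazard ratio
#'
#' Non-inferiority is concluded when the upper confidence limit of the
#' hazard ratio lies strictly below the margin; a limit exactly equal to
#' the margin is declared not non-inferior.
#'
#' @param fit An `ni_fit` (must have converged) or a list with `hr` and
#'   `ci_high`.
#' @param margin_hr Hazard-ratio margin (> 1 in a usual design).
#' @return A list of class `ni_verdict`: `margin_hr`, `hr`, `ci_high`,
#'   `non_inferior`.
#' @export
assess_ni <- function(fit, margin_hr) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop("cannot assess non-inferiority from a non-converged fit ",
         "(iterations = ", fit$iterations, ")", call. = FALSE)
  }
  structure(list(margin_hr = margin_hr, hr = fit$hr, ci_high = fit$ci_high,
                 non_inferior = fit$ci_high < margin_hr),
            class = "ni_verdict")
}

#' @export
print.ni_verdict <- function(x, ...) {
  cat(sprintf("HR %.3f, upper CI %.3f vs margin %.3f: %s\n",
              x$hr, x$ci_high, x$margin_hr,
              if (x$non_inferior) "non-inferior" else "not non-inferior"))
  invisible(x)
}

#' Sample size for a non-inferiority time-to-event design
#'
#' Schoenfeld event-count formula for testing the hazard ratio against a
#' non-inferiority margin under 1:1 allocation:
#' `d = 4 (z_{1-alpha} + z_{power})^2 / (ln margin - ln true_hr)^2`.
#' Subjects per arm are obtained by dividing the required events by the
#' average landmark event probability of the two arms,
#' `d / (rate_control + rate_max_experimental)`; this approximates a
#' design in which accrual and follow-up yield the landmark probabilities.
#'
#' @param rate_control Control-arm landmark event probability.
#' @param margin_hr Non-inferiority margin (> 1).
#' @param power Desired power.
#' @param alpha_one_sided One-sided significance level.
#' @param true_hr Hazard ratio assumed when computing power (default 1).
#' @return List with `events` / `events_ceiling` and `n_per_arm` /
#'   `n_per_arm_ceiling`.
#' @export
sample_size_ni <- function(rate_control, margin_hr, power = 0.90,
                           alpha_one_sided = 0.025, true_hr = 1.0) {
  if (rate_control <= 0 || rate_control >= 1) {
    stop("rate_control must lie strictly in (0, 1)", call. = FALSE)
  }
  if (margin_hr <= 1) stop("margin_hr must exceed 1", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha_one_sided <= 0 ||
      alpha_one_sided >= 0.5) {
    stop("power in (0,1) and alpha_one_sided in (0, 0.5) required",
         call. = FALSE)
  }
  delta <- log(margin_hr) - log(true_hr)
  if (abs(delta) < .Machine$double.eps^0.5) {
    stop("margin_hr equals true_hr; required sample size is infinite",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha_one_sided) + stats::qnorm(power)
  d <- 4 * z^2 / delta^2
  rate_exp <- max_rate_from_margin(rate_control, margin_hr)
  n_arm <- d / (rate_control + rate_exp)
  list(events = d, events_ceiling = ceiling(d),
       n_per_arm = n_arm, n_per_arm_ceiling = ceiling(n_arm),
       rate_max_experimental = rate_exp)
}
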