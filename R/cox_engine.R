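# Core weighted partial-likelihood engine for a single binary covariate on
# counting-process data (start, stop]. Everything in the package that fits
# a proportional-hazards term (cause-specific Cox, Fine-Gray with IPCW
# weights, WLW strata, frailty inner loop) goes through this engine.
#
# Because the covariate is binary (treatment arm) the risk-set sums at an
# event time t decompose by arm:
#   S0(t) = r0(t) + r1(t) e^beta,   S1(t) = r1(t) e^beta,
# where r_a(t) is the sum of risk weights of arm-a rows with
# start < t <= stop. The r_a(t) do not depend on beta, so they are
# computed once per fit and each Newton iteration costs O(#event times).

# Weighted count of `times >= at` for each element of `at`.
.sum_ge <- function(times, w, at) {
  ord <- order(times)
  cw <- c(0, cumsum(w[ord]))
  total <- cw[length(cw)]
  k <- findInterval(at, times[ord], left.open = TRUE)  # times < at
  total - cw[k + 1L]
}

# Aggregate `w` by event time for rows flagged ev, returning values aligned
# with the sorted unique event-time vector et.
.sum_by_time <- function(et, times, w) {
  out <- numeric(length(et))
  idx <- match(times, et)
  keep <- !is.na(idx)
  if (any(keep)) {
    s <- rowsum(w[keep], idx[keep])
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# Fit the partial likelihood for a binary covariate.
#   start, stop : at-risk interval (start < stop); start may be 0
#   status      : 1 event at stop, 0 otherwise
#   x           : binary covariate 0/1
#   eventwt     : weight of the event contribution (IPCW / case weight)
#   riskwt      : weight of the row in risk sets (IPCW weight times any
#                 frailty factor exp(offset))
#   ties        : "efron" or "breslow"; Efron requires unit weights
# Returns beta, se (inverse information), loglik, baseline increments and
# per-event-time summaries needed for residuals and the frailty E-step.
cox_engine <- function(start, stop, status, x,
                       eventwt = NULL, riskwt = NULL,
                       ties = c("efron", "breslow"),
                       init = 0, tol = 1e-8,
                       max_iter = 50L, max_halving = 10L) {
  ties <- match.arg(ties)
  n <- length(stop)
  if (is.null(start)) start <- numeric(n)
  if (is.null(eventwt)) eventwt <- rep(1, n)
  if (is.null(riskwt)) riskwt <- eventwt
  stopifnot(length(start) == n, length(status) == n, length(x) == n)
  if (any(stop <= start)) stop("need start < stop for every row", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("covariate must be binary 0/1", call. = FALSE)

  ev <- status == 1
  if (!any(ev)) stop("no events in the data", call. = FALSE)
  if (all(x[ev] == x[1L]) && all(x == x[1L])) {
    stop("covariate is constant; no treatment contrast", call. = FALSE)
  }

  et <- sort(unique(stop[ev]))
  K <- length(et)

  # risk sums by arm at each event time
  r0 <- .sum_ge(stop[x == 0], riskwt[x == 0], et) -
        .sum_ge(start[x == 0], riskwt[x == 0], et)
  r1 <- .sum_ge(stop[x == 1], riskwt[x == 1], et) -
        .sum_ge(start[x == 1], riskwt[x == 1], et)

  # event aggregates at each event time
  dwx <- .sum_by_time(et, stop[ev & x == 1], eventwt[ev & x == 1])
  dw0 <- .sum_by_time(et, stop[ev & x == 0], eventwt[ev & x == 0])
  dw <- dw0 + dwx
  dn <- .sum_by_time(et, stop[ev], rep(1, sum(ev)))

  tied <- any(dn > 1)
  if (ties == "efron" && tied) {
    if (any(abs(eventwt - 1) > 1e-12) || any(abs(riskwt - 1) > 1e-12)) {
      stop("Efron tie handling supports unit weights only; use breslow",
           call. = FALSE)
    }
    # risk-weight mass of the event rows themselves, by arm
    ew1 <- .sum_by_time(et, stop[ev & x == 1], riskwt[ev & x == 1])
    ew0 <- .sum_by_time(et, stop[ev & x == 0], riskwt[ev & x == 0])
    # expand: one row per (event time, l), l = 0..d-1
    kk <- rep.int(seq_len(K), dn)
    frac <- sequence(dn) - 1
    frac <- frac / dn[kk]
    efron <- list(kk = kk, frac = frac, ew0 = ew0, ew1 = ew1)
  } else {
    efron <- NULL
  }

  lp_parts <- function(beta) {
    eb <- exp(beta)
    if (is.null(efron)) {
      S0 <- r0 + r1 * eb
      S1 <- r1 * eb
      p <- S1 / S0
      list(loglik = beta * sum(dwx) - sum(dw * log(S0)),
           score = sum(dwx) - sum(dw * p),
           info = sum(dw * p * (1 - p)),
           S0 = S0)
    } else {
      S0k <- r0 + r1 * eb
      S1k <- r1 * eb
      S0 <- S0k[efron$kk] - efron$frac * (efron$ew0 + efron$ew1 * eb)[efron$kk]
      S1 <- S1k[efron$kk] - efron$frac * (efron$ew1 * eb)[efron$kk]
      p <- S1 / S0
      list(loglik = beta * sum(dwx) - sum(log(S0)),
           score = sum(dwx) - sum(p),
           info = sum(p * (1 - p)),
           S0 = S0k)
    }
  }

  beta <- init
  cur <- lp_parts(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (cur$info <= 0) break
    step <- cur$score / cur$info
    new_beta <- beta + step
    new <- lp_parts(new_beta)
    h <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik - 1e-12) &&
           h < max_halving) {
      step <- step / 2
      new_beta <- beta + step
      new <- lp_parts(new_beta)
      h <- h + 1L
    }
    beta <- new_beta
    cur <- new
    if (abs(cur$score) < tol) { converged <- TRUE; break }
    if (abs(beta) > 20) break  # monotone likelihood
  }

  if (abs(beta) > 15) converged <- FALSE  # monotone likelihood
  info <- cur$info
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  # Breslow baseline-hazard increments at the event times (weighted)
  dlambda <- dw / cur$S0
  xbar <- r1 * exp(beta) / cur$S0

  list(beta = beta, se = se, loglik = cur$loglik, info = info,
       converged = converged && is.finite(se), iterations = iter,
       n_events = sum(dn), event_times = et, dlambda = dlambda,
       xbar = xbar, tied = tied)
}

# Per-row score residuals (Breslow form) and clustered sandwich variance.
# `fit` is a cox_engine result on the same rows. Returns the per-cluster
# summed residuals and the robust variance I^-1 (sum g^2) I^-1.
cox_sandwich <- function(fit, start, stop, status, x,
                         eventwt = NULL, riskwt = NULL, cluster = NULL) {
  n <- length(stop)
  if (is.null(start)) start <- numeric(n)
  if (is.null(eventwt)) eventwt <- rep(1, n)
  if (is.null(riskwt)) riskwt <- eventwt
  if (is.null(cluster)) cluster <- seq_len(n)

  et <- fit$event_times
  cumA <- c(0, cumsum(fit$dlambda))
  cumB <- c(0, cumsum(fit$xbar * fit$dlambda))
  idx_stop <- findInterval(stop, et)
  idx_start <- findInterval(start, et)
  dA <- cumA[idx_stop + 1L] - cumA[idx_start + 1L]
  dB <- cumB[idx_stop + 1L] - cumB[idx_start + 1L]

  ev <- status == 1
  xbar_at <- fit$xbar[match(stop, et)]
  resid <- -riskwt * exp(fit$beta * x) * (x * dA - dB)
  resid[ev] <- resid[ev] + eventwt[ev] * (x[ev] - xbar_at[ev])

  g <- rowsum(resid, cluster)
  vrob <- sum(g^2) / fit$info^2
  list(resid = resid, cluster_scores = g, se_robust = sqrt(vrob),
       dfbeta = g / fit$info)
}

.zcrit <- function(conf_level = 0.95) stats::qnorm(1 - (1 - conf_level) / 2)

# Assemble a user-facing fit result from engine output.
.make_fit_result <- function(eng, se_robust = NA_real_,
                             conf_level = 0.95, model = "cox") {
  se_used <- if (is.finite(se_robust)) se_robust else eng$se
  z <- .zcrit(conf_level)
  out <- list(
    beta = eng$beta,
    se_model = eng$se,
    se_robust = se_robust,
    hr = exp(eng$beta),
    ci_low = exp(eng$beta - z * se_used),
    ci_high = exp(eng$beta + z * se_used),
    loglik = eng$loglik,
    n_events = eng$n_events,
    converged = eng$converged,
    iterations = eng$iterations,
    conf_level = conf_level,
    model = model
  )
  class(out) <- "ni_fit"
  out
}

#' @export
print.ni_fit <- function(x, ...) {
  cat(sprintf("%s fit: HR = %.4f (%.0f%% CI %.4f, %.4f)\n",
              x$model, x$hr, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  beta = %.6f  se(model) = %.6f  se(robust) = %s\n",
              x$beta, x$se_model,
              if (is.finite(x$se_robust)) sprintf("%.6f", x$se_robust) else "-"))
  cat(sprintf("  events = %d  loglik = %.4f  converged = %s (%d iter)\n",
              x$n_events, x$loglik, x$converged, x$iterations))
  invisible(x)
}
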