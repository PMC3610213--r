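# User-facing estimators: cause-specific Cox, censoring-distribution
# Kaplan-Meier, Fine-Gray subdistribution model, and the Aalen-Johansen
# cumulative incidence function.

#' Cox proportional hazards fit for a binary treatment
#'
#' Maximizes the partial likelihood by Newton-Raphson with step-halving
#' for a single binary covariate (treatment arm). The model-based standard
#' error comes from the inverse observed information; when `cluster` is
#' supplied a grouped sandwich (robust) standard error is added and used
#' for the confidence interval.
#'
#' @param records Data frame with columns `time`, `status` (1 event,
#'   0 censored) and `arm` (0/1); an optional `start` column gives
#'   counting-process intervals `(start, time]`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param cluster Optional column name or vector grouping rows into
#'   subjects for the robust variance.
#' @param weights Optional case weights (forces Breslow when tied).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `ni_fit`: `beta`, `se_model`, `se_robust`,
#'   `hr`, `ci_low`, `ci_high`, `loglik`, `n_events`, `converged`,
#'   `iterations`.
#' @export
cox_fit <- function(records, ties = c("efron", "breslow"), cluster = NULL,
                    weights = NULL, conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(records),
            all(c("time", "status", "arm") %in% names(records)))
  if (any(records$status == 1) == FALSE) {
    stop("no events in the data", call. = FALSE)
  }
  if (length(unique(records$arm)) < 2L) {
    stop("covariate is constant; no treatment contrast", call. = FALSE)
  }
  start <- if ("start" %in% names(records)) records$start else NULL
  if (is.character(cluster) && length(cluster) == 1L) {
    cluster <- records[[cluster]]
  }
  eng <- cox_engine(start, records$time, records$status, records$arm,
                    eventwt = weights, ties = ties)
  se_robust <- NA_real_
  if (!is.null(cluster)) {
    sw <- cox_sandwich(eng, start, records$time, records$status,
                       records$arm, eventwt = weights, cluster = cluster)
    se_robust <- sw$se_robust
  }
  .make_fit_result(eng, se_robust, conf_level, model = "cox")
}

#' Kaplan-Meier estimate of the censoring survival distribution
#'
#' Product-limit estimator with the roles of event and censoring swapped:
#' censored observations (status 0) are the "events" and true events are
#' censored. Used to build the inverse-probability-of-censoring weights of
#' the Fine-Gray model.
#'
#' @param time Observation times.
#' @param status 0 for censored, any nonzero code for an event.
#' @return A list with `time` (jump times), `surv` (value of G just after
#'   each jump) and an evaluator `g(t)` returning the right-continuous
#'   step function, with `G(0) = 1`.
#' @export
km_censoring <- function(time, status) {
  stopifnot(length(time) == length(status))
  cens <- status == 0
  ut <- sort(unique(time[cens]))
  if (length(ut) == 0L) {
    g <- function(t) rep(1, length(t))
    return(list(time = numeric(0), surv = numeric(0), g = g))
  }
  at_risk <- .sum_ge(time, rep(1, length(time)), ut)
  d <- .sum_by_time(ut, time[cens], rep(1, sum(cens)))
  surv <- cumprod(1 - d / at_risk)
  g <- function(t) {
    idx <- findInterval(t, ut)
    c(1, surv)[idx + 1L]
  }
  list(time = ut, surv = surv, g = g)
}

# Expand competing-risk records into the IPCW counting-process layout of
# the Fine-Gray model. Subjects with the event of interest or censoring
# contribute a single row (0, T]. A subject with a competing event at T
# stays in the risk set after T with time-varying weight G(t)/G(T); the
# weight is a step function that drops at each censoring time, so the
# subject is expanded into one row per censoring interval up to the last
# event-of-interest time (later intervals carry no event mass).
fg_expand <- function(records) {
  stopifnot(all(c("subject_id", "arm", "time", "status") %in% names(records)))
  G <- km_censoring(records$time, records$status)
  base <- data.frame(subject_id = records$subject_id, arm = records$arm,
                     start = 0, stop = records$time,
                     status = as.integer(records$status == 1L),
                     fgwt = 1)
  comp <- records[records$status == 2L, , drop = FALSE]
  if (nrow(comp) == 0L) return(base)

  horizon <- max(records$time[records$status == 1L])
  comp <- comp[comp$time < horizon, , drop = FALSE]
  if (nrow(comp) == 0L) return(base)

  # vectorized interval construction: subject i with competing event at
  # T_i gets one row per censoring interval in (T_i, horizon]
  cuts <- G$time[G$time < horizon]
  K <- length(cuts)
  ki <- findInterval(comp$time, cuts)       # cuts <= T_i
  n_i <- K - ki + 1L
  sub <- rep.int(seq_len(nrow(comp)), n_i)
  j <- sequence(n_i)
  pos <- ki[sub] + j - 1L                   # cut index of the row's start
  first <- j == 1L
  last <- j == n_i[sub]
  start <- numeric(length(j))
  start[first] <- comp$time[sub[first]]
  start[!first] <- cuts[pos[!first]]
  stop_ <- rep.int(horizon, length(j))
  stop_[!last] <- cuts[pos[!last] + 1L]
  g_ti <- G$g(comp$time)
  gstart <- numeric(length(j))
  gstart[first] <- g_ti[sub[first]]
  gstart[!first] <- G$surv[pos[!first]]
  ext <- data.frame(subject_id = comp$subject_id[sub], arm = comp$arm[sub],
                    start = start, stop = stop_, status = 0L,
                    fgwt = gstart / g_ti[sub])
  out <- rbind(base, ext)
  out <- out[out$fgwt > 1e-12 & out$stop > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fine-Gray subdistribution hazard fit
#'
#' Fits the proportional-subdistribution-hazards model for a binary
#' treatment. Subjects with a competing event remain in the risk set
#' after their event time with time-varying weight `G(t)/G(T_i)`, where
#' `G` is the Kaplan-Meier estimate of the censoring distribution in the
#' pooled sample; truly censored subjects leave at censoring. With no
#' competing events the fit is identical to [cox_fit()].
#'
#' The default standard error is a subject-grouped sandwich over the
#' weighted score residuals, treating `G` as fixed; the model-based
#' inverse-information standard error is also returned.
#'
#' @param records Data frame with `subject_id`, `arm`, `time`, `status`
#'   (0 censored, 1 event of interest, 2 competing event), as produced by
#'   [to_competing()].
#' @param ties Tie rule for the weighted partial likelihood; weighted
#'   expansions use `"breslow"`.
#' @param se One of `"robust"` (default, used for the CI) or `"model"`.
#' @param conf_level Confidence level.
#' @return An `ni_fit` (model label `"fine-gray"`).
#' @export
fine_gray_fit <- function(records, ties = c("breslow", "efron"),
                          se = c("robust", "model"), conf_level = 0.95) {
  ties <- match.arg(ties)
  se <- match.arg(se)
  stopifnot(is.data.frame(records),
            all(c("subject_id", "arm", "time", "status") %in% names(records)))
  if (!all(records$status %in% 0:2)) {
    stop("status must be coded 0/1/2", call. = FALSE)
  }
  if (!any(records$status == 1L)) {
    stop("no events of interest", call. = FALSE)
  }
  xp <- fg_expand(records)
  weighted <- any(xp$fgwt != 1)
  eng <- cox_engine(xp$start, xp$stop, xp$status, xp$arm,
                    eventwt = xp$fgwt,
                    ties = if (weighted) "breslow" else ties)
  sw <- cox_sandwich(eng, xp$start, xp$stop, xp$status, xp$arm,
                     eventwt = xp$fgwt, cluster = xp$subject_id)
  .make_fit_result(eng,
                   se_robust = sw$se_robust,
                   conf_level = conf_level, model = "fine-gray") -> out
  if (se == "model") {
    z <- .zcrit(conf_level)
    out$ci_low <- exp(out$beta - z * out$se_model)
    out$ci_high <- exp(out$beta + z * out$se_model)
  }
  out
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric cumulative incidence for each cause:
#' `CIF_j(t) = sum over event times u <= t of S(u-) dN_j(u) / Y(u)`,
#' with `S` the all-cause Kaplan-Meier. At every event time the identity
#' `sum_j CIF_j(t) + S(t) = 1` holds.
#'
#' @param records Data frame with `time` and `status` (0 censored, 1, 2,
#'   ... causes).
#' @return A list with `time` (all-cause event times), `surv` (all-cause
#'   KM), and `cif`, a matrix with one column per cause code.
#' @export
estimate_cif <- function(records) {
  stopifnot(all(c("time", "status") %in% names(records)))
  causes <- sort(unique(records$status[records$status != 0]))
  if (length(causes) == 0L) stop("no events", call. = FALSE)
  ev <- records$status != 0
  ut <- sort(unique(records$time[ev]))
  ones <- rep(1, nrow(records))
  at_risk <- .sum_ge(records$time, ones, ut)
  d_all <- .sum_by_time(ut, records$time[ev], rep(1, sum(ev)))
  surv <- cumprod(1 - d_all / at_risk)
  surv_minus <- c(1, surv[-length(surv)])
  cif <- sapply(causes, function(j) {
    ji <- records$status == j
    dj <- .sum_by_time(ut, records$time[ji], rep(1, sum(ji)))
    cumsum(surv_minus * dj / at_risk)
  })
  cif <- matrix(cif, nrow = length(ut),
                dimnames = list(NULL, paste0("cause_", causes)))
  list(time = ut, surv = surv, cif = cif)
}
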