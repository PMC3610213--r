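# Reshaping of subject histories into the three analysis layouts:
# WLW long format (three strata per subject), competing-risk coding, and
# counting records for the shared frailty model.

.check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  needed <- c("subject_id", "arm", "t_local", "local_event", "t_distant",
              "distant_event", "t_followup_end", "died")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Reshape a cohort to the WLW long format
#'
#' Produces exactly three records per subject, one per event stratum
#' (local, distant, death). A stratum whose event was not observed is
#' censored at the latest time the subject is known to be event-free for
#' that stratum: local recurrence is censored at the distant-recurrence
#' time when a distant recurrence occurred first, at the death time when
#' only death occurred, and at the end of follow-up otherwise; distant
#' recurrence is censored at death or end of follow-up; death is censored
#' at end of follow-up.
#'
#' @param cohort An `ni_cohort` data frame (see [simulate_trial()]).
#' @return A data frame with columns `subject_id`, `arm`, `stratum`
#'   (factor local/distant/death), `time`, `status`.
#' @export
to_wlw_long <- function(cohort) {
  .check_cohort(cohort)
  n <- nrow(cohort)
  t_end <- cohort$t_followup_end
  died <- cohort$died == 1L
  loc <- cohort$local_event == 1L
  dis <- cohort$distant_event == 1L

  # local stratum: event at t_local; otherwise censored at the first
  # terminating observation (distant recurrence, death, or follow-up end)
  local_time <- ifelse(loc, cohort$t_local,
                ifelse(dis, cohort$t_distant, t_end))
  local_status <- as.integer(loc)

  # distant stratum: death or follow-up end censors
  distant_time <- ifelse(dis, cohort$t_distant, t_end)
  distant_status <- as.integer(dis)

  death_time <- t_end
  death_status <- as.integer(died)

  out <- data.frame(
    subject_id = rep(cohort$subject_id, 3L),
    arm = rep(cohort$arm, 3L),
    stratum = factor(rep(c("local", "distant", "death"), each = n),
                     levels = c("local", "distant", "death")),
    time = c(local_time, distant_time, death_time),
    status = c(local_status, distant_status, death_status)
  )
  out[order(match(out$subject_id, cohort$subject_id)), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Competing-risks coding of a cohort for one event of interest
#'
#' Status is 0 for censored, 1 for the event of interest, 2 for a competing
#' event. For local recurrence, distant recurrence and death compete; for
#' distant recurrence, death competes and local recurrence is ignored; for
#' death the coding reduces to plain survival coding since death is always
#' observable.
#'
#' @param cohort An `ni_cohort` data frame.
#' @param event One of `"local"`, `"distant"`, `"death"`.
#' @return Data frame with `subject_id`, `arm`, `time`, `status`.
#' @export
to_competing <- function(cohort, event = c("local", "distant", "death")) {
  .check_cohort(cohort)
  event <- match.arg(event)
  t_end <- cohort$t_followup_end
  died <- cohort$died == 1L
  loc <- cohort$local_event == 1L
  dis <- cohort$distant_event == 1L

  if (event == "local") {
    # first of {local, distant, death, censoring}; local can only be first
    time <- ifelse(loc, cohort$t_local,
            ifelse(dis, cohort$t_distant, t_end))
    status <- ifelse(loc, 1L, ifelse(dis | died, 2L, 0L))
  } else if (event == "distant") {
    time <- ifelse(dis, cohort$t_distant, t_end)
    status <- ifelse(dis, 1L, ifelse(died, 2L, 0L))
  } else {
    time <- t_end
    status <- ifelse(died, 1L, 0L)
  }
  data.frame(subject_id = cohort$subject_id, arm = cohort$arm,
             time = time, status = as.integer(status))
}

#' Cause-specific (censoring) coding for one event of interest
#'
#' Same layout as [to_competing()] but with competing events recoded as
#' plain censoring (status 0), as used by the cause-specific Cox model.
#'
#' @inheritParams to_competing
#' @return Data frame with `subject_id`, `arm`, `time`, `status` in {0, 1}.
#' @export
to_cause_specific <- function(cohort, event = c("local", "distant", "death")) {
  x <- to_competing(cohort, event)
  x$status[x$status == 2L] <- 0L
  x
}

#' Counting records for the shared frailty model
#'
#' Every subject contributes one vital-status record (follow-up end, died
#' flag) plus one record per observed recurrence, all on the time scale
#' from randomization; the shared `subject_id` drives the frailty grouping.
#'
#' @param cohort An `ni_cohort` data frame.
#' @return Data frame with `subject_id`, `arm`, `time`, `status`,
#'   `record_role` (`"recurrence"` or `"vital_status"`).
#' @export
to_counting <- function(cohort) {
  .check_cohort(cohort)
  recs <- list(
    data.frame(subject_id = cohort$subject_id, arm = cohort$arm,
               time = cohort$t_local, status = 1L,
               record_role = "recurrence")[cohort$local_event == 1L, ],
    data.frame(subject_id = cohort$subject_id, arm = cohort$arm,
               time = cohort$t_distant, status = 1L,
               record_role = "recurrence")[cohort$distant_event == 1L, ],
    data.frame(subject_id = cohort$subject_id, arm = cohort$arm,
               time = cohort$t_followup_end, status = cohort$died,
               record_role = "vital_status")
  )
  out <- do.call(rbind, recs)
  out <- out[order(match(out$subject_id, cohort$subject_id), out$time), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
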