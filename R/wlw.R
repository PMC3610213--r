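# Wei-Lin-Weissfeld marginal model: stratified Cox fits with
# stratum-specific treatment effects, a subject-grouped robust covariance
# across strata, and a weighted-average overall effect.

.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Wei-Lin-Weissfeld marginal model
#'
#' Fits one Cox model per event stratum (treatment-by-stratum interaction,
#' stratum-specific baseline hazards), so each per-stratum coefficient
#' equals the corresponding single-stratum Cox fit exactly. Dependence
#' between a subject's event times is handled by a robust sandwich
#' covariance of the stratum coefficients built from subject-grouped
#' score residuals. The overall ("average") treatment effect is the
#' minimum-variance linear combination of the stratum coefficients under
#' the robust covariance (weights proportional to the row sums of its
#' inverse, normalized to sum to one); `weighting = "equal"` averages with
#' equal weights instead.
#'
#' @param long_records Data frame as produced by [to_wlw_long()]: columns
#'   `subject_id`, `arm`, `stratum`, `time`, `status`.
#' @param ties Tie rule for the per-stratum fits.
#' @param weighting `"min_variance"` (default) or `"equal"`.
#' @param conf_level Confidence level.
#' @return An object of class `wlw_fit`: `per_stratum` (named list of
#'   `ni_fit`, CI from the robust SE), `vcov_robust` (covariance of the
#'   stratum betas), `beta_bar`, `se_bar`, `hr_bar`, `ci_low_bar`,
#'   `ci_high_bar`, `weights`.
#' @export
wlw_fit <- function(long_records, ties = c("efron", "breslow"),
                    weighting = c("min_variance", "equal"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  weighting <- match.arg(weighting)
  stopifnot(all(c("subject_id", "arm", "stratum", "time", "status") %in%
                  names(long_records)))
  strata <- if (is.factor(long_records$stratum)) {
    levels(long_records$stratum)
  } else unique(long_records$stratum)

  subjects <- unique(long_records$subject_id)
  D <- matrix(0, nrow = length(subjects), ncol = length(strata),
              dimnames = list(NULL, strata))
  fits <- stats::setNames(vector("list", length(strata)), strata)
  ok <- logical(length(strata))
  z <- .zcrit(conf_level)

  for (j in seq_along(strata)) {
    rows <- long_records[long_records$stratum == strata[j], , drop = FALSE]
    if (!any(rows$status == 1)) {
      warning("stratum '", strata[j],
              "' has no events; dropped from the average", call. = FALSE)
      next
    }
    eng <- cox_engine(NULL, rows$time, rows$status, rows$arm, ties = ties)
    sw <- cox_sandwich(eng, NULL, rows$time, rows$status, rows$arm,
                       cluster = rows$subject_id)
    fits[[j]] <- .make_fit_result(eng, sw$se_robust, conf_level,
                                  model = paste0("wlw:", strata[j]))
    # dfbeta rows aligned to the global subject list (a subject absent from
    # a stratum contributes zero)
    D[match(rownames(sw$dfbeta), as.character(subjects)), j] <-
      sw$dfbeta[, 1L]
    ok[j] <- TRUE
  }
  if (!any(ok)) stop("no stratum has events", call. = FALSE)

  V <- crossprod(D[, ok, drop = FALSE])
  betas <- vapply(fits[ok], `[[`, numeric(1), "beta")
  w <- if (weighting == "min_variance") {
    # pseudo-inverse guards the degenerate case of perfectly correlated
    # strata (singular robust covariance), where any normalized weights
    # attain the same variance
    Vi <- .pinv(V)
    rowSums(Vi) / sum(Vi)
  } else {
    rep(1 / sum(ok), sum(ok))
  }
  beta_bar <- sum(w * betas)
  se_bar <- sqrt(drop(t(w) %*% V %*% w))

  out <- list(
    per_stratum = fits,
    vcov_robust = V,
    beta_bar = beta_bar,
    se_bar = se_bar,
    hr_bar = exp(beta_bar),
    ci_low_bar = exp(beta_bar - z * se_bar),
    ci_high_bar = exp(beta_bar + z * se_bar),
    weights = stats::setNames(w, strata[ok]),
    conf_level = conf_level
  )
  class(out) <- "wlw_fit"
  out
}

#' @export
print.wlw_fit <- function(x, ...) {
  cat("WLW marginal model\n")
  for (nm in names(x$per_stratum)) {
    f <- x$per_stratum[[nm]]
    if (is.null(f)) next
    cat(sprintf("  %-8s HR = %.4f (%.4f, %.4f)  [robust se %.4f]\n",
                nm, f$hr, f$ci_low, f$ci_high, f$se_robust))
  }
  cat(sprintf("  average  HR = %.4f (%.4f, %.4f)  weights: %s\n",
              x$hr_bar, x$ci_low_bar, x$ci_high_bar,
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}
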