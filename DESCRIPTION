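Package: nicomprisk
Title: Multiple Time-to-Event Estimators for Non-Inferiority Trials
Version: 0.1.0
Authors@R:
    person("nicomprisk", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing time-to-event estimators in non-inferiority
    trials where subjects are at risk for several event types (for example
    local recurrence, distant recurrence and death in breast cancer trials).
    Implements, from first principles, the cause-specific Cox proportional
    hazards model, the Fine-Gray subdistribution hazard model with
    censoring-weighted risk sets, the Wei-Lin-Weissfeld marginal model with a
    robust sandwich variance and an averaged treatment effect, and a shared
    gamma frailty model fitted by EM. Includes a latent-failure-time simulator
    for semi-competing risks with correlated exponential margins, calibrated
    independent censoring, non-inferiority margin arithmetic, and a replication
    pipeline that aggregates hazard ratios on the log scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite
Config/testthat/edition: 3
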