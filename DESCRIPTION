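Package: wardsim
Title: Monte Carlo Simulation of Hospital Ward Nurse Staffing
Version: 0.1.0
Authors@R:
    person("Ward", "Simulation Team", email = "wardsim@example.org",
           role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation of nurse staffing on hospital
    inpatient wards. Compares baseline staffing establishments (mean demand,
    80 percent of mean, 90th percentile of demand over an observation window)
    under flexible staffing policies (within-division redeployment, bank and
    agency hires with limited short-notice availability). Ward demand follows
    a five-level acuity/dependency classification with configurable hours per
    patient-day, short-notice sickness absence, and productivity discounts for
    redeployed and temporary staff. Outcomes are understaffed and overstaffed
    patient shifts under a tolerance band and staffing cost per patient-day,
    aggregated over replications with t-based confidence intervals. Includes a
    synthetic hospital generator so the full pipeline runs without any
    confidential hospital extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
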