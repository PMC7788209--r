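#' Care-hours multipliers per acuity level
#'
#' Hours of nursing care per patient-day for each of the five
#' acuity/dependency levels (0, 1a, 1b, 2, 3). The defaults are synthetic
#' placeholders ordered like published acuity tools and scaled so that a
#' typical general-ward mix yields roughly 6-7 nursing hours per
#' patient-day, the establishment scale reported for English acute wards;
#' the real instrument's multipliers are licensed and therefore
#' configuration, not constants. Keeping the per-period establishment large
#' relative to the 4/6-hour deployment blocks matters: with much smaller
#' multipliers, block rounding dominates the tolerance band and inflates
#' both outcome tails.
#'
#' @param hours_per_patient_day 5 strictly positive reals; the level-3
#'   multiplier must be the maximum.
#' @return numeric vector of class `care_multipliers`.
#' @export
care_multipliers <- function(hours_per_patient_day =
                               c(4.2, 5.8, 7.2, 8.4, 24.0)) {
  m <- as.numeric(hours_per_patient_day)
  if (length(m) != 5 || any(m <= 0))
    stop("care_multipliers: need 5 strictly positive values")
  if (max(m) != m[5])
    stop("care_multipliers: the level-3 multiplier must be the maximum")
  structure(m, class = "care_multipliers")
}

#' Simulation parameter set
#'
#' Bundles the demand-side and engine parameters that are configuration
#' rather than scenario: care multipliers, requirement noise, short-notice
#' absence rates, the tolerance band and the length of the simulated year.
#'
#' @param multipliers a [care_multipliers()] vector.
#' @param noise_cv coefficient of variation of the per-level multiplicative
#'   requirement noise (lognormal, mean 1); 0 disables noise.
#' @param absence named probabilities `c(rn = , hca = )` that a planned
#'   person-block is lost to short-notice sickness.
#' @param tau tolerance fraction of the adequate band (default 0.15).
#' @param specialing_group staff group that absorbs specialing hours
#'   (`"hca"` or `"rn"`).
#' @param days simulated days per replication (default 365).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(multipliers = care_multipliers(),
                       noise_cv = 0.1,
                       absence = c(rn = 0.03, hca = 0.04),
                       tau = 0.15,
                       specialing_group = "hca",
                       days = 365L) {
  if (noise_cv < 0) stop("sim_params: 'noise_cv' must be >= 0")
  if (any(absence < 0 | absence > 1))
    stop("sim_params: absence rates must lie in [0, 1]")
  if (tau < 0 || tau >= 1) stop("sim_params: 'tau' must lie in [0, 1)")
  if (!specialing_group %in% c("rn", "hca"))
    stop("sim_params: 'specialing_group' must be 'rn' or 'hca'")
  structure(list(multipliers = multipliers, noise_cv = noise_cv,
                 absence = absence[c("rn", "hca")], tau = tau,
                 specialing_group = specialing_group,
                 days = as.integer(days)),
            class = "sim_params")
}

# Hours of one whole person-shift (the four daily periods are 6 h each).
SHIFT_HOURS <- 6

#' Estimate the staffing requirement for one shift census
#'
#' Daily care hours are `sum(counts * multipliers)`; the shift receives that
#' total scaled by the period's diurnal weight. Each specialed patient adds
#' one whole person-shift (6 h) on top. General hours split between
#' registered nurses and assistants by the ward skill mix; specialing hours
#' go to the configured group.
#'
#' @param census a `shift_census` (see [sample_shift_census()]).
#' @param m a [care_multipliers()] vector.
#' @param diurnal_profile the ward's 4 period weights.
#' @param skill_mix registered-nurse fraction of general care hours.
#' @param specialing_group `"hca"` (default) or `"rn"`.
#' @return list of class `demand_estimate` with `rn_hours`, `hca_hours`,
#'   `total_hours`.
#' @export
estimate_demand <- function(census, m, diurnal_profile, skill_mix,
                            specialing_group = "hca") {
  w <- diurnal_profile[census$period_index + 1]
  stopifnot(w >= 0, w <= 1)
  general <- sum(census$counts_by_level * as.numeric(m)) * w
  spec <- SHIFT_HOURS * census$specialing_count
  rn <- skill_mix * general + if (specialing_group == "rn") spec else 0
  hca <- (1 - skill_mix) * general + if (specialing_group == "hca") spec else 0
  structure(list(ward_id = census$ward_id, day_index = census$day_index,
                 period_index = census$period_index,
                 rn_hours = rn, hca_hours = hca,
                 total_hours = rn + hca),
            class = "demand_estimate")
}

# sdlog of a mean-1 lognormal with coefficient of variation cv
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Realize the actual (noisy) staffing requirement
#'
#' Patients' true needs vary from the typical need for their
#' acuity/dependency category: each level's hours contribution is multiplied
#' by an independent lognormal factor with mean 1 and coefficient of
#' variation `noise_cv`. Specialing hours are not noised (a specialed
#' patient needs exactly one person). With `noise_cv = 0` the actual
#' requirement equals the estimate exactly.
#'
#' @param census the `shift_census` the estimate was built from.
#' @param m care multipliers.
#' @param diurnal_profile,skill_mix,specialing_group as in
#'   [estimate_demand()].
#' @param noise_cv coefficient of variation (>= 0).
#' @param streams RNG substreams; the `noise` stream is consumed.
#' @return list of class `actual_requirement` with the same shape as a
#'   demand estimate.
#' @export
realize_actual_requirement <- function(census, m, diurnal_profile, skill_mix,
                                       noise_cv, streams,
                                       specialing_group = "hca") {
  stopifnot(noise_cv >= 0)
  f <- if (noise_cv == 0) rep(1, 5) else with_stream(streams, "noise", {
    s <- lognormal_sdlog(noise_cv)
    stats::rlnorm(5, meanlog = -s^2 / 2, sdlog = s)
  })
  w <- diurnal_profile[census$period_index + 1]
  general <- sum(census$counts_by_level * as.numeric(m) * f) * w
  spec <- SHIFT_HOURS * census$specialing_count
  rn <- skill_mix * general + if (specialing_group == "rn") spec else 0
  hca <- (1 - skill_mix) * general + if (specialing_group == "hca") spec else 0
  structure(list(ward_id = census$ward_id, day_index = census$day_index,
                 period_index = census$period_index,
                 rn_hours = rn, hca_hours = hca,
                 total_hours = rn + hca),
            class = "actual_requirement")
}
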