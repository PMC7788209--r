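#' Baseline staffing scenario specification
#'
#' The three establishment-setting rules compared by the simulation, applied
#' to daily demand totals observed over a planning window (default 20 days,
#' emulating the tool guidance of rating 20 days in a reference month):
#' `standard` = mean daily demand, `low` = 80\% of the mean, `high` = the
#' empirical 90th percentile of daily demand.
#'
#' @param name one of `"low"`, `"standard"`, `"high"`.
#' @param observation_days length of the planning window (default 20).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("standard", "low", "high"),
                          observation_days = 20L) {
  name <- match.arg(name)
  if (observation_days < 1)
    stop("scenario_spec: 'observation_days' must be >= 1")
  statistic <- switch(name, standard = "mean", low = "mean_x0.8",
                      high = "p90")
  structure(list(name = name, statistic = statistic,
                 observation_days = as.integer(observation_days)),
            class = "scenario_spec")
}

#' Simulate the demand observation window for one ward
#'
#' Simulates `observation_days` days of census (all four periods) and
#' returns the daily summed requirement hours. The window represents the
#' classified (tool-measured) demand records an establishment would be
#' planned from, so requirement noise is off; specialing demand is included.
#'
#' @param ward a [ward_profile()].
#' @param multipliers care multipliers.
#' @param observation_days window length.
#' @param streams RNG substreams dedicated to planning (conventionally
#'   seeded from `base_seed - 1` so the window is independent of the
#'   simulated year).
#' @param specialing_group group absorbing specialing hours.
#' @return numeric vector of length `observation_days` (daily hours).
#' @export
observe_demand_window <- function(ward, multipliers, observation_days,
                                  streams, specialing_group = "hca") {
  stopifnot(observation_days >= 1)
  vapply(seq_len(observation_days) - 1L, function(day) {
    sum(vapply(0:3, function(p) {
      cen <- sample_shift_census(ward, day, p, streams)
      estimate_demand(cen, multipliers, ward$diurnal_profile,
                      ward$skill_mix, specialing_group)$total_hours
    }, numeric(1)))
  }, numeric(1))
}

#' Baseline daily hours from an observation window
#'
#' @param daily_hours non-empty numeric vector of observed daily demand.
#' @param scenario a [scenario_spec()].
#' @return daily baseline hours (real, before distribution and rounding).
#'   `standard` is the arithmetic mean, `low` is 0.8 times the mean, and
#'   `high` is the empirical 90th percentile computed by linear
#'   interpolation between order statistics at plotting positions
#'   `(i - 1) / (n - 1)` (R's default quantile type 7).
#' @export
baseline_from_window <- function(daily_hours, scenario) {
  if (length(daily_hours) == 0)
    stop("baseline_from_window: empty observation window")
  switch(scenario$name,
         standard = mean(daily_hours),
         low = 0.8 * mean(daily_hours),
         high = unname(stats::quantile(daily_hours, 0.9, type = 7)))
}

#' Round hours to the nearest deployable block sum
#'
#' Staff are deployed in 4-hour and 6-hour blocks, so achievable per-period
#' hours are non-negative integer combinations of 4 and 6:
#' `{0, 4, 6, 8, 10, 12, ...}` (every even number except 2). Values round to
#' the nearest achievable sum; exact ties round up.
#'
#' @param x non-negative hours (vectorised).
#' @return nearest achievable block sums.
#' @export
round_to_block_sum <- function(x) {
  stopifnot(all(x >= 0))
  vapply(x, function(v) {
    if (v <= 2) return(if (v < 2) 0 else 4)   # tie at 2 rounds up to 4
    if (v < 4) return(4)
    lo <- 2 * floor(v / 2)
    hi <- lo + 2
    if (v - lo < hi - v) lo else hi           # tie (v - lo == 1) rounds up
  }, numeric(1))
}

# Decompose an achievable block sum into person-blocks (6 h preferred,
# remainder covered with one or two 4 h blocks). Used to record the block
# multiset that sickness absence acts on.
plan_blocks <- function(hours) {
  if (hours == 0) return(numeric(0))
  r <- hours %% 6
  if (r == 0) rep(6, hours / 6)
  else if (r == 4) c(rep(6, (hours - 4) / 6), 4)
  else c(rep(6, (hours - 8) / 6), 4, 4)        # r == 2, hours >= 8
}

#' Distribute a daily baseline over periods and round to blocks
#'
#' Splits daily baseline hours over the four 6-hour periods by the ward's
#' diurnal profile, splits each period between registered nurses and
#' assistants by skill mix, then rounds each (period, group) value to the
#' nearest deployable block sum ([round_to_block_sum()]).
#'
#' @param daily_hours daily baseline hours (>= 0).
#' @param diurnal_profile 4 period weights.
#' @param skill_mix registered-nurse fraction.
#' @return data frame with columns `period` (0..3), `group` (`rn`/`hca`) and
#'   `hours`.
#' @export
distribute_and_round <- function(daily_hours, diurnal_profile, skill_mix) {
  stopifnot(daily_hours >= 0)
  per <- daily_hours * diurnal_profile
  data.frame(
    period = rep(0:3, each = 2),
    group = rep(c("rn", "hca"), 4),
    hours = as.vector(rbind(round_to_block_sum(per * skill_mix),
                            round_to_block_sum(per * (1 - skill_mix)))),
    stringsAsFactors = FALSE)
}

#' Plan establishments for every ward of a hospital
#'
#' Runs the observation window for each ward (a dedicated RNG seeded from
#' `base_seed - 1`, so the window is independent of any simulated year),
#' applies the scenario statistic, distributes over periods and rounds to
#' deployable blocks.
#'
#' @param hospital a [hospital_profile()].
#' @param scenario a [scenario_spec()] or scenario name.
#' @param params a [sim_params()].
#' @param base_seed base seed of the experiment (the window uses
#'   `base_seed - 1`).
#' @return object of class `establishment_plan`: a data frame
#'   (`ward_id`, `period`, `group`, `hours`) plus attributes `scenario`,
#'   `daily_total` (named per-ward daily hours) and
#'   `hours_per_patient_day_at_mean_census`.
#' @export
plan_hospital <- function(hospital, scenario = scenario_spec("standard"),
                          params = sim_params(), base_seed = 1) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  streams <- make_rng_streams(base_seed - 1)
  rows <- lapply(hospital$wards, function(w) {
    window <- observe_demand_window(w, params$multipliers,
                                    scenario$observation_days, streams,
                                    params$specialing_group)
    daily <- baseline_from_window(window, scenario)
    d <- distribute_and_round(daily, w$diurnal_profile, w$skill_mix)
    d$ward_id <- w$ward_id
    d[, c("ward_id", "period", "group", "hours")]
  })
  plan <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  daily_total <- tapply(plan$hours, plan$ward_id, sum)
  mean_census <- vapply(hospital$wards, function(w)
    mean(sapply(1:7, function(d) sum(w$census_dist[d, ] * (0:w$beds)))),
    numeric(1))
  hppd <- daily_total[names(mean_census)] / mean_census
  structure(plan, class = c("establishment_plan", "data.frame"),
            scenario = scenario,
            daily_total = daily_total,
            hours_per_patient_day_at_mean_census = hppd)
}
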