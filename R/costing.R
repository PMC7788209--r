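#' Staff pay-rate table
#'
#' Hourly base rates per staff group and pay band, the employer on-cost
#' fraction (superannuation and national insurance), agency capped hourly
#' rates, and the unsocial-hours uplift rule. All monetary values are
#' configuration stand-ins for national reference costs, which are not
#' distributed with the package.
#'
#' Channel pricing: permanent staff cost `base * (1 + oncost)` per hour;
#' bank staff attract employer on-costs on only half of hours worked, so
#' cost `base * (1 + 0.5 * oncost)` (slightly cheaper than permanent in the
#' same band); agency staff cost the capped rate regardless of on-costs.
#'
#' @param bands data frame with columns `group`, `band`, `base_rate`,
#'   `agency_cap`.
#' @param oncost employer on-cost fraction (>= 0).
#' @param unsocial list with `uplift` (fraction added to the permanent/bank
#'   hourly rate), `night_period` (period index receiving the uplift every
#'   day) and `weekend_all` (logical: uplift every period on Saturday and
#'   Sunday). Agency caps are treated as all-inclusive (no uplift).
#' @return list of class `rate_table`.
#' @export
rate_table <- function(bands = default_bands(), oncost = 0.30,
                       unsocial = list(uplift = 0.30, night_period = 3,
                                       weekend_all = TRUE)) {
  stopifnot(all(c("group", "band", "base_rate", "agency_cap") %in%
                  names(bands)))
  if (any(bands$base_rate < 0) || any(bands$agency_cap < 0) || oncost < 0 ||
      unsocial$uplift < 0)
    stop("rate_table: rates and fractions must be >= 0")
  structure(list(bands = bands, oncost = oncost, unsocial = unsocial),
            class = "rate_table")
}

default_bands <- function() {
  data.frame(
    group = c("rn", "rn", "rn", "hca", "hca"),
    band = c("band5", "band6", "band7", "band2", "band3"),
    base_rate = c(17, 21, 25, 10.5, 11.5),
    agency_cap = c(26, 32, 38, 16, 18),
    stringsAsFactors = FALSE)
}

#' Hourly cost of one staffed hour
#'
#' @param group `"rn"` or `"hca"`.
#' @param band pay band present in the rate table.
#' @param channel `"permanent"`, `"bank"` or `"agency"`.
#' @param rates a [rate_table()].
#' @return cost per hour (currency).
#' @export
hourly_rate <- function(group, band, channel, rates) {
  i <- which(rates$bands$group == group & rates$bands$band == band)
  if (!length(i))
    stop("hourly_rate: unknown band '", band, "' for group '", group,
         "'; known: ",
         paste(rates$bands$band[rates$bands$group == group],
               collapse = ", "))
  base <- rates$bands$base_rate[i]
  switch(channel,
         permanent = base * (1 + rates$oncost),
         bank = base * (1 + 0.5 * rates$oncost),
         agency = rates$bands$agency_cap[i],
         stop("hourly_rate: unknown channel '", channel, "'"))
}

# band-mix-weighted hourly rate for one group/channel
weighted_rate <- function(group, band_mix, channel, rates) {
  sum(vapply(names(band_mix), function(b)
    band_mix[[b]] * hourly_rate(group, b, channel, rates), numeric(1)))
}

#' Default hospital-level band mix for temporary staff
#' @return list of named proportion vectors per group.
#' @export
default_temp_band_mix <- function() {
  list(rn = c(band5 = 0.85, band6 = 0.15), hca = c(band2 = 1.0))
}

#' Cost a simulated year
#'
#' Permanent staff are salaried: their cost accrues on the full planned
#' establishment for every simulated day, whether or not individuals were
#' absent, and redeployed hours are cost-neutral. Bank and agency staff are
#' priced per worked hour at the hospital-level temporary band mix. The
#' unsocial-hours uplift adds `uplift * rate` per qualifying hour (night
#' period every day, all periods at weekends) for permanent and bank staff;
#' agency caps are all-inclusive. A patient-day is four patient shifts.
#'
#' @param records record data frame from [simulate_year()].
#' @param plan the establishment plan the records were simulated under.
#' @param hospital the [hospital_profile()] (for per-ward permanent band
#'   mixes).
#' @param rates a [rate_table()].
#' @param temp_band_mix hospital-level band mix for temporary staff.
#' @return list of class `cost_breakdown` with `permanent_cost`,
#'   `bank_cost`, `agency_cost`, `unsocial_supplement`, `total_cost`,
#'   `patient_days`, `cost_per_patient_day`.
#' @export
cost_year <- function(records, plan, hospital, rates = rate_table(),
                      temp_band_mix = default_temp_band_mix()) {
  if (!nrow(records)) stop("cost_year: empty record stream")
  n_days <- max(records$day_index) + 1
  days <- seq_len(n_days) - 1
  n_weekend <- sum(days %% 7 >= 5)            # day 0 is a Monday
  up <- rates$unsocial

  perm_rate <- lapply(hospital$wards, function(w)
    c(rn = weighted_rate("rn", w$band_mix$rn, "permanent", rates),
      hca = weighted_rate("hca", w$band_mix$hca, "permanent", rates)))
  permanent <- supplement <- 0
  for (k in seq_len(nrow(plan))) {
    h <- plan$hours[k]
    if (h == 0) next
    r <- perm_rate[[plan$ward_id[k]]][[plan$group[k]]]
    permanent <- permanent + h * n_days * r
    # qualifying days for this period: night period every day, other
    # periods at weekends only (the night period is not double-counted)
    q_days <- if (up$night_period == plan$period[k]) n_days
              else if (isTRUE(up$weekend_all)) n_weekend else 0
    supplement <- supplement + h * q_days * up$uplift * r
  }

  bank_rate <- c(rn = weighted_rate("rn", temp_band_mix$rn, "bank", rates),
                 hca = weighted_rate("hca", temp_band_mix$hca, "bank", rates))
  agency_rate <- c(rn = weighted_rate("rn", temp_band_mix$rn, "agency",
                                      rates),
                   hca = weighted_rate("hca", temp_band_mix$hca, "agency",
                                       rates))
  is_unsocial <- records$period_index == up$night_period |
    (isTRUE(up$weekend_all) & records$day_index %% 7 >= 5)
  bank <- supp_bank <- agency <- 0
  for (g in c("rn", "hca")) {
    bh <- records[[paste0("bank_", g)]]
    ah <- records[[paste0("agency_", g)]]
    bank <- bank + sum(bh) * bank_rate[[g]]
    supp_bank <- supp_bank + sum(bh[is_unsocial]) * up$uplift * bank_rate[[g]]
    agency <- agency + sum(ah) * agency_rate[[g]]
  }
  supplement <- supplement + supp_bank

  patient_days <- sum(records$patients) / 4
  total <- permanent + bank + agency + supplement
  structure(list(permanent_cost = permanent, bank_cost = bank,
                 agency_cost = agency, unsocial_supplement = supplement,
                 total_cost = total, patient_days = patient_days,
                 cost_per_patient_day =
                   if (patient_days > 0) total / patient_days else NA_real_),
            class = "cost_breakdown")
}
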