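#' Summarize one replication year
#'
#' Outcome rates are patient-shift weighted: every patient present at the
#' start of an understaffed ward-shift counts as one understaffed patient
#' shift. Hour shares are computed from raw worked hours (permanent hours
#' retained on the ward, redeployed-in, bank and agency), without
#' productivity weighting.
#'
#' @param records record data frame from [simulate_year()].
#' @param cost optional [cost_year()] breakdown for the same records.
#' @return one-row data frame with `patient_shifts`, `pct_understaffed`,
#'   `pct_overstaffed`, `pct_hours_permanent`, `pct_hours_redeployed`,
#'   `pct_hours_bank`, `pct_hours_agency` and, when `cost` is given,
#'   `cost_per_patient_day`, `total_cost`, `permanent_cost`.
#' @export
summarize_replication <- function(records, cost = NULL) {
  if (!nrow(records)) stop("summarize_replication: empty record stream")
  ps <- sum(records$patients)
  under <- sum(records$patients[records$state == "understaffed"])
  over <- sum(records$patients[records$state == "overstaffed"])
  hrs <- c(
    permanent = sum(records$permanent_rn + records$permanent_hca),
    redeployed = sum(records$redeployed_in_rn + records$redeployed_in_hca),
    bank = sum(records$bank_rn + records$bank_hca),
    agency = sum(records$agency_rn + records$agency_hca))
  shr <- if (sum(hrs) > 0) 100 * hrs / sum(hrs) else hrs * 0
  out <- data.frame(
    patient_shifts = ps,
    pct_understaffed = 100 * under / ps,
    pct_overstaffed = 100 * over / ps,
    pct_hours_permanent = shr[["permanent"]],
    pct_hours_redeployed = shr[["redeployed"]],
    pct_hours_bank = shr[["bank"]],
    pct_hours_agency = shr[["agency"]])
  if (!is.null(cost)) {
    out$cost_per_patient_day <- cost$cost_per_patient_day
    out$total_cost <- cost$total_cost
    out$permanent_cost <- cost$permanent_cost
  }
  out
}

#' Aggregate replication summaries
#'
#' Means across independent replication years with 95\% confidence-interval
#' halfwidths `t(n - 1, 0.975) * sd / sqrt(n)`. With a single replication
#' the mean is reported and the halfwidths are `NA` (flagged unavailable).
#'
#' @param reps data frame of per-replication rows
#'   (from [summarize_replication()]).
#' @return list of class `run_summary` with `mean` (named vector),
#'   `ci95_halfwidth` (named vector) and `n_replications`.
#' @export
aggregate_replications <- function(reps) {
  if (!nrow(reps)) stop("aggregate_replications: no replications")
  num <- vapply(reps, is.numeric, logical(1))
  m <- colMeans(reps[, num, drop = FALSE])
  n <- nrow(reps)
  hw <- if (n >= 2) {
    s <- vapply(reps[, num, drop = FALSE], stats::sd, numeric(1))
    stats::qt(0.975, n - 1) * s / sqrt(n)
  } else {
    warning("aggregate_replications: CIs unavailable with one replication")
    stats::setNames(rep(NA_real_, sum(num)), names(m))
  }
  structure(list(mean = m, ci95_halfwidth = hw, n_replications = n),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>", x$n_replications, "replications\n")
  tab <- rbind(mean = x$mean, ci95_halfwidth = x$ci95_halfwidth)
  print(round(t(tab), 3))
  invisible(x)
}

#' Run a (scenario, policy) cell over replications
#'
#' Plans the hospital once from the shared observation window
#' (`base_seed - 1`), then simulates `n_replications` independent years
#' with seeds `base_seed + 1 .. base_seed + n_replications`, costing and
#' summarizing each.
#'
#' @param hospital a [hospital_profile()].
#' @param scenario scenario name or [scenario_spec()].
#' @param policy policy mode name or [flex_policy()].
#' @param n_replications number of independent years (default 10).
#' @param base_seed experiment base seed.
#' @param params a [sim_params()].
#' @param rates a [rate_table()].
#' @return list with `reps` (per-replication data frame), `summary`
#'   (a `run_summary`), `plan`, and the resolved `scenario`/`policy`.
#' @export
run_replications <- function(hospital, scenario = "standard",
                             policy = "empirical", n_replications = 10,
                             base_seed = 1, params = sim_params(),
                             rates = rate_table()) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.character(policy)) policy <- flex_policy(policy)
  plan <- plan_hospital(hospital, scenario, params, base_seed)
  reps <- do.call(rbind, lapply(seq_len(n_replications), function(i) {
    rec <- simulate_year(hospital, plan, policy, params,
                         replication_seed = base_seed + i)
    summarize_replication(rec, cost_year(rec, plan, hospital, rates))
  }))
  list(scenario = scenario$name, policy = policy$mode, plan = plan,
       reps = reps, summary = aggregate_replications(reps))
}

#' Run the full scenario-by-policy grid
#'
#' @param hospital a [hospital_profile()].
#' @param scenarios character vector of baseline scenarios.
#' @param policies character vector of policy modes.
#' @inheritParams run_replications
#' @return data frame with one row per (scenario, policy) cell: outcome
#'   means and CI halfwidths.
#' @export
run_scenario_grid <- function(hospital,
                              scenarios = c("low", "standard", "high"),
                              policies = c("none", "empirical", "higher",
                                           "unlimited"),
                              n_replications = 10, base_seed = 1,
                              params = sim_params(), rates = rate_table()) {
  rows <- list()
  for (sc in scenarios) for (po in policies) {
    res <- run_replications(hospital, sc, po, n_replications, base_seed,
                            params, rates)
    m <- res$summary$mean
    hw <- res$summary$ci95_halfwidth
    rows[[length(rows) + 1]] <- data.frame(
      scenario = sc, policy = po, t(m),
      ci95_understaffed = hw[["pct_understaffed"]],
      ci95_cost = if ("cost_per_patient_day" %in% names(hw))
        hw[["cost_per_patient_day"]] else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Render scenario-grid tables
#'
#' Produces the wide understaffed/overstaffed/cost layout (one row per
#' policy, one column block per baseline scenario) as CSV text and a
#' markdown table, deterministically ordered.
#'
#' @param grid data frame from [run_scenario_grid()].
#' @param metric column of `grid` to tabulate.
#' @return list with `wide` (data frame), `csv` (character scalar) and
#'   `markdown` (character scalar).
#' @export
render_tables <- function(grid, metric = "pct_understaffed") {
  stopifnot(metric %in% names(grid))
  scen <- intersect(c("low", "standard", "high"), unique(grid$scenario))
  pol <- intersect(c("unlimited", "higher", "empirical", "none"),
                   unique(grid$policy))
  wide <- data.frame(policy = pol, stringsAsFactors = FALSE)
  for (sc in scen)
    wide[[sc]] <- vapply(pol, function(p)
      grid[[metric]][grid$scenario == sc & grid$policy == p][1], numeric(1))
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  close(con)
  md <- c(paste0("| ", paste(names(wide), collapse = " | "), " |"),
          paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|"),
          vapply(seq_len(nrow(wide)), function(i)
            paste0("| ", paste(c(wide$policy[i],
                                 sprintf("%.2f", as.numeric(wide[i, -1]))),
                               collapse = " | "), " |"), character(1)))
  list(wide = wide, csv = paste(csv_out, collapse = "\n"),
       markdown = paste(md, collapse = "\n"))
}

#' Ward-level correlation between understaffing and overstaffing
#'
#' Pearson correlation between per-ward percentages of understaffed and
#' overstaffed patient shifts.
#'
#' @param pct_understaffed,pct_overstaffed numeric vectors (one entry per
#'   ward, length >= 3).
#' @return list with `r`, `p_value`, `n`; `r` is `NA` (flagged by a
#'   warning) when either input is constant.
#' @export
correlation_under_over <- function(pct_understaffed, pct_overstaffed) {
  n <- length(pct_understaffed)
  if (n < 3 || length(pct_overstaffed) != n)
    stop("correlation_under_over: need >= 3 paired ward values")
  if (stats::sd(pct_understaffed) == 0 || stats::sd(pct_overstaffed) == 0) {
    warning("correlation_under_over: constant input, correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- stats::cor.test(pct_understaffed, pct_overstaffed,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Per-ward outcome percentages from a record stream
#'
#' @param records record data frame (possibly several replications bound
#'   together).
#' @return data frame with `ward_id`, `pct_understaffed`,
#'   `pct_overstaffed`, `patient_shifts`.
#' @export
ward_level_rates <- function(records) {
  sp <- split(records, records$ward_id)
  out <- do.call(rbind, lapply(sp, function(r) {
    ps <- sum(r$patients)
    data.frame(
      ward_id = r$ward_id[1],
      pct_understaffed = 100 * sum(r$patients[r$state == "understaffed"]) /
        ps,
      pct_overstaffed = 100 * sum(r$patients[r$state == "overstaffed"]) / ps,
      patient_shifts = ps, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a record stream as CSV
#'
#' RFC 4180 CSV with a header row; numeric columns are written with full
#' precision so regenerated files are byte-identical for a fixed seed.
#'
#' @param records record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(format(records, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
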