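#' Apply short-notice sickness absence to planned person-blocks
#'
#' Sickness removes whole people, not continuous hours: each person-block
#' recorded at planning time is lost independently with the staff group's
#' absence probability.
#'
#' @param blocks list with elements `rn` and `hca`, each a numeric vector of
#'   planned block sizes (hours) for one ward-period.
#' @param rates named absence probabilities `c(rn = , hca = )`.
#' @param streams RNG substreams; the `absence` stream is consumed.
#' @return named numeric vector `c(rn = , hca = )` of available permanent
#'   hours (<= planned).
#' @export
apply_absence <- function(blocks, rates, streams) {
  stopifnot(all(rates >= 0 & rates <= 1))
  with_stream(streams, "absence", {
    vapply(c("rn", "hca"), function(g) {
      b <- blocks[[g]]
      if (!length(b)) return(0)
      sum(b[stats::runif(length(b)) >= rates[[g]]])
    }, numeric(1))
  })
}

# Decompose a face-value shortfall into requestable person-blocks:
# floor(s/6) whole 6 h blocks, then one final block for the remainder -
# a 3 h half-block when the remainder is <= 3 h, a whole 6 h block
# otherwise (fewest blocks first, then least excess).
#' Shortfall block decomposition
#'
#' @param shortfall_hours non-negative shortfall in hours.
#' @return numeric vector of block sizes (6 and possibly one trailing 3).
#' @export
shortfall_blocks <- function(shortfall_hours) {
  eps <- 1e-9
  if (shortfall_hours <= eps) return(numeric(0))
  k <- floor(shortfall_hours / 6 + eps)
  rem <- shortfall_hours - 6 * k
  c(rep(6, k), if (rem > 3 + eps) 6 else if (rem > eps) 3)
}

#' Face-value balance of a ward-shift
#'
#' Shortfall and surplus are assessed at face value against the classified
#' demand estimate (no productivity discounting at request time), and the
#' shortfall is expressed as requestable person-blocks via
#' [shortfall_blocks()].
#'
#' @param available_hours,estimate_hours non-negative hours (per group).
#' @return list with `shortfall_hours`, `surplus_hours`, `blocks`.
#' @export
assess_balance <- function(available_hours, estimate_hours) {
  stopifnot(available_hours >= 0, estimate_hours >= 0)
  sh <- max(0, estimate_hours - available_hours)
  list(shortfall_hours = sh,
       surplus_hours = max(0, available_hours - estimate_hours),
       blocks = shortfall_blocks(sh))
}

# Greedy within-division redeployment for one staff group.
# sur/sho: face-value surplus/shortfall hours per ward (same order).
# Moves one block at a time from the largest-surplus donor to the
# largest-shortfall recipient (ties: lowest index, i.e. lowest ward_id);
# a donor never drops below its own estimate; blocks are 6 h or 3 h
# (half-shift), 3 h being used when the recipient needs <= 3 h or the
# donor's spare is under 6 h.
greedy_redeploy <- function(sur, sho) {
  eps <- 1e-9
  give <- recv <- numeric(length(sur))
  moves <- list()
  repeat {
    d <- which(sur >= 3 - eps)
    r <- which(sho > eps)
    if (!length(d) || !length(r)) break
    d_star <- d[which.max(sur[d])]
    r_star <- r[which.max(sho[r])]
    need <- if (sho[r_star] <= 3 + eps) 3 else 6
    size <- if (sur[d_star] >= need - eps) need else 3
    sur[d_star] <- sur[d_star] - size
    sho[r_star] <- max(0, sho[r_star] - size)
    give[d_star] <- give[d_star] + size
    recv[r_star] <- recv[r_star] + size
    moves[[length(moves) + 1]] <- c(donor = d_star, recipient = r_star,
                                    block_hours = size)
  }
  list(give = give, recv = recv, moves = moves)
}

#' Redeploy staff within one division for one shift
#'
#' Whole people (6 h) or half-shifts (3 h) move from wards with a face-value
#' surplus to wards with a face-value shortfall in the same division,
#' greedily (largest surplus to largest shortfall, deterministic tie-break
#' by ward id). Registered nurses substitute only for registered nurses and
#' assistants only for assistants. A donation never leaves the donor below
#' its own estimate.
#'
#' @param balances data frame with columns `ward_id`, `group`,
#'   `surplus_hours`, `shortfall_hours` for the wards of one division.
#' @return data frame of moves with columns `donor`, `recipient`, `group`,
#'   `block_hours` (zero rows when nothing moves).
#' @export
redeploy_division <- function(balances) {
  out <- list()
  for (g in unique(balances$group)) {
    b <- balances[balances$group == g, , drop = FALSE]
    b <- b[order(b$ward_id), , drop = FALSE]
    res <- greedy_redeploy(b$surplus_hours, b$shortfall_hours)
    for (m in res$moves) {
      out[[length(out) + 1]] <- data.frame(
        donor = b$ward_id[m["donor"]], recipient = b$ward_id[m["recipient"]],
        group = g, block_hours = unname(m["block_hours"]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor = character(), recipient = character(),
                      group = character(), block_hours = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Request temporary staff for a residual shortfall
#'
#' Each residual block is first requested from the internal bank; a failed
#' bank request escalates to an external agency. Each request independently
#' succeeds with the policy's availability probability for the staff group,
#' period and channel. Unfilled blocks remain unfilled. The engine derives
#' `blocks` from the gap between face-value staffing (after redeployment)
#' and the *adequate* boundary `(1 - tau) * estimate`, so temporary staff
#' are only requested to raise staffing to adequacy and never create a
#' surplus beyond block granularity.
#'
#' @param blocks numeric vector of residual block sizes
#'   (from [shortfall_blocks()]).
#' @param group `"rn"` or `"hca"`.
#' @param period_index 0..3.
#' @param policy a [flex_policy()].
#' @param streams RNG substreams; the `availability` stream is consumed.
#' @return named numeric vector `c(bank = , agency = )` of hired raw hours.
#' @export
request_temporary <- function(blocks, group, period_index, policy, streams) {
  if (policy$mode == "none" || !length(blocks))
    return(c(bank = 0, agency = 0))
  p_bank <- policy$availability$bank[group, period_index + 1]
  p_agency <- policy$availability$agency[group, period_index + 1]
  with_stream(streams, "availability", {
    bank <- agency <- 0
    for (b in blocks) {
      if (stats::runif(1) < p_bank) bank <- bank + b
      else if (stats::runif(1) < p_agency) agency <- agency + b
    }
    c(bank = bank, agency = agency)
  })
}

#' Classify a ward-shift state
#'
#' Understaffed when achieved effective hours fall more than `tau` below the
#' actual requirement, overstaffed when more than `tau` above; inequalities
#' are strict, so a ward exactly at +/-15\% counts as adequately staffed. A
#' shift with zero requirement and zero achieved hours is adequate.
#'
#' @param achieved achieved productivity-weighted hours (>= 0, vectorised).
#' @param requirement actual requirement hours (>= 0, vectorised).
#' @param tau tolerance fraction (default 0.15).
#' @return character vector: `"understaffed"`, `"adequate"` or
#'   `"overstaffed"`.
#' @export
classify_shift <- function(achieved, requirement, tau = 0.15) {
  if (any(achieved < 0) || any(requirement < 0))
    stop("classify_shift: negative inputs")
  # tolerance-scaled epsilon keeps exact boundary cases (e.g. 115 vs
  # 1.15 * 100) inside the adequate band despite binary rounding
  eps <- 1e-9 * pmax(1, requirement)
  ifelse(achieved < (1 - tau) * requirement - eps, "understaffed",
         ifelse(achieved > (1 + tau) * requirement + eps, "overstaffed",
                "adequate"))
}

# ---- internal simulation context ------------------------------------------

# Precompute per-ward arrays and the planned block multisets so the
# per-shift core is vectorised over wards.
build_sim_context <- function(hospital, plan, params) {
  wards <- hospital$wards[order(names(hospital$wards))]
  n <- length(wards)
  ids <- names(wards)
  H <- list(rn = matrix(0, n, 4), hca = matrix(0, n, 4))
  stopifnot(all(plan$ward_id %in% ids))
  wi <- match(plan$ward_id, ids)
  for (k in seq_len(nrow(plan)))
    H[[plan$group[k]]][wi[k], plan$period[k] + 1] <- plan$hours[k]
  # flattened block lists per (group, period): sizes + owning ward index
  bf <- lapply(c(rn = "rn", hca = "hca"), function(g) {
    lapply(1:4, function(p) {
      sizes <- ward <- list()
      for (w in seq_len(n)) {
        b <- plan_blocks(H[[g]][w, p])
        if (length(b)) {
          sizes[[length(sizes) + 1]] <- b
          ward[[length(ward) + 1]] <- rep(w, length(b))
        }
      }
      list(sizes = unlist(sizes) %||% numeric(0),
           ward = unlist(ward) %||% integer(0))
    })
  })
  list(n = n, ids = ids,
       division = vapply(wards, `[[`, character(1), "division_id"),
       beds = vapply(wards, `[[`, integer(1), "beds"),
       skill = vapply(wards, `[[`, numeric(1), "skill_mix"),
       spec_rate = vapply(wards, `[[`, numeric(1), "specialing_rate"),
       diurnal = t(vapply(wards, `[[`, numeric(4), "diurnal_profile")),
       acuity_mean = t(vapply(wards, `[[`, numeric(5), "acuity_mean")),
       conc = vapply(wards, `[[`, numeric(1), "acuity_conc"),
       cdf = lapply(wards, function(w)
         t(apply(w$census_dist, 1, cumsum))),
       H = H, bf = bf,
       mult = as.numeric(params$multipliers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One (day, period) step across all wards of the hospital. Returns a list of
# per-ward vectors. Substreams are consumed in a fixed order (census,
# acuity, specialing, absence, availability, noise), each stream touched
# once per shift with wards in ascending ward_id order and group rn before
# hca, so a replication is bit-reproducible.
core_shift <- function(ctx, policy, params, streams, day, period) {
  n <- ctx$n
  dow <- day %% 7
  totals <- with_stream(streams, "census", {
    u <- stats::runif(n)
    vapply(seq_len(n), function(w)
      findInterval(u[w], ctx$cdf[[w]][dow + 1, ], left.open = TRUE),
      numeric(1))
  })
  fin <- is.finite(ctx$conc)
  props <- ctx$acuity_mean
  if (any(fin)) {
    shapes <- ctx$acuity_mean[fin, , drop = FALSE] * ctx$conc[fin]
    g <- with_stream(streams, "acuity",
                     matrix(stats::rgamma(sum(fin) * 5, shape = shapes),
                            ncol = 5))
    s <- rowSums(g)
    bad <- s <= 0
    if (any(bad)) { g[bad, ] <- ctx$acuity_mean[fin, , drop = FALSE][bad, ]
                    s[bad] <- 1 }
    props[fin, ] <- g / s
  }
  counts <- lr_integerize_matrix(totals, props)
  spec <- with_stream(streams, "specialing",
                      pmin(stats::rpois(n, ctx$spec_rate), totals))
  w_p <- ctx$diurnal[, period + 1]
  general_est <- drop(counts %*% ctx$mult) * w_p
  spec_h <- SHIFT_HOURS * spec
  sg <- params$specialing_group
  est <- list(rn = ctx$skill * general_est + if (sg == "rn") spec_h else 0,
              hca = (1 - ctx$skill) * general_est +
                if (sg == "hca") spec_h else 0)
  # absence on planned person-blocks (rn stream draws before hca)
  avail <- with_stream(streams, "absence", {
    lapply(c(rn = "rn", hca = "hca"), function(g) {
      fb <- ctx$bf[[g]][[period + 1]]
      a <- ctx$H[[g]][, period + 1]
      if (length(fb$sizes)) {
        lost <- fb$sizes * (stats::runif(length(fb$sizes)) <
                              params$absence[[g]])
        a - drop(rowsum(lost, fb$ward, reorder = FALSE)[
          match(seq_len(n), unique(fb$ward)), 1])
      } else a
    })
  })
  for (g in c("rn", "hca")) avail[[g]][is.na(avail[[g]])] <- 0
  sh <- list(rn = pmax(0, est$rn - avail$rn),
             hca = pmax(0, est$hca - avail$hca))
  su <- list(rn = pmax(0, avail$rn - est$rn),
             hca = pmax(0, avail$hca - est$hca))
  give <- recv <- list(rn = numeric(n), hca = numeric(n))
  if (policy$redeployment_enabled) {
    for (div in unique(ctx$division)) {
      idx <- which(ctx$division == div)
      if (length(idx) < 2) next
      for (g in c("rn", "hca")) {
        res <- greedy_redeploy(su[[g]][idx], sh[[g]][idx])
        give[[g]][idx] <- res$give
        recv[[g]][idx] <- res$recv
      }
    }
  }
  bank <- agency <- list(rn = numeric(n), hca = numeric(n))
  if (policy$mode != "none") {
    for (g in c("rn", "hca")) {
      p_b <- policy$availability$bank[g, period + 1]
      p_a <- policy$availability$agency[g, period + 1]
      # temporary staff are requested only to raise face-value staffing to
      # the 'adequate' boundary (1 - tau of the estimate), so hires do not
      # create overstaffing beyond block granularity
      resid <- pmax(0, (1 - params$tau) * est[[g]] -
                      (avail[[g]] + recv[[g]]))
      hires <- with_stream(streams, "availability", {
        t(vapply(seq_len(n), function(w) {
          b <- shortfall_blocks(resid[w])
          bk <- ag <- 0
          for (bl in b) {
            if (stats::runif(1) < p_b) bk <- bk + bl
            else if (stats::runif(1) < p_a) ag <- ag + bl
          }
          c(bk, ag)
        }, numeric(2)))
      })
      bank[[g]] <- hires[, 1]
      agency[[g]] <- hires[, 2]
    }
  }
  # actual (noisy) requirement, realized after staffing decisions
  Fn <- if (params$noise_cv == 0) matrix(1, n, 5) else
    with_stream(streams, "noise", {
      s <- lognormal_sdlog(params$noise_cv)
      matrix(stats::rlnorm(n * 5, meanlog = -s^2 / 2, sdlog = s), ncol = 5)
    })
  general_act <- rowSums(counts * rep(ctx$mult, each = n) * Fn) * w_p
  act <- list(rn = ctx$skill * general_act + if (sg == "rn") spec_h else 0,
              hca = (1 - ctx$skill) * general_act +
                if (sg == "hca") spec_h else 0)
  e <- policy$productivity
  perm <- list(rn = avail$rn - give$rn, hca = avail$hca - give$hca)
  ach_g <- lapply(c(rn = "rn", hca = "hca"), function(g)
    perm[[g]] + e["redeploy"] * recv[[g]] + e["bank"] * bank[[g]] +
      e["agency"] * agency[[g]])
  ach_total <- ach_g$rn + ach_g$hca
  act_total <- act$rn + act$hca
  list(day_index = rep(day, n), period_index = rep(period, n),
       patients = totals, specialing = spec,
       estimate_rn = est$rn, estimate_hca = est$hca,
       estimate_total = est$rn + est$hca,
       actual_rn = act$rn, actual_hca = act$hca, actual_total = act_total,
       permanent_rn = perm$rn, permanent_hca = perm$hca,
       redeployed_in_rn = recv$rn, redeployed_in_hca = recv$hca,
       redeployed_out_rn = give$rn, redeployed_out_hca = give$hca,
       bank_rn = bank$rn, bank_hca = bank$hca,
       agency_rn = agency$rn, agency_hca = agency$hca,
       achieved_effective_total = ach_total,
       state = classify_shift(ach_total, act_total, params$tau))
}

#' Simulate a single shift across a hospital
#'
#' Executes, for one (day, period), the full per-shift pipeline: census
#' sampling, demand estimation, absence, face-value balance, within-division
#' redeployment, bank/agency requests, realization of the actual (noisy)
#' requirement and ward-state classification.
#'
#' @param hospital a [hospital_profile()].
#' @param plan an [plan_hospital()] establishment plan.
#' @param policy a [flex_policy()].
#' @param params a [sim_params()].
#' @param streams RNG substreams.
#' @param day_index,period_index shift to simulate (day 0 is a Monday).
#' @return data frame with one `ShiftStaffingRecord` row per ward.
#' @export
simulate_shift <- function(hospital, plan, policy, params, streams,
                           day_index = 0, period_index = 0) {
  ctx <- build_sim_context(hospital, plan, params)
  res <- core_shift(ctx, policy, params, streams, day_index, period_index)
  cbind(data.frame(ward_id = ctx$ids, stringsAsFactors = FALSE),
        as.data.frame(res, stringsAsFactors = FALSE))
}

#' Simulate one replication year
#'
#' Runs `params$days` days times four 6-hour periods over every ward.
#' Day 0 is a Monday and the day-of-week census distributions cycle with
#' period 7. All randomness derives from `replication_seed` through named
#' substreams, so a replication is exactly reproducible and two replications
#' with different seeds are independent.
#'
#' @param hospital a [hospital_profile()].
#' @param plan establishment plan from [plan_hospital()].
#' @param policy a [flex_policy()].
#' @param params a [sim_params()].
#' @param replication_seed integer seed for this replication.
#' @return data frame of per-ward-shift records
#'   (`days * 4 * n_wards` rows).
#' @export
simulate_year <- function(hospital, plan, policy, params = sim_params(),
                          replication_seed = 1) {
  streams <- make_rng_streams(replication_seed)
  ctx <- build_sim_context(hospital, plan, params)
  n <- ctx$n
  steps <- params$days * 4L
  out <- NULL
  row0 <- 0L
  for (day in seq_len(params$days) - 1L) {
    for (period in 0:3) {
      res <- core_shift(ctx, policy, params, streams, day, period)
      if (is.null(out)) {
        out <- lapply(res, function(v) {
          x <- vector(typeof(v), n * steps)
          x
        })
      }
      idx <- row0 + seq_len(n)
      for (nm in names(res)) out[[nm]][idx] <- res[[nm]]
      row0 <- row0 + n
    }
  }
  cbind(data.frame(ward_id = rep(ctx$ids, steps), stringsAsFactors = FALSE),
        as.data.frame(out, stringsAsFactors = FALSE))
}
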