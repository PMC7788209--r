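# Shared fixture builders (all fixtures are constructed in code).

# Degenerate probability vector over 0..beds with all mass at `at`.
point_pmf <- function(beds, at) {
  p <- numeric(beds + 1)
  p[at + 1] <- 1
  p
}

# A zero-variance ward: constant census, fixed acuity mix (all level 0),
# no specialing. With multipliers whose level-0 entry is `m0`, daily demand
# is exactly beds * m0 hours.
constant_ward <- function(ward_id = "W001", division_id = "D01", beds = 20,
                          skill_mix = 0.5,
                          diurnal = c(0.25, 0.25, 0.25, 0.25)) {
  ward_profile(ward_id, division_id, beds,
               census_dist = matrix(rep(point_pmf(beds, beds), 7),
                                    nrow = 7, byrow = TRUE),
               acuity_mean = c(1, 0, 0, 0, 0), acuity_conc = Inf,
               specialing_rate = 0, skill_mix = skill_mix,
               diurnal_profile = diurnal)
}

# Multipliers giving an exactly block-achievable establishment for
# constant_ward(beds = 20): daily 20 * 4.8 = 96 h -> 24 h/period -> 12 h
# per group at skill mix 0.5.
exact_fit_multipliers <- function() care_multipliers(c(4.8, 5.8, 7.2, 8.4, 24))

# Parameters for deterministic limit checks.
no_noise_params <- function(...) {
  sim_params(noise_cv = 0, absence = c(rn = 0, hca = 0), ...)
}

# Build an establishment-plan data frame by hand (bypassing planning).
manual_plan <- function(ward_ids, hours_rn, hours_hca) {
  do.call(rbind, lapply(seq_along(ward_ids), function(i) {
    data.frame(ward_id = ward_ids[i], period = rep(0:3, each = 2),
               group = rep(c("rn", "hca"), 4),
               hours = rep(c(hours_rn[i], hours_hca[i]), 4),
               stringsAsFactors = FALSE)
  }))
}

# Load the checked-in reference fixtures from inst/extdata.
fixture_hospital <- function(n = 4) {
  path <- system.file("extdata", sprintf("hospital_%dward.json", n),
                      package = "wardsim")
  if (!nzchar(path))
    path <- file.path("..", "..", "inst", "extdata",
                      sprintf("hospital_%dward.json", n))
  read_hospital_json(path)
}

# Brute-force minimum residual shortfall over all feasible redeployment
# move sequences (independent oracle for the greedy allocator). Moves are
# 3 h or 6 h, never exceed the donor's surplus; a recipient's shortfall is
# floored at zero.
oracle_min_residual <- function(sur, sho, memo = new.env(parent = emptyenv())) {
  key <- paste(c(round(sur, 4), ":", round(sho, 4)), collapse = ",")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  best <- sum(sho)
  for (d in which(sur >= 3 - 1e-9)) {
    for (r in which(sho > 1e-9)) {
      for (size in c(3, 6)) {
        if (sur[d] < size - 1e-9) next
        s2 <- sur; h2 <- sho
        s2[d] <- s2[d] - size
        h2[r] <- max(0, h2[r] - size)
        best <- min(best, oracle_min_residual(s2, h2, memo))
      }
    }
  }
  memo[[key]] <- best
  best
}

# Residual shortfall left by the package's greedy division allocator.
greedy_residual <- function(sur, sho) {
  ids <- sprintf("W%02d", seq_along(sur))
  bal <- data.frame(ward_id = rep(ids, 2),
                    group = rep(c("rn", "hca"), each = length(sur)),
                    surplus_hours = c(sur, numeric(length(sur))),
                    shortfall_hours = c(sho, numeric(length(sur))),
                    stringsAsFactors = FALSE)
  moves <- redeploy_division(bal)
  recv <- numeric(length(sur))
  if (nrow(moves)) {
    m <- moves[moves$group == "rn", , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      r <- match(m$recipient[k], ids)
      recv[r] <- recv[r] + m$block_hours[k]
    }
  }
  sum(pmax(0, sho - recv))
}

# A minimal one-band rate table used by the hand-built oracle fixture.
oracle_rates <- function() {
  rate_table(bands = data.frame(group = c("rn", "hca"),
                                band = c("band5", "band2"),
                                base_rate = c(15, 10),
                                agency_cap = c(30, 20),
                                stringsAsFactors = FALSE),
             oncost = 0.2,
             unsocial = list(uplift = 0.30, night_period = 3,
                             weekend_all = TRUE))
}
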