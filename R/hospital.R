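#' Ward profile
#'
#' Static description of one inpatient ward: bed complement, redeployment
#' division, day-of-week census distributions, acuity/dependency mix,
#' specialing rate, skill mix, diurnal staffing profile and pay-band mix.
#'
#' The census distribution is a discrete distribution over patient counts
#' `0..beds`, one per day of week (day 0 is a Monday). The acuity mix is a
#' Dirichlet over the five acuity/dependency levels (0, 1a, 1b, 2, 3),
#' parameterised by a mean proportion vector and a concentration; an infinite
#' concentration gives a fixed (degenerate) mix, which the zero-variance test
#' fixtures rely on.
#'
#' @param ward_id character identifier.
#' @param division_id character identifier of the redeployment pool.
#' @param beds positive integer bed complement.
#' @param census_dist numeric matrix `7 x (beds + 1)`; row `d` is the
#'   probability mass over patient counts `0..beds` on day-of-week `d`
#'   (row 1 = Monday). Rows must each sum to 1.
#' @param acuity_mean length-5 mean proportion vector over acuity levels,
#'   summing to 1.
#' @param acuity_conc Dirichlet concentration (> 0, may be `Inf` for a fixed
#'   mix).
#' @param specialing_rate expected number of specialed (one-to-one care)
#'   patients per shift, >= 0.
#' @param skill_mix fraction of general care hours delivered by registered
#'   nurses, in `[0, 1]`.
#' @param diurnal_profile 4 non-negative weights over the four 6-hour periods
#'   (morning, afternoon, evening, night), summing to 1.
#' @param band_mix list with elements `rn` and `hca`, each a named numeric
#'   vector of pay-band proportions summing to 1.
#' @return An object of class `ward_profile`.
#' @export
ward_profile <- function(ward_id, division_id, beds, census_dist,
                         acuity_mean, acuity_conc = 50,
                         specialing_rate = 0, skill_mix = 0.5,
                         diurnal_profile = c(0.3, 0.27, 0.23, 0.2),
                         band_mix = default_band_mix()) {
  beds <- as.integer(beds)
  if (length(beds) != 1 || is.na(beds) || beds < 1)
    stop("ward_profile: 'beds' must be a positive integer (ward ",
         ward_id, ")")
  census_dist <- as.matrix(census_dist)
  if (!identical(dim(census_dist), c(7L, beds + 1L)))
    stop("ward_profile: 'census_dist' must be 7 x (beds + 1) for ward ",
         ward_id)
  if (any(census_dist < 0) ||
      any(abs(rowSums(census_dist) - 1) > 1e-9))
    stop("ward_profile: census_dist rows must be probability vectors")
  acuity_mean <- as.numeric(acuity_mean)
  if (length(acuity_mean) != 5 || any(acuity_mean < 0) ||
      abs(sum(acuity_mean) - 1) > 1e-9)
    stop("ward_profile: 'acuity_mean' must be 5 proportions summing to 1")
  if (!(acuity_conc > 0)) stop("ward_profile: 'acuity_conc' must be > 0")
  if (specialing_rate < 0) stop("ward_profile: 'specialing_rate' must be >= 0")
  if (skill_mix < 0 || skill_mix > 1)
    stop("ward_profile: 'skill_mix' must lie in [0, 1]")
  diurnal_profile <- as.numeric(diurnal_profile)
  if (length(diurnal_profile) != 4 || any(diurnal_profile < 0) ||
      abs(sum(diurnal_profile) - 1) > 1e-9)
    stop("ward_profile: 'diurnal_profile' must be 4 weights summing to 1")
  for (g in c("rn", "hca")) {
    bm <- band_mix[[g]]
    if (is.null(names(bm)) || any(bm < 0) || abs(sum(bm) - 1) > 1e-9)
      stop("ward_profile: band_mix$", g,
           " must be a named proportion vector summing to 1")
  }
  structure(list(ward_id = as.character(ward_id),
                 division_id = as.character(division_id),
                 beds = beds,
                 census_dist = census_dist,
                 acuity_mean = acuity_mean,
                 acuity_conc = acuity_conc,
                 specialing_rate = specialing_rate,
                 skill_mix = skill_mix,
                 diurnal_profile = diurnal_profile,
                 band_mix = band_mix),
            class = "ward_profile")
}

#' Default pay-band mix for permanent staff
#'
#' @return list with named proportion vectors for registered nurses (`rn`)
#'   and assistants (`hca`).
#' @export
default_band_mix <- function() {
  list(rn = c(band5 = 0.7, band6 = 0.2, band7 = 0.1),
       hca = c(band2 = 0.6, band3 = 0.4))
}

#' Hospital profile
#'
#' A set of wards partitioned into divisions (the within-hospital
#' redeployment pools).
#'
#' @param hospital_id character identifier.
#' @param wards list of [ward_profile()] objects.
#' @return An object of class `hospital_profile` with a `divisions` element
#'   mapping division ids to ward ids.
#' @export
hospital_profile <- function(hospital_id, wards) {
  if (length(wards) < 1) stop("hospital_profile: at least one ward required")
  ids <- vapply(wards, function(w) w$ward_id, character(1))
  if (anyDuplicated(ids)) stop("hospital_profile: duplicate ward ids")
  names(wards) <- ids
  div <- vapply(wards, function(w) w$division_id, character(1))
  divisions <- split(ids, div)
  structure(list(hospital_id = as.character(hospital_id),
                 wards = wards,
                 divisions = divisions),
            class = "hospital_profile")
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat("<hospital_profile>", x$hospital_id, "-", length(x$wards), "wards in",
      length(x$divisions), "divisions,",
      sum(vapply(x$wards, `[[`, integer(1), "beds")), "beds\n")
  invisible(x)
}

#' Discretized truncated-normal census distribution
#'
#' Builds the probability mass over patient counts `0..beds` used as a
#' two-parameter stand-in for an empirical census histogram: a normal with
#' mean `mean_frac * beds` and coefficient of variation `cv`, discretized to
#' integer counts and truncated to `[0, beds]` by renormalisation.
#'
#' @param beds bed complement.
#' @param mean_frac mean occupancy as a fraction of beds, in `(0, 1]`.
#' @param cv coefficient of variation of the underlying normal (0 gives a
#'   point mass at `round(mean_frac * beds)`).
#' @return numeric probability vector of length `beds + 1`.
#' @export
census_pmf <- function(beds, mean_frac, cv) {
  if (beds < 1) stop("census_pmf: 'beds' must be positive")
  mu <- mean_frac * beds
  if (cv <= 0) {
    p <- numeric(beds + 1)
    p[min(beds, max(0, round(mu))) + 1] <- 1
    return(p)
  }
  sd <- cv * mu
  ks <- 0:beds
  p <- stats::pnorm(ks + 0.5, mu, sd) - stats::pnorm(ks - 0.5, mu, sd)
  if (sum(p) <= 0) stop("census_pmf: degenerate parameters")
  p / sum(p)
}

#' Generate a synthetic hospital
#'
#' Creates a hospital whose wards have the statistical structure the
#' simulation needs: per-ward, day-of-week-specific census distributions
#' (weekday vs weekend occupancy contrast), Dirichlet acuity-mix dispersion,
#' Poisson specialing, heterogeneous skill mixes and a common diurnal
#' staffing profile. Deterministic for a fixed `seed`.
#'
#' @param n_wards number of wards (>= 1).
#' @param wards_per_division wards per redeployment division; wards are
#'   assigned to contiguous blocks, the last division possibly smaller.
#' @param seed integer seed.
#' @param bed_range integer range `c(min, max)` from which bed complements
#'   are drawn uniformly.
#' @param occupancy_weekday,occupancy_weekend mean occupancy fractions for
#'   Monday-Friday and Saturday-Sunday.
#' @param census_cv coefficient of variation of the daily census.
#' @param acuity_mean hospital-level mean acuity mix (levels 0, 1a, 1b, 2, 3).
#' @param acuity_conc Dirichlet concentration of the per-shift acuity mix.
#' @param specialing_rate expected specialed patients per ward-shift.
#' @param skill_mix_range range of per-ward registered-nurse skill mixes.
#' @param diurnal_profile shared 4-period staffing weight profile.
#' @param hospital_id identifier for the generated hospital.
#' @return A [hospital_profile()].
#' @export
generate_hospital <- function(n_wards, wards_per_division = 4, seed,
                              bed_range = c(10L, 36L),
                              occupancy_weekday = 0.90,
                              occupancy_weekend = 0.85,
                              census_cv = 0.08,
                              acuity_mean = c(0.40, 0.30, 0.20, 0.08, 0.02),
                              acuity_conc = 50,
                              specialing_rate = 0.2,
                              skill_mix_range = c(0.45, 0.70),
                              diurnal_profile = c(0.3, 0.27, 0.23, 0.2),
                              hospital_id = "synthetic") {
  if (n_wards < 1) stop("generate_hospital: 'n_wards' must be >= 1")
  if (wards_per_division < 1)
    stop("generate_hospital: 'wards_per_division' must be >= 1")
  bed_range <- as.integer(bed_range)
  if (any(bed_range < 1) || bed_range[2] < bed_range[1])
    stop("generate_hospital: invalid 'bed_range' (beds must be positive)")
  if (missing(seed)) stop("generate_hospital: 'seed' is required")

  streams <- make_rng_streams(derive_seed(seed, 99))
  wards <- with_stream(streams, "census", {
    lapply(seq_len(n_wards), function(i) {
      beds <- if (bed_range[1] == bed_range[2]) bed_range[1] else
        sample(bed_range[1]:bed_range[2], 1)
      # small per-ward jitter so wards differ in occupancy and acuity
      occ_wd <- min(0.98, max(0.5, occupancy_weekday + stats::rnorm(1, 0, 0.03)))
      occ_we <- min(occ_wd, max(0.4, occupancy_weekend + stats::rnorm(1, 0, 0.03)))
      cd <- rbind(
        matrix(rep(census_pmf(beds, occ_wd, census_cv), 5),
               nrow = 5, byrow = TRUE),
        matrix(rep(census_pmf(beds, occ_we, census_cv), 2),
               nrow = 2, byrow = TRUE))
      am <- acuity_mean * stats::runif(5, 0.8, 1.2)
      am <- am / sum(am)
      sm <- stats::runif(1, skill_mix_range[1], skill_mix_range[2])
      ward_profile(
        ward_id = sprintf("W%03d", i),
        division_id = sprintf("D%02d", (i - 1) %/% wards_per_division + 1),
        beds = beds,
        census_dist = cd,
        acuity_mean = am,
        acuity_conc = acuity_conc,
        specialing_rate = specialing_rate,
        skill_mix = sm,
        diurnal_profile = diurnal_profile)
    })
  })
  hospital_profile(hospital_id, wards)
}

#' Write a hospital profile to JSON
#'
#' Serialises the full profile (including census probability matrices) as
#' plain-text JSON, the package's configuration interchange format.
#'
#' @param hospital a [hospital_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hospital_json <- function(hospital, path) {
  wards <- lapply(hospital$wards, function(w) {
    list(ward_id = w$ward_id, division_id = w$division_id, beds = w$beds,
         census_dist = apply(w$census_dist, 1, function(r) r,
                             simplify = FALSE),
         acuity_mean = w$acuity_mean, acuity_conc = w$acuity_conc,
         specialing_rate = w$specialing_rate, skill_mix = w$skill_mix,
         diurnal_profile = w$diurnal_profile,
         band_mix = lapply(w$band_mix, as.list))
  })
  # 8 significant digits keeps files compact; census rows are renormalised
  # to sum exactly to 1 on read
  jsonlite::write_json(
    list(hospital_id = hospital$hospital_id, wards = unname(wards)),
    path, auto_unbox = TRUE, digits = I(8), pretty = FALSE)
  invisible(path)
}

#' Read a hospital profile from JSON
#'
#' @param path JSON file written by [write_hospital_json()].
#' @return A [hospital_profile()].
#' @export
read_hospital_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  wards <- lapply(x$wards, function(w) {
    ac <- w$acuity_conc
    if (is.character(ac)) ac <- as.numeric(ac)  # "Inf" round-trips as string
    cd <- do.call(rbind, lapply(w$census_dist, unlist))
    cd <- cd / rowSums(cd)
    am <- unlist(w$acuity_mean)
    dp <- unlist(w$diurnal_profile)
    ward_profile(
      ward_id = w$ward_id, division_id = w$division_id, beds = w$beds,
      census_dist = cd,
      acuity_mean = am / sum(am), acuity_conc = ac,
      specialing_rate = w$specialing_rate, skill_mix = w$skill_mix,
      diurnal_profile = dp / sum(dp),
      band_mix = lapply(w$band_mix, unlist))
  })
  hospital_profile(x$hospital_id, wards)
}

#' Write the 4-ward and 20-ward reference hospitals
#'
#' Emits the two fixture hospitals used throughout the test-suite and
#' documentation: `hospital_4ward.json` (one division) and
#' `hospital_20ward.json` (five divisions). Both are fully reproducible from
#' [generate_hospital()] with the seeds fixed here.
#'
#' @param dir output directory.
#' @return character vector of the two file paths, invisibly.
#' @export
write_reference_fixtures <- function(dir = ".") {
  h4 <- reference_hospital(4)
  h20 <- reference_hospital(20)
  p4 <- file.path(dir, "hospital_4ward.json")
  p20 <- file.path(dir, "hospital_20ward.json")
  write_hospital_json(h4, p4)
  write_hospital_json(h20, p20)
  invisible(c(p4, p20))
}

#' Construct a reference fixture hospital in memory
#'
#' @param n_wards 4 or 20 (other values allowed; seeds are fixed per size).
#' @return A [hospital_profile()].
#' @export
reference_hospital <- function(n_wards = 4) {
  generate_hospital(n_wards = n_wards, wards_per_division = 4,
                    seed = 20200326 + n_wards,
                    hospital_id = sprintf("fixture-%dw", n_wards))
}
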