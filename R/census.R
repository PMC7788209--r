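#' Largest-remainder integerization
#'
#' Converts a sampled proportion vector into whole patients: each level gets
#' `floor(total * p)`, and the remaining units go to the levels with the
#' largest fractional remainders, ties broken in favour of the lowest index.
#' Outputs always sum to `total` and each lies within 1 of `total * p`.
#'
#' @param total non-negative integer number of patients.
#' @param proportions numeric vector summing to 1.
#' @return integer vector of the same length as `proportions`.
#' @export
largest_remainder_integerize <- function(total, proportions) {
  if (length(total) != 1 || is.na(total) || total < 0)
    stop("largest_remainder_integerize: 'total' must be a non-negative integer")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("largest_remainder_integerize: 'proportions' must sum to 1")
  drop(lr_integerize_matrix(as.integer(total),
                            matrix(proportions, nrow = 1)))
}

# Vectorised largest-remainder over rows: totals (n), props (n x k).
# At most k-1 extra units per row, allocated one pass at a time via max.col
# (ties.method = "first" implements the lowest-index tie-break).
lr_integerize_matrix <- function(totals, props) {
  raw <- totals * props
  base <- floor(raw + 1e-9)
  rem <- raw - base
  k <- as.integer(round(totals - rowSums(base)))
  if (any(k < 0)) stop("lr_integerize_matrix: internal rounding error")
  maxk <- max(k, 0L)
  if (maxk > 0) {
    score <- rem
    for (pass in seq_len(maxk)) {
      act <- which(k >= pass)
      if (!length(act)) break
      j <- max.col(score[act, , drop = FALSE], ties.method = "first")
      idx <- cbind(act, j)
      base[idx] <- base[idx] + 1
      score[idx] <- -Inf
    }
  }
  storage.mode(base) <- "integer"
  base
}

#' Sample a Dirichlet proportion vector
#'
#' @param mean mean proportion vector.
#' @param conc concentration parameter; `Inf` returns `mean` unchanged.
#' @param n number of draws.
#' @return `n x length(mean)` matrix of proportions.
#' @export
sample_acuity_mix <- function(mean, conc, n = 1) {
  if (!is.finite(conc)) {
    return(matrix(rep(mean, each = n), nrow = n))
  }
  g <- matrix(stats::rgamma(n * length(mean),
                            shape = rep(mean * conc, each = n)),
              nrow = n)
  s <- rowSums(g)
  # all-zero rows can only arise from zero shapes; fall back to the mean
  bad <- s <= 0
  if (any(bad)) {
    g[bad, ] <- rep(mean, each = sum(bad))
    s[bad] <- 1
  }
  g / s
}

#' Sample one shift census for a ward
#'
#' Draws the total patients present at the shift start from the ward's
#' day-of-week census distribution, a five-level acuity/dependency mix from
#' the ward's Dirichlet (resampled once per 6-hour shift), integerizes by
#' largest remainder, and draws a Poisson specialing count truncated at the
#' total number of patients.
#'
#' @param ward a [ward_profile()].
#' @param day_index 0-based day within the simulated year (day 0 = Monday).
#' @param period_index 0..3 (morning, afternoon, evening, night).
#' @param streams a [make_rng_streams()] object.
#' @return list of class `shift_census` with `ward_id`, `day_index`,
#'   `period_index`, `counts_by_level` (length 5) and `specialing_count`.
#' @export
sample_shift_census <- function(ward, day_index, period_index, streams) {
  stopifnot(day_index >= 0, period_index %in% 0:3)
  dow <- day_index %% 7
  total <- with_stream(streams, "census", {
    u <- stats::runif(1)
    findInterval(u, cumsum(ward$census_dist[dow + 1, ]), left.open = TRUE)
  })
  props <- with_stream(streams, "acuity",
                       sample_acuity_mix(ward$acuity_mean, ward$acuity_conc))
  counts <- largest_remainder_integerize(total, drop(props))
  spec <- with_stream(streams, "specialing", {
    if (ward$specialing_rate <= 0) 0L else
      min(stats::rpois(1, ward$specialing_rate), total)
  })
  structure(list(ward_id = ward$ward_id, day_index = day_index,
                 period_index = period_index,
                 counts_by_level = counts,
                 specialing_count = as.integer(spec)),
            class = "shift_census")
}
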