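test_that("generate_hospital partitions wards into divisions as documented", {
  h1 <- generate_hospital(4, wards_per_division = 4, seed = 1)
  expect_length(h1$divisions, 1)
  expect_length(h1$divisions[[1]], 4)

  # contiguous blocks, last division possibly smaller: 81 wards / 5 -> 17
  h2 <- generate_hospital(81, wards_per_division = 5, seed = 7)
  expect_length(h2$divisions, 17)
  sizes <- lengths(h2$divisions)
  expect_equal(sort(unname(sizes), decreasing = TRUE),
               c(rep(5, 16), 1))
})

test_that("generate_hospital is deterministic and validates its config", {
  a <- generate_hospital(6, 3, seed = 42)
  b <- generate_hospital(6, 3, seed = 42)
  expect_identical(a, b)
  c <- generate_hospital(6, 3, seed = 43)
  expect_false(identical(a, c))
  expect_error(generate_hospital(6, 3, seed = 1, bed_range = c(0, 10)),
               "bed_range")
  expect_error(generate_hospital(0, 3, seed = 1), "n_wards")
})

test_that("generated wards satisfy the profile invariants", {
  h <- generate_hospital(10, 4, seed = 3)
  for (w in h$wards) {
    expect_true(w$beds >= 1)
    expect_equal(rowSums(w$census_dist), rep(1, 7), tolerance = 1e-9)
    expect_true(all(w$census_dist >= 0))
    expect_equal(sum(w$acuity_mean), 1, tolerance = 1e-9)
    expect_equal(sum(w$diurnal_profile), 1, tolerance = 1e-9)
    expect_gte(w$skill_mix, 0)
    expect_lte(w$skill_mix, 1)
  }
  # weekday/weekend occupancy contrast present in expectation
  w <- h$wards[[1]]
  mean_wd <- sum(w$census_dist[1, ] * (0:w$beds))
  mean_we <- sum(w$census_dist[7, ] * (0:w$beds))
  expect_false(isTRUE(all.equal(mean_wd, mean_we)))
})

test_that("largest_remainder_integerize matches its contract", {
  expect_equal(largest_remainder_integerize(10, rep(0.2, 5)),
               rep(2L, 5))
  expect_equal(largest_remainder_integerize(0, c(0.3, 0.2, 0.5, 0, 0)),
               rep(0L, 5))
  # tie between first two indices: first index wins the extra unit
  expect_equal(largest_remainder_integerize(7, c(0.5, 0.5, 0, 0, 0)),
               c(4L, 3L, 0L, 0L, 0L))
  expect_error(largest_remainder_integerize(-1, rep(0.2, 5)))
  # property: sums conserved, each entry within 1 of total * p
  set.seed(11)
  for (i in 1:200) {
    p <- as.vector(sample_acuity_mix(rep(0.2, 5), 5))
    tot <- sample(0:40, 1)
    out <- largest_remainder_integerize(tot, p)
    expect_identical(sum(out), as.integer(tot))
    expect_true(all(abs(out - tot * p) < 1 + 1e-9))
    expect_true(all(out >= 0))
  }
})

test_that("sample_shift_census honours degenerate distributions", {
  w <- constant_ward(beds = 10)
  w$census_dist <- matrix(rep(point_pmf(10, 10), 7), 7, byrow = TRUE)
  s <- make_rng_streams(1)
  cen <- sample_shift_census(w, 0, 0, s)
  expect_equal(cen$counts_by_level, c(10L, 0L, 0L, 0L, 0L))
  expect_identical(cen$specialing_count, 0L)
  # specialing_rate = 0 -> always zero, and never exceeds total patients
  for (d in 0:6) {
    cen <- sample_shift_census(w, d, 3, s)
    expect_identical(cen$specialing_count, 0L)
    expect_lte(sum(cen$counts_by_level), w$beds)
  }
})

test_that("sampled census totals match the configured distribution", {
  beds <- 12
  pmf <- numeric(beds + 1)
  pmf[c(9, 13)] <- 0.5            # totals 8 and 12, equally likely
  w <- ward_profile("W1", "D1", beds,
                    census_dist = matrix(rep(pmf, 7), 7, byrow = TRUE),
                    acuity_mean = c(1, 0, 0, 0, 0), acuity_conc = Inf)
  s <- make_rng_streams(202)
  n <- 10000
  tot <- vapply(seq_len(n) - 1L, function(i)
    sum(sample_shift_census(w, i %% 7, 0, s)$counts_by_level), numeric(1))
  expect_true(all(tot %in% c(8, 12)))
  se <- 2 / sqrt(n)               # sd of {8,12} w.p. 1/2 each is 2
  expect_lt(abs(mean(tot) - 10), 3 * se)
  # distributional fidelity of the variance as well (4 sd corridor)
  expect_lt(abs(stats::var(tot) - 4), 4 * 4 / sqrt(n) * 3)
})

test_that("census and acuity streams are reproducible and independent", {
  w <- generate_hospital(1, 1, seed = 5)$wards[[1]]
  s1 <- make_rng_streams(9)
  s2 <- make_rng_streams(9)
  a <- lapply(0:9, function(d) sample_shift_census(w, d, d %% 4, s1))
  b <- lapply(0:9, function(d) sample_shift_census(w, d, d %% 4, s2))
  expect_identical(a, b)
  s3 <- make_rng_streams(10)
  c3 <- lapply(0:9, function(d) sample_shift_census(w, d, d %% 4, s3))
  expect_false(identical(a, c3))
})

test_that("hospital JSON round-trips through read/write", {
  h <- generate_hospital(3, 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_hospital_json(h, path)
  h2 <- read_hospital_json(path)
  expect_identical(names(h2$wards), names(h$wards))
  for (id in names(h$wards)) {
    expect_equal(h2$wards[[id]]$census_dist, h$wards[[id]]$census_dist,
                 tolerance = 1e-6)
    expect_equal(h2$wards[[id]]$skill_mix, h$wards[[id]]$skill_mix,
                 tolerance = 1e-6)
    expect_identical(h2$wards[[id]]$division_id, h$wards[[id]]$division_id)
  }
})
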