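test_that("apply_absence removes whole person-blocks at the group rate", {
  blocks <- list(rn = rep(6, 5), hca = c(6, 6, 4))
  s <- make_rng_streams(1)
  expect_equal(apply_absence(blocks, c(rn = 0, hca = 0), s),
               c(rn = 30, hca = 16))
  expect_equal(apply_absence(blocks, c(rn = 1, hca = 1), s),
               c(rn = 0, hca = 0))
  # binomial calibration at the configured rate
  s <- make_rng_streams(33)
  n <- 10000
  kept <- vapply(seq_len(n), function(i)
    apply_absence(list(rn = rep(6, 10), hca = numeric(0)),
                  c(rn = 0.03, hca = 0), s)[["rn"]], numeric(1))
  frac_absent <- 1 - mean(kept) / 60
  se <- sqrt(0.03 * 0.97 / (n * 10))
  expect_lt(abs(frac_absent - 0.03), 3 * se)
})

test_that("assess_balance reports shortfall, surplus and blocks", {
  b <- assess_balance(30, 30)
  expect_equal(b$shortfall_hours, 0)
  expect_equal(b$surplus_hours, 0)
  expect_length(b$blocks, 0)
  expect_equal(assess_balance(24, 30)$blocks, 6)
  # 9 h decomposes as one whole and one half block; oracle: enumerate all
  # multisets of {3, 6} covering >= 9, fewest blocks then least excess
  combos <- expand.grid(n3 = 0:4, n6 = 0:4)
  combos$sum <- combos$n3 * 3 + combos$n6 * 6
  feas <- combos[combos$sum >= 9, ]
  feas <- feas[order(feas$n3 + feas$n6, feas$sum - 9), ]
  expect_equal(unname(unlist(feas[1, c("n6", "n3")])), c(1, 1))
  expect_equal(sort(assess_balance(24, 33)$blocks), c(3, 6))
  # remainder above a half block escalates to a whole block
  expect_equal(shortfall_blocks(10), c(6, 6))
  expect_equal(shortfall_blocks(2), 3)
  expect_length(shortfall_blocks(0), 0)
})

test_that("redeployment respects groups, conservation and donors", {
  # surplus RN ward covers shortfall RN ward exactly
  bal <- data.frame(ward_id = c("A", "B"), group = "rn",
                    surplus_hours = c(6, 0), shortfall_hours = c(0, 6))
  mv <- redeploy_division(bal)
  expect_equal(nrow(mv), 1)
  expect_equal(mv$donor, "A")
  expect_equal(mv$recipient, "B")
  expect_equal(mv$block_hours, 6)

  # no substitution across staff groups
  bal2 <- data.frame(ward_id = c("A", "A", "B", "B"),
                     group = c("rn", "hca", "rn", "hca"),
                     surplus_hours = c(6, 0, 0, 0),
                     shortfall_hours = c(0, 0, 0, 6))
  expect_equal(nrow(redeploy_division(bal2)), 0)

  # spec worked example: surpluses (6, 3) against shortfall 9
  expect_equal(greedy_residual(c(6, 3, 0), c(0, 0, 9)), 0)
})

test_that("greedy redeployment equals the brute-force optimum on block instances", {
  # all divisions of <= 3 wards with imbalances in {-9,...,9} step 3 and at
  # most 4 blocks of total imbalance (the acceptance suite runs the full
  # <= 4-ward enumeration)
  vals <- seq(-9, 9, by = 3)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  grid <- grid[rowSums(abs(grid)) / 3 <= 4, ]
  for (i in seq_len(nrow(grid))) {
    v <- as.numeric(grid[i, ])
    sur <- pmax(v, 0); sho <- pmax(-v, 0)
    expect_equal(greedy_residual(sur, sho), oracle_min_residual(sur, sho),
                 info = paste(v, collapse = ","))
  }
})

test_that("request_temporary follows the two-stage escalation", {
  s <- make_rng_streams(2)
  unlim <- flex_policy("unlimited")
  expect_equal(request_temporary(c(6, 6), "rn", 0, unlim, s),
               c(bank = 12, agency = 0))
  none_avail <- flex_policy("empirical",
                            availability = list(bank = matrix(0, 2, 4,
                              dimnames = list(c("rn", "hca"), NULL)),
                              agency = matrix(0, 2, 4,
                              dimnames = list(c("rn", "hca"), NULL))))
  expect_equal(request_temporary(c(6, 6), "rn", 0, none_avail, s),
               c(bank = 0, agency = 0))
  expect_equal(request_temporary(numeric(0), "rn", 0, unlim, s),
               c(bank = 0, agency = 0))
})

test_that("classify_shift applies the strict tolerance band", {
  expect_equal(classify_shift(84, 100, 0.15), "understaffed")
  expect_equal(classify_shift(115, 100, 0.15), "adequate")
  expect_equal(classify_shift(116, 100, 0.15), "overstaffed")
  expect_equal(classify_shift(85, 100, 0.15), "adequate")
  expect_equal(classify_shift(0, 0, 0.15), "adequate")
  expect_error(classify_shift(-1, 10), "negative")
})

test_that("simulate_shift holds its record invariants", {
  h <- fixture_hospital(4)
  plan <- plan_hospital(h, "standard", sim_params(), 1)
  s <- make_rng_streams(7)
  rec <- simulate_shift(h, plan, flex_policy("empirical"), sim_params(), s,
                        day_index = 3, period_index = 1)
  expect_equal(nrow(rec), 4)
  hour_cols <- grep("_(rn|hca)$|achieved", names(rec), value = TRUE)
  expect_true(all(as.matrix(rec[hour_cols]) >= -1e-9))
  # achieved = permanent + 0.9 (redeployed_in + bank) + 0.75 agency
  ach <- with(rec, permanent_rn + permanent_hca +
                0.9 * (redeployed_in_rn + redeployed_in_hca +
                         bank_rn + bank_hca) +
                0.75 * (agency_rn + agency_hca))
  expect_equal(rec$achieved_effective_total, ach, tolerance = 1e-9)
  # conservation within the division-shift
  expect_equal(sum(rec$redeployed_in_rn + rec$redeployed_in_hca),
               sum(rec$redeployed_out_rn + rec$redeployed_out_hca))

  # policy none: no redeployment, no temporary staff
  s <- make_rng_streams(7)
  rec0 <- simulate_shift(h, plan, flex_policy("none"), sim_params(), s, 3, 1)
  expect_true(all(rec0[c("redeployed_in_rn", "redeployed_in_hca",
                         "bank_rn", "bank_hca", "agency_rn",
                         "agency_hca")] == 0))
})

test_that("simulate_year has the documented shape and patient accounting", {
  h <- fixture_hospital(4)
  params <- sim_params(days = 14L)
  plan <- plan_hospital(h, "standard", params, 1)
  rec <- simulate_year(h, plan, flex_policy("empirical"), params, 2)
  expect_equal(nrow(rec), 14 * 4 * 4)
  expect_identical(sum(rec$patients),
                   sum(tapply(rec$patients, rec$ward_id, sum)))
  # full-year row count on one ward (365 x 4)
  h1 <- hospital_profile("one", list(constant_ward()))
  p1 <- manual_plan("W001", 12, 12)
  rec1 <- simulate_year(h1, p1, flex_policy("none"),
                        no_noise_params(multipliers = exact_fit_multipliers()),
                        1)
  expect_equal(nrow(rec1), 1460)
})

test_that("no-donor-harm and hire-cap invariants hold on random instances", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:4, 1)
    v <- round(stats::runif(n, -12, 12), 1)
    sur <- pmax(v, 0); sho <- pmax(-v, 0)
    res <- wardsim:::greedy_redeploy(sur, sho)
    # conservation of moved hours
    expect_equal(sum(res$give), sum(res$recv))
    # donations never exceed the donor's surplus
    expect_true(all(res$give <= sur + 1e-9))
  }
})
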