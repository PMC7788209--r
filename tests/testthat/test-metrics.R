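test_that("summarize_replication weights by patient shifts", {
  rec <- data.frame(ward_id = c("A", "B"), patients = c(10, 30),
                    state = c("understaffed", "adequate"),
                    permanent_rn = c(10, 10), permanent_hca = c(10, 10),
                    redeployed_in_rn = 0, redeployed_in_hca = 0,
                    bank_rn = 0, bank_hca = 0, agency_rn = 0,
                    agency_hca = 0)
  s <- summarize_replication(rec)
  expect_equal(s$pct_understaffed, 25)
  expect_equal(s$pct_overstaffed, 0)
  expect_equal(s$pct_hours_permanent, 100)
  rec$state <- "adequate"
  s0 <- summarize_replication(rec)
  expect_equal(s0$pct_understaffed + s0$pct_overstaffed, 0)
  expect_error(summarize_replication(rec[0, ]), "empty")
})

test_that("a simulated year re-aggregates identically via an independent count", {
  h <- fixture_hospital(4)
  params <- sim_params(days = 30L)
  plan <- plan_hospital(h, "standard", params, 1)
  rec <- simulate_year(h, plan, flex_policy("empirical"), params, 6)
  s <- summarize_replication(rec)
  # naive re-count straight off the exported CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(rec, path)
  csv <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(s$pct_understaffed,
               100 * sum(csv$patients[csv$state == "understaffed"]) /
                 sum(csv$patients))
  expect_equal(s$pct_overstaffed,
               100 * sum(csv$patients[csv$state == "overstaffed"]) /
                 sum(csv$patients))
  shares <- c(sum(csv$permanent_rn + csv$permanent_hca),
              sum(csv$redeployed_in_rn + csv$redeployed_in_hca),
              sum(csv$bank_rn + csv$bank_hca),
              sum(csv$agency_rn + csv$agency_hca))
  expect_equal(as.numeric(s[paste0("pct_hours_", c("permanent",
                                                   "redeployed", "bank",
                                                   "agency"))]),
               100 * shares / sum(shares), tolerance = 1e-6)
  expect_equal(s$pct_hours_permanent + s$pct_hours_redeployed +
                 s$pct_hours_bank + s$pct_hours_agency, 100,
               tolerance = 1e-6)
})

test_that("aggregate_replications computes t-based confidence intervals", {
  reps <- data.frame(pct_understaffed = c(10, 20))
  agg <- aggregate_replications(reps)
  expect_equal(agg$mean[["pct_understaffed"]], 15)
  # closed form: qt(.975, 1) * sd / sqrt(2) = 12.7062 * 7.0711 / 1.4142
  expect_equal(agg$ci95_halfwidth[["pct_understaffed"]],
               stats::qt(0.975, 1) * stats::sd(c(10, 20)) / sqrt(2))
  expect_equal(round(agg$ci95_halfwidth[["pct_understaffed"]], 2), 63.53)

  same <- data.frame(x = rep(4.2, 5))
  expect_equal(aggregate_replications(same)$ci95_halfwidth[["x"]], 0)
  expect_warning(one <- aggregate_replications(data.frame(x = 1)),
                 "unavailable")
  expect_true(is.na(one$ci95_halfwidth[["x"]]))
})

test_that("render_tables produces the deterministic wide layout", {
  grid <- expand.grid(scenario = c("low", "standard", "high"),
                      policy = c("none", "empirical"),
                      stringsAsFactors = FALSE)
  grid$pct_understaffed <- seq_len(nrow(grid)) * 10
  tab <- render_tables(grid, "pct_understaffed")
  expect_equal(names(tab$wide), c("policy", "low", "standard", "high"))
  expect_equal(tab$wide$policy, c("empirical", "none"))
  expect_match(tab$csv, "policy,low,standard,high")
  expect_match(tab$markdown, "\\| policy \\|")
  # regenerating from the same grid is byte-identical
  expect_identical(tab$csv, render_tables(grid, "pct_understaffed")$csv)
})

test_that("whole-sample weighting lies between hospital extremes", {
  ps <- c(1000, 3000, 500)
  pct <- c(10, 40, 70)
  whole <- sum(ps * pct) / sum(ps)
  expect_gte(whole, min(pct))
  expect_lte(whole, max(pct))
})

test_that("correlation_under_over matches the closed form", {
  expect_equal(correlation_under_over(c(1, 2, 3), c(3, 2, 1))$r, -1)
  u <- c(10, 20, 30); o <- c(5, 2, 6)
  r_hand <- sum((u - mean(u)) * (o - mean(o))) /
    sqrt(sum((u - mean(u))^2) * sum((o - mean(o))^2))
  expect_equal(correlation_under_over(u, o)$r, r_hand)
  set.seed(1)
  x <- stats::rnorm(1000); y <- stats::rnorm(1000)
  expect_lt(abs(correlation_under_over(x, y)$r), 0.1)
  expect_warning(res <- correlation_under_over(rep(1, 3), 1:3), "constant")
  expect_true(is.na(res$r))
  expect_error(correlation_under_over(1:2, 1:2), ">= 3")
})

test_that("ward_level_rates splits outcomes by ward", {
  rec <- data.frame(ward_id = c("A", "A", "B"), patients = c(10, 10, 5),
                    state = c("understaffed", "adequate", "overstaffed"))
  wl <- ward_level_rates(rec)
  expect_equal(wl$pct_understaffed[wl$ward_id == "A"], 50)
  expect_equal(wl$pct_overstaffed[wl$ward_id == "B"], 100)
})
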