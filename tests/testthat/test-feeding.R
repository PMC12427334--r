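test_that("stage classification follows the half-open interval table", {
  expect_equal(classify_stage(50)$stage, "Fattening Stage II")
  expect_equal(classify_stage(90)$stage, "Fattening Stage III")
  expect_equal(classify_stage(15.05)$stage, "Fattening Stage I")
  expect_equal(classify_stage(10)$stage, "Weaning Period")
  # printed interior weights land in their printed stages
  expect_equal(classify_stage(14.9)$stage, "Weaning Period")
  expect_equal(classify_stage(15.1)$stage, "Fattening Stage I")
  expect_equal(classify_stage(40.0)$stage, "Fattening Stage I")
  expect_equal(classify_stage(40.1)$stage, "Fattening Stage II")
  expect_equal(classify_stage(80.0)$stage, "Fattening Stage II")
  expect_equal(classify_stage(80.1)$stage, "Fattening Stage III")
  expect_equal(classify_stage(300)$stage, "Fattening Stage III")
})

test_that("weights below the table map to the first stage, flagged", {
  st <- classify_stage(5)
  expect_equal(st$stage, "Weaning Period")
  expect_true(st$below_range)
  expect_false(classify_stage(10)$below_range)
  expect_error(classify_stage(0), "positive")
})

test_that("classification is total and unique over a dense weight grid", {
  tab <- default_stage_table()
  for (w in seq(1, 200, by = 0.7)) {
    st <- classify_stage(w, tab)
    expect_length(st$stage, 1)
  }
})

test_that("daily gain is the OLS slope of the trailing window", {
  expect_equal(daily_gain(c(0, 7), c(50, 54.55)), 4.55 / 7)
  expect_equal(daily_gain(c(0, 5, 10), c(60, 60, 60)), 0)
  expect_equal(daily_gain(c(3, 10), c(40, 44)), 4 / 7)  # finite difference
  expect_error(daily_gain(5, 50), "distinct")
  # trailing window sees only the recent, slower phase
  days <- seq(0, 28, by = 7)
  w <- c(30, 37, 44, 44.5, 45)  # 1 kg/day then ~0.07 kg/day
  expect_lt(daily_gain(days, w, window_days = 14), 0.2)
  expect_gt(daily_gain(days, w, window_days = 100), 0.4)
})

test_that("rapid-growth adjustment matches the pro-rata arithmetic", {
  base <- ration(65, 18, 13, 4)  # Fattening Stage II
  adj <- adjust_ration(base, weight = 50, adg = 0.7)
  expect_equal(adj$corn, 68)
  expect_equal(adj$soybean_meal, 19)
  expect_equal(adj$wheat_bran, 13 * 13 / 17, tolerance = 1e-10)
  expect_equal(adj$compound_and_other, 13 * 4 / 17, tolerance = 1e-10)
  expect_equal(sum(unlist(adj[c("corn", "soybean_meal", "wheat_bran",
                                "compound_and_other", "fishmeal")])), 100)
  expect_equal(attr(adj, "rule"), "rapid_growth")
})

test_that("slow growers get the corrective diet with precedence", {
  base <- ration(65, 18, 13, 4)
  adj <- adjust_ration(base, weight = 50, adg = 0.5)  # both rules fire
  expect_equal(adj$soybean_meal, 20)
  expect_equal(adj$fishmeal, 2)
  expect_equal(adj$corn, 65)  # rapid-growth rule did not apply
  expect_equal(attr(adj, "rule"), "slow_grower")
  expect_equal(sum(unlist(adj[c("corn", "soybean_meal", "wheat_bran",
                                "compound_and_other", "fishmeal")])), 100)
})

test_that("no rule fires outside the band at healthy gain", {
  base <- ration(67, 15, 14, 4)
  adj <- adjust_ration(base, weight = 90, adg = 0.7)
  expect_equal(attr(adj, "rule"), "none")
  expect_equal(unclass(adj)[names(unclass(base))], unclass(base),
               ignore_attr = TRUE)
})

test_that("adjustment is idempotent", {
  base <- ration(65, 18, 13, 4)
  once <- adjust_ration(base, 50, 0.7)
  twice <- adjust_ration(once, 50, 0.7)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)
  once2 <- adjust_ration(base, 50, 0.5)
  twice2 <- adjust_ration(once2, 50, 0.5)
  expect_equal(unclass(twice2), unclass(once2), ignore_attr = TRUE)
})

test_that("re-balancing parks residual mass when no free component is left", {
  base <- ration(70, 25, 0, 0, 5)
  adj <- adjust_ration(base, 50, 0.7)  # corn 68 + sbm 19 + fish 5 = 92
  comps <- unlist(adj[c("corn", "soybean_meal", "wheat_bran",
                        "compound_and_other", "fishmeal")])
  expect_true(all(comps >= 0))
  expect_equal(sum(comps), 100)
  expect_true(attr(adj, "clamped"))
  # adjusted components that already exceed 100% cannot be balanced
  expect_error(adjust_ration(ration(82, 18, 0, 0), 50, 0.5), "exceed")
})

test_that("ration construction enforces the 100% invariant", {
  expect_error(ration(60, 20, 5, 10), "sum to 100")
  expect_error(ration(105, -5, 0, 0), ">= 0")
  tab <- default_stage_table()
  for (r in tab$ration) {
    expect_equal(sum(unlist(r[c("corn", "soybean_meal", "wheat_bran",
                                "compound_and_other", "fishmeal")])), 100)
  }
})

test_that("feed allowance interpolates the configured curve", {
  al <- c(`30` = 1.4, `80` = 2.6)
  expect_equal(plan_feed_quantity(55, allowance = al), 2.0)
  expect_equal(plan_feed_quantity(30, allowance = al), 1.4)
  expect_equal(plan_feed_quantity(80, allowance = al), 2.6)
  expect_error(plan_feed_quantity(55, allowance = numeric(0)), "allowance")
  # denser diet plans proportionally less mass
  expect_equal(plan_feed_quantity(55, energy_density = 13, allowance = al),
               2.0 * 12 / 13)
})

test_that("per-pig plans are emitted for every animal", {
  co <- generate_cohort(cohort_spec(n_pigs = 8, seed = 3))
  plans <- feeding_plan(co)
  expect_equal(nrow(plans), 8)
  comps <- plans[, c("corn", "soybean_meal", "wheat_bran",
                     "compound_and_other", "fishmeal")]
  expect_true(all(abs(rowSums(comps) - 100) < 0.01))
  expect_true(all(plans$feed_kg_day > 0))
})
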