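test_that("grouping index is the elementwise population-profile product", {
  pop <- make_initial_population(1e6, seed = 1)
  prof <- make_he_index_profile(seed = 1, pop = pop)
  gi <- grouping_index(pop, prof)
  expect_equal(gi, pop * unclass(prof), ignore_attr = TRUE)
  expect_equal(gi[3, "F"], pop[3, "F"] * prof[3, "F"])
  expect_equal(grouping_index(0 * pop, prof), 0 * pop, ignore_attr = TRUE)
  expect_error(grouping_index(pop[1:5, ], prof), "42 cells")
})

test_that("total index sums all 42 cells and an aged population right-skews it", {
  ones <- matrix(1, 21, 2)
  expect_equal(total_he_index(ones), 42)
  single <- matrix(0, 21, 2)
  single[16, 1] <- 3.7
  expect_equal(total_he_index(single), 3.7)

  # by 2060 under low TFR the old-age groups dominate the grouping index
  res <- run_scenario(scenario_config(tfr = 1.05, seed = 1))
  pop60 <- res$trajectory$pop[, , "2060"]
  gi60 <- grouping_index(pop60, res$inputs$he_profile)
  expect_gt(sum(gi60[12:19, ]), sum(gi60[1:11, ]))
  # and in 2000 the reverse held
  gi00 <- grouping_index(res$trajectory$pop[, , "2000"],
                         res$inputs$he_profile)
  expect_lt(sum(gi00[12:19, ]), sum(gi00[1:11, ]))
})

test_that("per-unit calibration divides the anchor by the base-year index", {
  expect_equal(per_unit_index(5, 5), 1)
  expect_equal(per_unit_index(0.127e12, 1.243e9), 102.17216,
               tolerance = 1e-7)
  expect_equal(per_unit_index(10, 2), 2 * per_unit_index(10, 4))
  expect_error(per_unit_index(10, 0), "positive")
})

test_that("the four-factor identity recovers its anchor and multiplies exactly", {
  expect_equal(total_health_expenditure(7, 1, 1, 1), 7)
  expect_equal(total_health_expenditure(100, 1, 1.03, 1.05), 108.15)
  expect_equal(total_health_expenditure(2, 3, 5, 7),
               total_health_expenditure(7, 5, 3, 2))
  expect_error(total_health_expenditure(-1, 1, 1, 1), "positive")
})

test_that("the efficiency divisor compounds from 2021 and deflates expenditure", {
  zero <- function(year) 0
  expect_equal(apply_efficiency(5e12, zero, 2060), 5e12)
  expect_equal(efficiency_divisor(zero, 2015), 1)
  sched <- default_efficiency_schedule()
  expect_equal(efficiency_divisor(sched, 2020), 1)
  expect_equal(efficiency_divisor(sched, 2040), 1.03^20, tolerance = 1e-12)
  expect_equal(efficiency_divisor(sched, 2060), 1.03^20 * 1.04^20,
               tolerance = 1e-12)
  five <- function(year) 0.05
  expect_equal(efficiency_divisor(five, 2060), 1.05^40, tolerance = 1e-12)
  expect_equal(1.05^40, 7.039989, tolerance = 1e-6)
  # multiplier form deflates more than the divisor form at equal rates
  expect_gt(efficiency_divisor(sched, 2060, form = "multiplier"),
            efficiency_divisor(sched, 2060, form = "divisor"))
  expect_error(efficiency_divisor(function(y) -0.01, 2025), "non-negative")
  expect_error(default_efficiency_schedule(0.06), "0, 0.05")
})

test_that("per-capita and GDP-share accessors are plain ratios", {
  expect_equal(per_capita(8.6e12, 1.09e9), 7889.908, tolerance = 1e-6)
  expect_equal(per_capita(5, 1), 5)
  expect_error(per_capita(1, 0), "positive")
  expect_equal(the_to_gdp(5, 5), 100)
  expect_equal(the_to_gdp(8.6e12, 87e12), 9.885057, tolerance = 1e-6)
  expect_gt(the_to_gdp(1, 2), the_to_gdp(1, 3))
  expect_error(the_to_gdp(1, 0), "positive")
})

test_that("anchor is recovered at the base year in both price bases", {
  for (basis in c("constant_2015_usd", "current_cny")) {
    res <- run_scenario(scenario_config(price_basis = basis, seed = 1))
    expect_equal(res$series$the_raw[1], he_params(basis)$the_anchor_2000)
    expect_equal(res$series$the_adjusted[1], res$series$the_raw[1])
  }
})

test_that("pointwise-larger efficiency schedules deflate expenditure more, every year", {
  cfgs <- lapply(1:5 / 100, function(e)
    scenario_config(tfr = 1.45, efficiency = e, seed = 1))
  runs <- lapply(cfgs, run_scenario)
  for (i in 1:4) {
    a <- runs[[i]]$series
    b <- runs[[i + 1]]$series
    expect_equal(a$the_raw, b$the_raw)   # raw series untouched
    expect_true(all(b$the_adjusted <= a$the_adjusted))
    expect_true(all(b$the_adjusted[b$year > 2021] <
                      a$the_adjusted[a$year > 2021]))
  }
  # adjusted never exceeds raw under non-negative gains
  expect_true(all(runs[[1]]$series$the_adjusted <= runs[[1]]$series$the_raw))
})

test_that("with a frozen population THE grows at exactly (1+d)(1+c) - 1", {
  pui <- 250
  idx <- 1.7e9
  d <- 0.03
  c_ <- 0.05
  the <- sapply(0:30, function(n)
    total_health_expenditure(pui, idx, compound(d, 0, n), compound(c_, 0, n)))
  g <- annualized_growth(the[1], the[31], 30)
  expect_equal(g, (1 + d) * (1 + c_) - 1, tolerance = 1e-10)
  step_growth <- the[-1] / head(the, -1) - 1
  expect_equal(step_growth, rep((1 + d) * (1 + c_) - 1, 30),
               tolerance = 1e-12)
})
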