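test_that("scenario configuration validates its slider ranges", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(tfr = 0.9), "\\[1, 3\\]")
  expect_error(scenario_config(tfr = 3.5), "\\[1, 3\\]")
  expect_error(scenario_config(efficiency = 0.06), "0, 0.05")
  expect_error(scenario_config(productivity_growth = 0.005), "0.01, 0.09")
  expect_error(scenario_config(retirement_scenario = 5), "0, 1 or 2")
  expect_error(scenario_config(start = 2060, end = 2000), "precede")
})

test_that("runs are deterministic and carry a reproducible manifest", {
  cfg <- scenario_config(tfr = 1.45, seed = 3)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$manifest$input_hash, b$manifest$input_hash)
  c_ <- run_scenario(scenario_config(tfr = 1.45, seed = 4))
  expect_false(identical(a$manifest$input_hash, c_$manifest$input_hash))
  expect_equal(a$manifest$seed, 3L)
  # every year present exactly once
  expect_equal(a$series$year, 2000:2060)
})

test_that("per-capita, population and adjusted expenditure are mutually consistent", {
  res <- run_scenario(scenario_config(tfr = 1.05, seed = 1))
  s <- res$series
  expect_equal(s$he_pc * s$population, s$the_adjusted, tolerance = 1e-12)
  expect_equal(s$the_to_gdp_pct, 100 * s$the_adjusted / s$gdp,
               tolerance = 1e-12)
  expect_true(all(s$workforce <= s$population))
})

test_that("fertility scenarios order population, expenditure and the GDP share", {
  runs <- lapply(TFR_PRESETS, function(f)
    run_scenario(scenario_config(tfr = f, seed = 1)))
  at2060 <- lapply(runs, function(r) r$series[r$series$year == 2060, ])
  # population strictly larger under higher fertility
  expect_lt(at2060$low$population, at2060$medium$population)
  expect_lt(at2060$medium$population, at2060$high$population)
  # THE rises with TFR while per-capita expenditure falls
  expect_lte(at2060$low$the_adjusted, at2060$medium$the_adjusted)
  expect_lte(at2060$medium$the_adjusted, at2060$high$the_adjusted)
  expect_gte(at2060$low$he_pc, at2060$medium$he_pc)
  expect_gte(at2060$medium$he_pc, at2060$high$he_pc)
  # THE/GDP fan ordered low > medium > high
  expect_gt(at2060$low$the_to_gdp_pct, at2060$medium$the_to_gdp_pct)
  expect_gt(at2060$medium$the_to_gdp_pct, at2060$high$the_to_gdp_pct)
  # scenario curves coincide before the switch year
  pre <- runs$low$series$year < 2021
  expect_equal(runs$low$series$the_raw[pre], runs$high$series$the_raw[pre])
})

test_that("efficiency-only changes leave the raw series untouched", {
  none <- run_scenario(scenario_config(efficiency = 0, seed = 1))
  sched <- run_scenario(scenario_config(efficiency = c(0.03, 0.04), seed = 1))
  expect_equal(none$series$the_raw, sched$series$the_raw)
  expect_equal(none$series$the_adjusted, none$series$the_raw)
  expect_true(all(sched$series$the_adjusted[sched$series$year > 2020] <
                    sched$series$the_raw[sched$series$year > 2020]))
})

test_that("sweeps run one scenario per value and respect known monotonicity", {
  base <- scenario_config(tfr = 1.45, seed = 1)
  sw <- sweep_scenarios(base, "efficiency", c(0.01, 0.03, 0.05))
  expect_length(sw, 3L)
  pc <- sapply(sw, function(r) r$series$he_pc[r$series$year == 2060])
  expect_true(all(diff(pc) < 0))
  expect_length(sweep_scenarios(base, "tfr", numeric(0)), 0L)
  one <- sweep_scenarios(base, "tfr", 1.45)
  expect_equal(one[[1]]$series, run_scenario(base)$series)
  expect_error(sweep_scenarios(base, "gravity", 1), "valid names")
})

test_that("the comparison report rounds the way the headline table does", {
  res <- run_scenario(scenario_config(tfr = 1.05, seed = 1))
  # inject the published 2060 magnitudes to pin the rounding rules
  n <- nrow(res$series)
  res$series$population[n] <- 1.09e9
  res$series$the_adjusted[n] <- 8.6e12
  res$series$he_pc[n] <- 8.6e12 / 1.09e9
  rep1 <- table1_report(list(res), labels = "2060 low")
  expect_equal(rep1$he_per_capita[2], 7900)
  expect_equal(rep1$the_trillions[2], 8.6)
  expect_equal(rep1$total_population_billions[2], 1.09)
  # the medium-scenario magnitudes round to 7300
  res$series$population[n] <- 1.22e9
  res$series$the_adjusted[n] <- 8.9e12
  res$series$he_pc[n] <- 8.9e12 / 1.22e9
  rep2 <- table1_report(list(res))
  expect_equal(rep2$he_per_capita[2], 7300)
  # base-year per-capita prints unrounded-to-hundreds (small values)
  expect_equal(rep1$scenario[1], "2000")
  expect_lt(abs(rep1$he_per_capita[1] - rep1$the_trillions[1] * 1e12 /
                  (rep1$total_population_billions[1] * 1e9)), 100)
  # a single result gives a baseline plus one scenario row
  expect_equal(nrow(rep1), 2L)
  expect_error(table1_report(list(res, run_scenario(
    scenario_config(start = 2005, end = 2060)))), "start year")
})

test_that("results export a series CSV and JSON manifest that reload", {
  res <- run_scenario(scenario_config(seed = 2, start = 2000, end = 2010))
  dir <- withr::local_tempdir()
  paths <- write_result(res, dir, stem = "demo")
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["series"]])
  expect_equal(nrow(back), 11L)
  expect_equal(back$the_raw, res$series$the_raw, tolerance = 1e-9)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 2L)
  expect_equal(man$input_hash, res$manifest$input_hash)
})
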