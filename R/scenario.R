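# Scenario engine: configuration, end-to-end runs, parameter sweeps, and the
# comparison report. A run couples the population projection, workforce/GDP
# model and expenditure model on one shared annual grid; scenario levers
# (TFR, efficiency, retirement) switch on at the scenario switch year so all
# scenarios share one historical path before it.

#' Scenario configuration
#'
#' Bundles every lever and constant defining one simulation run. Slider
#' ranges follow the interactive model: TFR 1.0-3.0, efficiency gains
#' 0-5%/yr, post-switch productivity growth 1-9%/yr, retirement scenario
#' 0/1/2.
#'
#' @param tfr Scenario total fertility rate in \[1, 3\] (low/medium/high
#'   presets are 1.05/1.45/1.85).
#' @param retirement_scenario 0 (normal), 1 (delayed) or 2 (maximum delayed
#'   retirement).
#' @param efficiency Either a single annual gain applied 2021-2060, or a
#'   length-2 vector `c(rate_2021_2040, rate_2041_2060)`; gains in
#'   \[0, 0.05\]. Default `c(0.03, 0.04)`.
#' @param productivity_growth Post-switch annual productivity growth in
#'   \[0.01, 0.09\] (default 0.05; pre-switch rate fixed at 0.09).
#' @param price_basis `"constant_2015_usd"` or `"current_cny"`.
#' @param start,end Simulation years (default 2000-2060).
#' @param switch_year Year scenario levers take effect (default 2021).
#' @param baseline_tfr TFR before the switch year (default 1.6).
#' @param seed Integer seed for the synthetic input generators.
#' @param total_population_2000 Initial population, persons.
#' @param mortality_level Multiplier on the synthetic mortality schedule.
#' @param srb Sex ratio at birth.
#' @param initial_gdp_per_workforce Base-year GDP per worker.
#' @param efficiency_form `"divisor"` or `"multiplier"`; see [he_params()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(tfr = 1.45,
                            retirement_scenario = 0L,
                            efficiency = c(0.03, 0.04),
                            productivity_growth = 0.05,
                            price_basis = "constant_2015_usd",
                            start = 2000L, end = 2060L,
                            switch_year = 2021L,
                            baseline_tfr = 1.6,
                            seed = 1L,
                            total_population_2000 = 1.243e9,
                            mortality_level = 1,
                            srb = 1.07,
                            initial_gdp_per_workforce = 2000,
                            efficiency_form = "divisor") {
  if (tfr < 1 || tfr > 3) stop("`tfr` must lie in [1, 3]", call. = FALSE)
  if (!retirement_scenario %in% 0:2)
    stop("`retirement_scenario` must be 0, 1 or 2", call. = FALSE)
  if (!length(efficiency) %in% 1:2 || any(efficiency < 0) || any(efficiency > 0.05))
    stop("`efficiency` must be 1-2 gains in [0, 0.05]", call. = FALSE)
  if (productivity_growth < 0.01 || productivity_growth > 0.09)
    stop("`productivity_growth` must lie in [0.01, 0.09]", call. = FALSE)
  if (start >= end) stop("`start` must precede `end`", call. = FALSE)
  structure(list(tfr = tfr,
                 retirement_scenario = as.integer(retirement_scenario),
                 efficiency = efficiency,
                 productivity_growth = productivity_growth,
                 price_basis = match.arg(price_basis,
                                         c("constant_2015_usd", "current_cny")),
                 start = as.integer(start), end = as.integer(end),
                 switch_year = as.integer(switch_year),
                 baseline_tfr = baseline_tfr,
                 seed = as.integer(seed),
                 total_population_2000 = total_population_2000,
                 mortality_level = mortality_level,
                 srb = srb,
                 initial_gdp_per_workforce = initial_gdp_per_workforce,
                 efficiency_form = efficiency_form),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration\n")
  cat(sprintf("  TFR %.2f (baseline %.2f before %d), retirement %d\n",
              x$tfr, x$baseline_tfr, x$switch_year, x$retirement_scenario))
  eff <- if (length(x$efficiency) == 1L) rep(x$efficiency, 2L) else x$efficiency
  cat(sprintf("  efficiency %.1f%%/yr 2021-2040, %.1f%%/yr 2041-2060 (%s form)\n",
              100 * eff[1L], 100 * eff[2L], x$efficiency_form))
  cat(sprintf("  productivity %.0f%%/yr post-switch, basis %s, years %d-%d, seed %d\n",
              100 * x$productivity_growth, x$price_basis, x$start, x$end, x$seed))
  invisible(x)
}

efficiency_schedule_from_config <- function(config) {
  eff <- config$efficiency
  if (length(eff) == 1L) eff <- c(eff, eff)
  default_efficiency_schedule(eff[1L], eff[2L])
}

#' Run one scenario end to end
#'
#' Generates the synthetic inputs from the config seed, projects the
#' population, and evaluates the workforce, GDP and expenditure models on
#' every year of the run. Deterministic given the config (including seed).
#'
#' @param config A [scenario_config()].
#' @return An object of class `sd_forecast`: list with `series` (per-year
#'   data frame), `config`, `inputs` (the generated profiles) and `manifest`.
#' @examples
#' res <- run_scenario(scenario_config(tfr = 1.05, seed = 1))
#' summary(res)
#' @export
run_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  years <- seq.int(config$start, config$end)

  profile <- demographic_profile(total = config$total_population_2000,
                                 mortality_level = config$mortality_level,
                                 srb = config$srb, seed = config$seed)
  he_profile <- make_he_index_profile(config$seed,
                                      pop = profile$initial_population)
  part_base <- make_participation_profile(0L, years)
  part_scen <- make_participation_profile(config$retirement_scenario, years)
  eco <- economy_params(initial_gdp_per_workforce = config$initial_gdp_per_workforce,
                        productivity_rate_post = config$productivity_growth)
  hep <- he_params(price_basis = config$price_basis,
                   efficiency_schedule = efficiency_schedule_from_config(config),
                   efficiency_form = config$efficiency_form)

  traj <- project(profile, config$tfr, config$start, config$end,
                  tfr_switch_year = config$switch_year,
                  baseline_tfr = config$baseline_tfr)

  index_2000 <- total_he_index(grouping_index(traj$pop[, , 1L], he_profile))
  pui <- per_unit_index(hep$the_anchor_2000, index_2000)

  n <- length(years)
  series <- data.frame(year = years, population = NA_real_,
                       pct_65plus = NA_real_, births = traj$births,
                       deaths = traj$deaths, workforce = NA_real_,
                       productivity_index = NA_real_, gdp = NA_real_,
                       the_index = NA_real_, demand_index = NA_real_,
                       cost_index = NA_real_, efficiency_divisor = NA_real_,
                       the_raw = NA_real_, the_adjusted = NA_real_,
                       he_pc = NA_real_, the_to_gdp_pct = NA_real_)
  for (i in seq_len(n)) {
    y <- years[i]
    pop_y <- traj$pop[, , i]
    am <- ageing_metrics(traj, y)
    part <- if (y >= config$switch_year) part_scen else part_base
    wf <- workforce(pop_y, part, y)
    pidx <- productivity_index(eco, y, base_year = config$start)
    gdp_y <- gdp(wf, eco, pidx)
    the_idx <- total_he_index(grouping_index(pop_y, he_profile))
    d_idx <- compound(hep$demand_growth_rate, config$start, y)
    c_idx <- compound(hep$cost_growth_rate, config$start, y)
    div <- efficiency_divisor(hep$efficiency_schedule, y, hep$efficiency_form)
    the_raw <- total_health_expenditure(pui, the_idx, d_idx, c_idx)
    the_adj <- the_raw / div
    series[i, -(1L)] <- c(am["total"], am["pct_65plus"], traj$births[i],
                          traj$deaths[i], wf, pidx, gdp_y, the_idx, d_idx,
                          c_idx, div, the_raw, the_adj,
                          the_adj / am["total"], the_to_gdp(the_adj, gdp_y))
  }

  inputs <- list(profile = profile, he_profile = he_profile,
                 participation = part_scen)
  manifest <- list(package = "hesd",
                   version = as.character(packageVersion("hesd")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "efficiency_form")],
                   efficiency_form = config$efficiency_form,
                   input_hash = hash_inputs(inputs))
  structure(list(series = series, config = config, inputs = inputs,
                 trajectory = traj, manifest = manifest),
            class = "sd_forecast")
}

# md5 of all generated input arrays, so published tables are re-derivable.
hash_inputs <- function(inputs) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeBin(c(as.vector(inputs$profile$initial_population),
             as.vector(inputs$profile$mortality),
             as.vector(inputs$profile$fertility_shape),
             inputs$profile$sex_ratio_at_birth,
             as.vector(unclass(inputs$he_profile)),
             as.vector(inputs$participation$rates)), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' Sweep one scenario parameter
#'
#' Runs [run_scenario()] once per value of a recognised lever, holding the
#' rest of the configuration fixed.
#'
#' @param base A [scenario_config()] providing all other settings.
#' @param parameter One of `"tfr"`, `"efficiency"`, `"productivity"`,
#'   `"retirement"`.
#' @param values Values to sweep; an empty vector yields an empty list.
#' @return List of `sd_forecast` objects (class `sd_sweep`), in `values`
#'   order, with the parameter and values attached as attributes.
#' @export
sweep_scenarios <- function(base, parameter, values) {
  stopifnot(inherits(base, "scenario_config"))
  valid <- c("tfr", "efficiency", "productivity", "retirement")
  if (!is.character(parameter) || length(parameter) != 1L || !parameter %in% valid)
    stop("unknown parameter; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  field <- switch(parameter, tfr = "tfr", efficiency = "efficiency",
                  productivity = "productivity_growth",
                  retirement = "retirement_scenario")
  results <- lapply(values, function(v) {
    cfg <- base
    cfg[[field]] <- v
    cfg <- do.call(scenario_config, unclass(cfg))  # revalidate
    run_scenario(cfg)
  })
  structure(results, class = "sd_sweep", parameter = parameter,
            values = values)
}

#' Scenario comparison report
#'
#' Formats a baseline row plus one row per scenario in the style of the
#' headline comparison table: total population in billions, percentage aged
#' 65+, per-capita expenditure (rounded to the nearest hundred once above
#' 1000, else to the nearest unit) and total expenditure in trillions (two
#' decimals below one trillion, else one).
#'
#' @param results A list of `sd_forecast` objects (or an `sd_sweep`); all
#'   must share their start year and price basis.
#' @param labels Optional row labels for the scenarios.
#' @return A data frame of class `table1_report`.
#' @export
table1_report <- function(results, labels = NULL) {
  if (inherits(results, "sd_forecast")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1L), "sd_forecast")))
  starts <- vapply(results, function(r) r$config$start, integer(1L))
  bases <- vapply(results, function(r) r$config$price_basis, character(1L))
  if (length(unique(starts)) != 1L)
    stop("results must share their start year", call. = FALSE)
  if (length(unique(bases)) != 1L)
    stop("results mix price bases", call. = FALSE)
  if (is.null(labels))
    labels <- vapply(results, function(r)
      sprintf("%d TFR %.2f scenario", r$config$end, r$config$tfr), character(1L))

  fmt_row <- function(s, label) {
    pc <- s$he_pc
    data.frame(scenario = label,
               total_population_billions = signif(s$population / 1e9, 3),
               pct_65plus = round(s$pct_65plus, 1),
               he_per_capita = if (pc >= 1000) round_hundred(pc) else round(pc),
               the_trillions = if (s$the_adjusted < 1e12)
                 round(s$the_adjusted / 1e12, 2)
               else round(s$the_adjusted / 1e12, 1))
  }
  base <- results[[1L]]$series[1L, ]
  rows <- rbind(fmt_row(base, as.character(starts[1L])),
                do.call(rbind, Map(function(r, lab)
                  fmt_row(r$series[nrow(r$series), ], lab), results, labels)))
  rownames(rows) <- NULL
  class(rows) <- c("table1_report", "data.frame")
  attr(rows, "price_basis") <- bases[1L]
  rows
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Scenario comparison (", attr(x, "price_basis"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
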