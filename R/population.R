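# Cohort population projection: an ageing chain of 21 five-year stocks per
# sex advanced annually. Promotion moves 1/5 of each group's survivors up the
# chain each year; the terminal group is open-ended.

#' Annual births from an age-sex population
#'
#' Births per year implied by a total fertility rate spread over the seven
#' childbearing groups (ages 15-49.99): each group contributes
#' `tfr * shape_g / 5` births per woman per year (the division by 5 converts
#' a per-5-year-group lifetime share to an annual rate). Total births are
#' split by the sex ratio at birth.
#'
#' @param pop 21 x 2 population matrix, persons.
#' @param tfr Total fertility rate, children per woman; non-negative.
#' @param shape Fertility weights over groups 4-10 summing to 1.
#' @param srb Male births per female birth.
#' @return Named numeric vector `c(M = male births, F = female births)` per year.
#' @export
annual_births <- function(pop, tfr, shape = make_fertility_shape(), srb = 1.07) {
  check_agesex(pop, "pop")
  if (!is.numeric(tfr) || length(tfr) != 1L || !is.finite(tfr) || tfr < 0)
    stop("`tfr` must be a single non-negative number", call. = FALSE)
  if (abs(sum(shape) - 1) > 1e-8) stop("`shape` must sum to 1", call. = FALSE)
  total <- sum(tfr * shape / 5 * pop[FERTILE_GROUPS, "F"])
  f <- total / (1 + srb)
  c(M = total - f, F = f)
}

#' One annual step of the ageing chain
#'
#' Applies mortality, promotes one fifth of each group's survivors to the
#' next group (groups 1-20), retains survivors in the open-ended terminal
#' group, and adds the year's births to group 1. Births entering group 1 are
#' not exposed to mortality until the following step.
#'
#' @param pop 21 x 2 population matrix, persons.
#' @param mortality 21 x 2 matrix of annual death probabilities in \[0,1\].
#' @param births Named vector `c(M=, F=)` of births entering group 1.
#' @return The updated 21 x 2 population matrix.
#' @export
step_population <- function(pop, mortality, births = c(M = 0, F = 0)) {
  check_agesex(pop, "pop")
  check_agesex(mortality, "mortality", max = 1)
  if (any(births < 0)) stop("births must be non-negative", call. = FALSE)
  if (is.null(names(births))) names(births) <- SEXES
  surv <- pop * (1 - mortality)
  promoted <- surv / 5
  promoted[N_GROUPS, ] <- 0                # terminal stock retains survivors
  new <- surv - promoted
  new[-1L, ] <- new[-1L, ] + promoted[-N_GROUPS, ]
  new[1L, ] <- new[1L, ] + births[SEXES]
  if (any(new < -1e-9))
    stop("negative population after update: check the rate schedules",
         call. = FALSE)
  pmax(new, 0)
}

#' Project the population over a span of years
#'
#' Runs the ageing chain annually from `start` to `end` under a scenario
#' total fertility rate. The scenario TFR switches on at `tfr_switch_year`
#' (default 2021, where scenario trajectories begin to diverge); earlier
#' years use `baseline_tfr` so all scenarios share one historical path.
#'
#' @param profile A [demographic_profile()].
#' @param tfr Scenario total fertility rate.
#' @param start,end First and last calendar years (start < end).
#' @param tfr_switch_year Year the scenario TFR takes effect.
#' @param baseline_tfr TFR applied before the switch year.
#' @return A `population_trajectory`: list with `years`, a 21 x 2 x n_years
#'   array `pop`, and per-year `births`, `deaths` vectors (flows during each
#'   year; the final year's flows are not applied).
#' @export
project <- function(profile, tfr, start = 2000L, end = 2060L,
                    tfr_switch_year = 2021L, baseline_tfr = 1.6) {
  validate_demographic_profile(profile)
  if (start >= end) stop("`start` must precede `end`", call. = FALSE)
  if (tfr < 0) stop("`tfr` must be non-negative", call. = FALSE)
  years <- seq.int(start, end)
  n <- length(years)
  pop <- array(0, dim = c(N_GROUPS, 2L, n),
               dimnames = c(dimnames(empty_pop()), list(year = years)))
  births <- deaths <- numeric(n)
  cur <- profile$initial_population
  for (i in seq_len(n)) {
    pop[, , i] <- cur
    if (i == n) break
    tfr_y <- if (years[i] >= tfr_switch_year) tfr else baseline_tfr
    b <- annual_births(cur, tfr_y, profile$fertility_shape,
                       profile$sex_ratio_at_birth)
    d <- cur * profile$mortality
    births[i] <- sum(b)
    deaths[i] <- sum(d)
    cur <- step_population(cur, profile$mortality, b)
  }
  structure(list(years = years, pop = pop, births = births, deaths = deaths,
                 tfr = tfr, baseline_tfr = baseline_tfr,
                 tfr_switch_year = tfr_switch_year),
            class = "population_trajectory")
}

#' Population size and ageing share at a year
#'
#' @param traj A `population_trajectory`.
#' @param year Calendar year inside the trajectory.
#' @return Named vector: `total` persons and `pct_65plus`, the percentage of
#'   the population in groups 14-21 (ages 65+).
#' @export
ageing_metrics <- function(traj, year) {
  stopifnot(inherits(traj, "population_trajectory"))
  check_year(year, traj$years)
  p <- traj$pop[, , as.character(year)]
  total <- sum(p)
  pct <- if (total > 0) 100 * sum(p[ELDERLY_GROUPS, ]) / total else 0
  c(total = total, pct_65plus = pct)
}

#' @export
print.population_trajectory <- function(x, ...) {
  n <- length(x$years)
  first <- ageing_metrics(x, x$years[1L])
  last <- ageing_metrics(x, x$years[n])
  cat("Population trajectory ", x$years[1L], "-", x$years[n],
      " (TFR ", x$tfr, " from ", x$tfr_switch_year, ")\n", sep = "")
  cat(sprintf("  %d: %.4g persons (%.1f%% aged 65+)\n",
              x$years[1L], first["total"], first["pct_65plus"]))
  cat(sprintf("  %d: %.4g persons (%.1f%% aged 65+)\n",
              x$years[n], last["total"], last["pct_65plus"]))
  invisible(x)
}

#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  n <- length(x$years)
  data.frame(year = rep(x$years, each = 2L * N_GROUPS),
             group = rep(seq_len(N_GROUPS), times = 2L * n),
             sex = rep(rep(SEXES, each = N_GROUPS), times = n),
             count = as.vector(x$pop))
}

#' Per-year summary of a trajectory
#'
#' @param object A `population_trajectory`.
#' @param ... Unused.
#' @return Data frame with year, total, pct_65plus, births, deaths.
#' @export
summary.population_trajectory <- function(object, ...) {
  m <- t(vapply(object$years, function(y) ageing_metrics(object, y),
                numeric(2L)))
  data.frame(year = object$years, total = m[, "total"],
             pct_65plus = m[, "pct_65plus"],
             births = object$births, deaths = object$deaths)
}
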