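# Synthetic exogenous inputs: initial pyramid, mortality, fertility shape,
# age-sex expenditure index, participation schedules. Every generator is
# deterministic for a fixed seed and scale-free where the quantity admits it.

#' Generate a synthetic initial age-sex population
#'
#' Builds a 21-group x 2-sex array of persons with a realistic (monotone
#' young-heavy, old-age attenuated) pyramid, a slight male excess at young
#' ages from the sex ratio at birth and a female excess at old ages from
#' differential survival. Entries are jittered multiplicatively (a few
#' percent, seeded) so distinct seeds give distinct but structurally similar
#' pyramids; entries always sum to `total` exactly.
#'
#' @param total Total persons across all 42 cells; must be positive.
#'   Default 1.243e9, a year-2000 China-scale population.
#' @param seed Integer RNG seed; the array is reproducible bit-for-bit.
#' @return A 21 x 2 numeric matrix (rows = age groups, cols = `M`,`F`).
#' @examples
#' pop <- make_initial_population(1.243e9, seed = 1)
#' sum(pop)            # 1.243e9
#' @export
make_initial_population <- function(total = 1.243e9, seed = 1L) {
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0)
    stop("`total` must be a single positive number", call. = FALSE)
  mid <- group_midpoints()
  # Gentle decline with age, extra attrition past 65.
  base <- exp(-0.025 * mid) * exp(-pmax(mid - 65, 0) * 0.035)
  jitter <- with_seed(seed, exp(rnorm(N_GROUPS, sd = 0.03)))
  shape <- base * jitter
  # Male share: ~SRB-driven excess young, female survival advantage old.
  male_share <- 0.517 - pmax(mid - 50, 0) / 52.5 * 0.10
  w <- cbind(M = shape * male_share, F = shape * (1 - male_share))
  pop <- w / sum(w) * total
  dimnames(pop) <- dimnames(empty_pop())
  pop
}

#' Generate a synthetic age-sex mortality schedule
#'
#' Annual death probability per age group and sex: a small background hazard
#' plus a Gompertz (exponential-in-age) term, females below males, strictly
#' increasing with age. `level` scales the whole schedule; probabilities are
#' clipped at 1 (with a warning) if the level pushes them past it.
#'
#' @param level Non-negative multiplier on the schedule; `level = 0` gives an
#'   all-zero schedule.
#' @param seed Integer RNG seed for the small multiplicative jitter.
#' @return A 21 x 2 matrix of probabilities in \[0, 1\].
#' @export
make_mortality_schedule <- function(level = 1, seed = 1L) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) || level < 0)
    stop("`level` must be a single non-negative number", call. = FALSE)
  mid <- group_midpoints()
  gomp <- cbind(M = 6.0e-5 * exp(0.085 * mid),
                F = 4.2e-5 * exp(0.085 * mid))
  base <- 0.002 + gomp
  jitter <- with_seed(seed, exp(rnorm(N_GROUPS, sd = 0.01)))
  m <- level * base * jitter
  if (any(m > 1)) {
    warning("mortality level clips some probabilities at 1", call. = FALSE)
    m <- pmin(m, 1)
  }
  dimnames(m) <- dimnames(empty_pop())
  m
}

#' Fertility shape over the childbearing age groups
#'
#' Seven non-negative weights over age groups 4-10 (ages 15-49.99) summing to
#' one, peaked at group 6 (ages 25-29.99): a near-triangular schedule with a
#' thinner late-30s/40s tail.
#'
#' @return Named numeric vector of length 7 summing to 1.
#' @export
make_fertility_shape <- function() {
  w <- c(0.10, 0.22, 0.28, 0.22, 0.10, 0.05, 0.03)
  names(w) <- as.character(FERTILE_GROUPS)
  w
}

#' Bundle a demographic profile
#'
#' Everything the population projection consumes: initial array, mortality
#' schedule, fertility shape and sex ratio at birth. Invariants (non-negative
#' populations, shape summing to 1, mortality rising over the last five
#' groups) are checked at construction.
#'
#' @param total Initial total population, persons.
#' @param mortality_level Multiplier on the synthetic mortality schedule.
#' @param srb Sex ratio at birth, male births per female birth (default 1.07).
#' @param seed Integer RNG seed shared by the generators.
#' @return An object of class `demographic_profile`.
#' @export
demographic_profile <- function(total = 1.243e9, mortality_level = 1,
                                srb = 1.07, seed = 1L) {
  if (!is.numeric(srb) || srb <= 0) stop("`srb` must be positive", call. = FALSE)
  prof <- structure(list(
    initial_population = make_initial_population(total, seed),
    mortality = make_mortality_schedule(mortality_level, seed),
    fertility_shape = make_fertility_shape(),
    sex_ratio_at_birth = srb,
    seed = as.integer(seed)
  ), class = "demographic_profile")
  validate_demographic_profile(prof)
}

#' @rdname demographic_profile
#' @param x A `demographic_profile`.
#' @export
validate_demographic_profile <- function(x) {
  check_agesex(x$initial_population, "initial_population")
  check_agesex(x$mortality, "mortality", max = 1)
  if (abs(sum(x$fertility_shape) - 1) > 1e-8)
    stop("fertility_shape must sum to 1", call. = FALSE)
  if (any(x$fertility_shape < 0))
    stop("fertility_shape must be non-negative", call. = FALSE)
  last5 <- (N_GROUPS - 4L):N_GROUPS
  for (s in SEXES)
    if (x$mortality[N_GROUPS, s] > 0 && any(diff(x$mortality[last5, s]) <= 0))
      stop("mortality must rise strictly over the last five age groups",
           call. = FALSE)
  if (x$sex_ratio_at_birth <= 0)
    stop("sex_ratio_at_birth must be positive", call. = FALSE)
  invisible(x)
}

#' @export
print.demographic_profile <- function(x, ...) {
  cat("Demographic profile (synthetic, seed ", x$seed, ")\n", sep = "")
  cat("  initial population:", format(sum(x$initial_population), big.mark = ","),
      "persons\n")
  cat("  crude mortality at terminal group:",
      signif(x$mortality[N_GROUPS, "M"], 3), "(M)",
      signif(x$mortality[N_GROUPS, "F"], 3), "(F)\n")
  cat("  sex ratio at birth:", x$sex_ratio_at_birth, "\n")
  invisible(x)
}

#' Generate the per-capita health-expenditure index by age and sex
#'
#' A J-shaped dimensionless expenditure profile over the 42 age-sex cells:
#' elevated in infancy (males above females in group 1), a maternity bump for
#' females in groups 5-7 (ages 20-34.99), a steep rise through late adulthood
#' peaking at group 16 (ages 75-79.99) for males and group 17 (80-84.99) for
#' females, then tapering. The profile is normalised so its population-
#' weighted mean over `pop` equals 1, making the per-unit calibration scalar
#' interpretable as base-year per-capita expenditure.
#'
#' @param seed Integer RNG seed for the small multiplicative jitter.
#' @param pop Population used for the mean-1 normalisation; defaults to the
#'   synthetic year-2000 array built with the same seed.
#' @return An object of class `he_index_profile`: a 21 x 2 positive matrix.
#' @export
make_he_index_profile <- function(seed = 1L, pop = NULL) {
  if (is.null(pop)) pop <- make_initial_population(seed = seed)
  check_agesex(pop, "pop")
  base_m <- c(1.40, 0.50, 0.45, 0.55, 0.65, 0.70, 0.75, 0.85, 1.00, 1.20,
              1.50, 1.90, 2.50, 3.30, 4.20, 5.00, 4.60, 4.00, 3.30, 2.60, 2.00)
  base_f <- c(1.10, 0.45, 0.42, 0.60, 1.00, 1.10, 1.05, 0.85, 0.95, 1.10,
              1.35, 1.70, 2.20, 2.90, 3.70, 4.40, 4.80, 4.20, 3.50, 2.80, 2.10)
  # sd kept well under the log-gap between each sex's peak group and its
  # runner-up, so the profile maxima stay at groups 16 (M) / 17 (F)
  jitter <- with_seed(seed, matrix(exp(rnorm(2L * N_GROUPS, sd = 0.01)),
                                   nrow = N_GROUPS))
  idx <- cbind(M = base_m, F = base_f) * jitter
  idx <- idx / (sum(idx * pop) / sum(pop))  # population-weighted mean = 1
  dimnames(idx) <- dimnames(empty_pop())
  validate_he_index_profile(structure(idx, class = c("he_index_profile", "matrix")))
}

#' @rdname make_he_index_profile
#' @param x An `he_index_profile`.
#' @export
validate_he_index_profile <- function(x) {
  check_agesex(unclass(x), "he_index_profile")
  if (any(x <= 0)) stop("expenditure index must be positive", call. = FALSE)
  if (x[1L, "M"] <= x[1L, "F"])
    stop("male infant index must exceed the female one", call. = FALSE)
  if (any(x[5:7, "F"] <= x[5:7, "M"]))
    stop("female index must exceed male at groups 5-7 (maternity)", call. = FALSE)
  if (which.max(x[, "M"]) != 16L || which.max(x[, "F"]) != 17L)
    stop("profile maxima must sit at group 16 (M) and 17 (F)", call. = FALSE)
  invisible(x)
}

#' Workforce participation schedule for a retirement scenario
#'
#' Participation fraction per age group and sex, constant over the covered
#' years. Scenario 0 is the normal-retirement baseline (participation winds
#' down through group 12, ages 55-59.99); scenario 1 (delayed retirement)
#' raises participation at groups 12-13; scenario 2 (maximum delay) raises it
#' further and extends into group 14. Rates are weakly ordered across
#' scenarios at groups >= 12.
#'
#' @param scenario_id 0, 1 or 2.
#' @param years Years the schedule covers (default 2000:2060).
#' @return An object of class `participation_profile` with fields `rates`
#'   (21 x 2 matrix in \[0,1\]), `scenario_id`, `years`.
#' @export
make_participation_profile <- function(scenario_id = 0L, years = 2000:2060) {
  if (!is.numeric(scenario_id) || length(scenario_id) != 1L ||
      !scenario_id %in% 0:2)
    stop("`scenario_id` must be 0, 1 or 2", call. = FALSE)
  scenario_id <- as.integer(scenario_id)
  rates <- empty_pop()
  # Working-age core, groups 4-11 (ages 15-54.99).
  rates[4L, ]    <- c(0.35, 0.32)     # many still in education
  rates[5L, ]    <- c(0.78, 0.68)
  rates[6:10, ]  <- rep(c(0.88, 0.72), each = 5L)
  rates[11L, ]   <- c(0.84, 0.66)
  late <- switch(as.character(scenario_id),
    "0" = rbind("12" = c(0.68, 0.50), "13" = c(0.12, 0.06), "14" = c(0.00, 0.00)),
    "1" = rbind("12" = c(0.78, 0.62), "13" = c(0.45, 0.34), "14" = c(0.05, 0.02)),
    "2" = rbind("12" = c(0.85, 0.70), "13" = c(0.66, 0.55), "14" = c(0.25, 0.15)))
  rates[12:14, ] <- late
  structure(list(rates = rates, scenario_id = scenario_id, years = years),
            class = "participation_profile")
}

#' Write a 21 x 2 profile to CSV
#'
#' Long format with columns `group_index` (1-21), `sex` (M/F), `value`, the
#' interchange layout used for all age-sex schedules.
#'
#' @param x A 21 x 2 matrix (population, mortality, expenditure index or
#'   participation rates).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "participation_profile")) x <- x$rates
  check_agesex(unclass(x), "profile")
  df <- data.frame(group_index = rep(seq_len(N_GROUPS), 2L),
                   sex = rep(SEXES, each = N_GROUPS),
                   value = c(x[, "M"], x[, "F"]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group_index", "sex", "value") %in% names(df)))
  out <- empty_pop()
  out[cbind(df$group_index, match(df$sex, SEXES))] <- df$value
  out
}
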