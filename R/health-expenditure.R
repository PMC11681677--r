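# Total health expenditure model. The core identity multiplies four factors:
#   THE(t) = per-unit index * THE index(t) * demand index(t) * cost index(t)
# where the THE index aggregates population weighted by the age-sex
# expenditure profile, and demand/cost are compounding stocks. An efficiency
# divisor, itself a compounding stock switched on in 2021, deflates THE.

#' Health-expenditure model parameters
#'
#' @param price_basis `"constant_2015_usd"` or `"current_cny"`. The constant
#'   basis pairs a 5% annual cost growth with a 2000 anchor of 0.127e12 USD
#'   (consistent with $102 per capita across 1.243e9 persons); the current
#'   basis uses 8% cost growth (absorbing inflation) anchored at 458.7e9 CNY.
#' @param the_anchor_2000 Total health expenditure in 2000 in the chosen
#'   basis; defaults as above.
#' @param demand_growth_rate Annual health-demand growth (default 3%).
#' @param cost_growth_rate Annual facility and pharmaceutical cost growth;
#'   default depends on the basis.
#' @param efficiency_schedule Function of the calendar year returning the
#'   annual efficiency gain (fraction in \[0, 0.05\]); the default returns 3%
#'   for 2021-2040, 4% for 2041-2060 and 0 elsewhere.
#' @param efficiency_form `"divisor"` (deflate by the compounded `1 + e`
#'   index, the default) or `"multiplier"` (multiply by compounded `1 - e`).
#' @return An object of class `he_params`.
#' @export
he_params <- function(price_basis = c("constant_2015_usd", "current_cny"),
                      the_anchor_2000 = NULL,
                      demand_growth_rate = 0.03,
                      cost_growth_rate = NULL,
                      efficiency_schedule = default_efficiency_schedule(),
                      efficiency_form = c("divisor", "multiplier")) {
  price_basis <- match.arg(price_basis)
  efficiency_form <- match.arg(efficiency_form)
  if (is.null(the_anchor_2000))
    the_anchor_2000 <- if (price_basis == "constant_2015_usd") 0.127e12 else 458.7e9
  if (is.null(cost_growth_rate))
    cost_growth_rate <- if (price_basis == "constant_2015_usd") 0.05 else 0.08
  if (the_anchor_2000 <= 0) stop("`the_anchor_2000` must be positive", call. = FALSE)
  if (demand_growth_rate < 0 || cost_growth_rate < 0)
    stop("growth rates must be non-negative", call. = FALSE)
  structure(list(price_basis = price_basis,
                 the_anchor_2000 = the_anchor_2000,
                 demand_growth_rate = demand_growth_rate,
                 cost_growth_rate = cost_growth_rate,
                 efficiency_schedule = efficiency_schedule,
                 efficiency_form = efficiency_form),
            class = "he_params")
}

#' Stepped efficiency schedule
#'
#' @param rate_2021_2040 Annual efficiency gain over 2021-2040 (default 3%).
#' @param rate_2041_2060 Annual efficiency gain over 2041-2060 (default 4%).
#' @return A function of the calendar year returning the gain (0 outside
#'   2021-2060).
#' @export
default_efficiency_schedule <- function(rate_2021_2040 = 0.03,
                                        rate_2041_2060 = 0.04) {
  for (r in c(rate_2021_2040, rate_2041_2060))
    if (r < 0 || r > 0.05)
      stop("efficiency rates must lie in [0, 0.05]", call. = FALSE)
  function(year) {
    if (year >= 2021 && year <= 2040) rate_2021_2040
    else if (year >= 2041 && year <= 2060) rate_2041_2060
    else 0
  }
}

#' Health-expenditure grouping index
#'
#' Elementwise product of the population array and the per-capita
#' expenditure index profile: one dimensionless value per age-sex cell.
#'
#' @param pop 21 x 2 population matrix.
#' @param profile An [make_he_index_profile()] object (21 x 2 positive matrix).
#' @return 21 x 2 matrix of grouping-index values.
#' @export
grouping_index <- function(pop, profile) {
  check_agesex(pop, "pop")
  check_agesex(unclass(profile), "profile")
  pop * unclass(profile)
}

#' Total health-expenditure index
#'
#' Cumulative sum of all 42 grouping-index cells; tracks the pure demographic
#' pressure on expenditure (size and age structure), with demand and cost
#' growth factored out.
#'
#' @param gi A grouping-index matrix from [grouping_index()].
#' @return A single dimensionless value.
#' @export
total_he_index <- function(gi) sum(gi)

#' Per-unit calibration scalar
#'
#' Converts the dimensionless total index into currency: base-year total
#' expenditure divided by the base-year index. Held constant over the run.
#'
#' @param anchor Total health expenditure in the base year (currency).
#' @param index_2000 Total index in the base year; must be positive.
#' @return Currency per index unit.
#' @export
per_unit_index <- function(anchor, index_2000) {
  if (index_2000 <= 0) stop("base-year index must be positive", call. = FALSE)
  anchor / index_2000
}

#' The four-factor expenditure identity
#'
#' @param pui Per-unit calibration scalar (currency per index unit).
#' @param the_index Total expenditure index at the year.
#' @param demand_index Compounded health-demand index (1 in the base year).
#' @param cost_index Compounded cost index (1 in the base year).
#' @return Total health expenditure, currency per year.
#' @export
total_health_expenditure <- function(pui, the_index, demand_index = 1,
                                     cost_index = 1) {
  if (any(c(pui, the_index, demand_index, cost_index) <= 0))
    stop("all factors must be positive", call. = FALSE)
  pui * the_index * demand_index * cost_index
}

#' Efficiency divisor at a year
#'
#' The compounded efficiency index: 1 through 2020, then the product of
#' `1 + e(y)` over 2021..year (or of `1/(1 - e(y))` under the multiplier
#' form, so that division by the index always deflates).
#'
#' @param schedule Function of the year returning the efficiency gain.
#' @param year Calendar year.
#' @param form `"divisor"` or `"multiplier"`; see [he_params()].
#' @return Dimensionless divisor >= 1 for non-negative gains.
#' @export
efficiency_divisor <- function(schedule, year, form = "divisor") {
  if (year <= 2020) return(1)
  yrs <- 2021:year
  e <- vapply(yrs, schedule, numeric(1L))
  if (any(e < 0)) stop("efficiency gains must be non-negative", call. = FALSE)
  if (form == "divisor") prod(1 + e) else prod(1 / (1 - e))
}

#' Apply the efficiency adjustment
#'
#' @param the_raw Unadjusted total health expenditure, currency per year.
#' @param schedule Efficiency-gain schedule (function of year).
#' @param year Calendar year.
#' @param form `"divisor"` or `"multiplier"`.
#' @return Adjusted expenditure `the_raw / D(year)`.
#' @export
apply_efficiency <- function(the_raw, schedule, year, form = "divisor") {
  the_raw / efficiency_divisor(schedule, year, form)
}

#' Per-capita expenditure
#'
#' @param the Total health expenditure, currency per year.
#' @param pop_total Total population, persons; must be positive.
#' @return Currency per person per year.
#' @export
per_capita <- function(the, pop_total) {
  if (pop_total <= 0) stop("population must be positive", call. = FALSE)
  the / pop_total
}

#' Expenditure share of GDP
#'
#' @param the Total health expenditure, currency per year.
#' @param gdp GDP in the same price basis, currency per year; positive.
#' @return Percentage `100 * the / gdp`.
#' @export
the_to_gdp <- function(the, gdp) {
  if (gdp <= 0) stop("GDP must be positive", call. = FALSE)
  100 * the / gdp
}
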