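# Workforce and GDP: participation-weighted population, a regime-switching
# productivity index, and the three-factor GDP identity
#   GDP = workforce * initial GDP per worker * productivity index.

#' Workforce implied by a population and participation schedule
#'
#' Sum over all 42 age-sex cells of population times participation rate.
#'
#' @param pop 21 x 2 population matrix, persons.
#' @param participation A [make_participation_profile()] object.
#' @param year Calendar year; must lie in the profile's covered range.
#' @return Workforce in persons, between 0 and the total population.
#' @export
workforce <- function(pop, participation, year = 2000L) {
  stopifnot(inherits(participation, "participation_profile"))
  check_agesex(pop, "pop")
  check_year(year, participation$years, "workforce year")
  sum(pop * participation$rates)
}

#' Compound an annual-rate schedule into a growth factor
#'
#' The value of a unit stock grown by `rate(y)` during each year `y` in
#' `[from, to)`: the product of `1 + rate(y)`. For a constant rate this is
#' the closed form `(1 + r)^(to - from)`.
#'
#' @param rate A single rate, or a function of the calendar year returning
#'   the annual growth fraction for that year.
#' @param from,to Calendar years, `to >= from`.
#' @return Dimensionless growth factor (1 when `to == from`).
#' @examples
#' compound(0.09, 2000, 2019)       # 1.09^19
#' @export
compound <- function(rate, from, to) {
  if (to < from) stop("`to` must not precede `from`", call. = FALSE)
  if (to == from) return(1)
  yrs <- seq.int(from, to - 1L)
  r <- if (is.function(rate)) vapply(yrs, rate, numeric(1L)) else rep(rate, length(yrs))
  if (any(r <= -1)) stop("growth rates must exceed -1", call. = FALSE)
  prod(1 + r)
}

#' Economy parameters
#'
#' @param initial_gdp_per_workforce Base-year GDP per worker (currency per
#'   person per year). The default, 2000, puts base-year GDP of a
#'   China-scale synthetic workforce at order 1e12 USD.
#' @param productivity_rate_pre Annual productivity growth before the regime
#'   switch (default 9%).
#' @param productivity_rate_post Annual productivity growth from the switch
#'   year on (default 5%); the exposed slider covers 1-9%.
#' @param regime_switch_year First year the post-switch rate applies
#'   (default 2020).
#' @return An object of class `economy_params`.
#' @export
economy_params <- function(initial_gdp_per_workforce = 2000,
                           productivity_rate_pre = 0.09,
                           productivity_rate_post = 0.05,
                           regime_switch_year = 2020L) {
  if (initial_gdp_per_workforce <= 0)
    stop("`initial_gdp_per_workforce` must be positive", call. = FALSE)
  for (r in c(productivity_rate_pre, productivity_rate_post))
    if (r < 0.01 || r > 0.09)
      stop("productivity rates must lie in [0.01, 0.09]", call. = FALSE)
  structure(list(initial_gdp_per_workforce = initial_gdp_per_workforce,
                 productivity_rate_pre = productivity_rate_pre,
                 productivity_rate_post = productivity_rate_post,
                 regime_switch_year = as.integer(regime_switch_year)),
            class = "economy_params")
}

#' Productivity index at a year
#'
#' Unit value at `base_year`, compounded at the pre-switch rate through the
#' year before `regime_switch_year` and at the post-switch rate thereafter.
#'
#' @param params An [economy_params()] object.
#' @param year Calendar year (>= `base_year`).
#' @param base_year Year at which the index equals 1.
#' @return Dimensionless index value.
#' @export
productivity_index <- function(params, year, base_year = 2000L) {
  stopifnot(inherits(params, "economy_params"))
  rate_fn <- function(y)
    if (y < params$regime_switch_year) params$productivity_rate_pre
    else params$productivity_rate_post
  compound(rate_fn, base_year, year)
}

#' GDP identity
#'
#' @param wf Workforce, persons.
#' @param params An [economy_params()] object.
#' @param index_value Productivity index (dimensionless).
#' @return GDP in currency per year: the exact three-factor product.
#' @export
gdp <- function(wf, params, index_value) {
  stopifnot(inherits(params, "economy_params"))
  if (wf < 0 || index_value <= 0) stop("inputs must be positive", call. = FALSE)
  wf * params$initial_gdp_per_workforce * index_value
}

#' Annualised (geometric mean) growth rate
#'
#' @param v_start,v_end Positive start and end values.
#' @param n_years Number of years between them (>= 1).
#' @return Annual growth fraction `(v_end / v_start)^(1/n_years) - 1`.
#' @export
annualized_growth <- function(v_start, v_end, n_years) {
  if (v_start <= 0 || v_end <= 0) stop("values must be positive", call. = FALSE)
  if (n_years < 1) stop("`n_years` must be at least 1", call. = FALSE)
  (v_end / v_start)^(1 / n_years) - 1
}
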