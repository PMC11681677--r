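# Shared constants and small helpers.

# 21 five-year age groups: group g spans [5(g-1), 5g) years; group 21 open-ended.
N_GROUPS <- 21L
SEXES <- c("M", "F")
# Childbearing groups 4-10 cover ages 15-49.99.
FERTILE_GROUPS <- 4:10
# Groups 14-21 cover ages 65+.
ELDERLY_GROUPS <- 14:21

#' Age-group midpoints in years
#'
#' Midpoint age of each of the 21 five-year groups; the open-ended terminal
#' group is assigned a nominal midpoint of 102.5 years.
#' @return Numeric vector of length 21.
#' @keywords internal
group_midpoints <- function() {
  c(5 * (seq_len(N_GROUPS - 1L) - 1L) + 2.5, 102.5)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Empty 21 x 2 matrix with the canonical dimnames.
empty_pop <- function() {
  matrix(0, nrow = N_GROUPS, ncol = 2L,
         dimnames = list(group = as.character(seq_len(N_GROUPS)), sex = SEXES))
}

# Validate a 21 x 2 age-sex array of non-negative counts or rates.
check_agesex <- function(x, what = "age-sex array", max = Inf) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != N_GROUPS || ncol(x) != 2L)
    stop(what, " must be a numeric ", N_GROUPS, " x 2 matrix (42 cells)",
         call. = FALSE)
  if (anyNA(x)) stop(what, " contains NA", call. = FALSE)
  if (any(x < 0)) stop(what, " has negative entries", call. = FALSE)
  if (any(x > max)) stop(what, " exceeds ", max, call. = FALSE)
  invisible(x)
}

#' Round to the nearest hundred
#'
#' Report rounding used for per-capita expenditure in scenario comparison
#' tables.
#' @param x Numeric vector.
#' @return `x` rounded to the nearest 100.
#' @export
round_hundred <- function(x) round(x / 100) * 100

# Geometric-mean annual growth between two positive values n_years apart.
check_year <- function(year, years, what = "year") {
  if (!all(year %in% years))
    stop(what, " ", paste(setdiff(year, years), collapse = ", "),
         " outside the covered range [", min(years), ", ", max(years), "]",
         call. = FALSE)
  invisible(year)
}
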