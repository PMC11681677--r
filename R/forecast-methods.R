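# Methods for the sd_forecast result object.

#' @export
print.sd_forecast <- function(x, ...) {
  s <- x$series
  last <- s[nrow(s), ]
  first <- s[1L, ]
  cat("System-dynamics health expenditure forecast\n")
  print(x$config)
  cat(sprintf("  population: %.3f -> %.3f billion; 65+ share %.1f%% -> %.1f%%\n",
              first$population / 1e9, last$population / 1e9,
              first$pct_65plus, last$pct_65plus))
  cat(sprintf("  THE: %.2f -> %.1f trillion (raw), %.1f trillion adjusted\n",
              first$the_raw / 1e12, last$the_raw / 1e12,
              last$the_adjusted / 1e12))
  cat(sprintf("  per-capita HE %.0f -> %.0f; THE/GDP %.2f%% -> %.2f%%\n",
              first$he_pc, last$he_pc, first$the_to_gdp_pct,
              last$the_to_gdp_pct))
  invisible(x)
}

#' @export
as.data.frame.sd_forecast <- function(x, ...) x$series

#' Key indicators of a scenario run
#'
#' @param object An `sd_forecast`.
#' @param years Years to report (default first, switch and last).
#' @param ... Unused.
#' @return Data frame slice of the per-year series.
#' @export
summary.sd_forecast <- function(object, years = NULL, ...) {
  s <- object$series
  if (is.null(years))
    years <- unique(c(s$year[1L], object$config$switch_year,
                      s$year[nrow(s)]))
  check_year(years, s$year)
  s[s$year %in% years,
    c("year", "population", "pct_65plus", "workforce", "gdp", "the_raw",
      "the_adjusted", "he_pc", "the_to_gdp_pct")]
}

#' Plot a scenario run
#'
#' Four base-graphics panels: population and 65+ share, GDP, total health
#' expenditure (raw and efficiency-adjusted, log scale) and THE/GDP.
#'
#' @param x An `sd_forecast`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sd_forecast <- function(x, ...) {
  s <- x$series
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(s$year, s$population / 1e9, type = "l", xlab = "year",
       ylab = "population (billions)", main = "Population", ...)
  plot(s$year, s$gdp / 1e12, type = "l", xlab = "year",
       ylab = "GDP (trillions)", main = "GDP", ...)
  matplot(s$year, cbind(s$the_raw, s$the_adjusted) / 1e12, type = "l",
          lty = c(1, 2), col = 1, log = "y", xlab = "year",
          ylab = "THE (trillions, log)", main = "Total health expenditure")
  legend("topleft", c("raw", "efficiency-adjusted"), lty = c(1, 2), bty = "n")
  plot(s$year, s$the_to_gdp_pct, type = "l", xlab = "year",
       ylab = "THE/GDP (%)", main = "Expenditure share of GDP", ...)
  invisible(x)
}

#' Write a run to disk
#'
#' Writes the per-year series as CSV and the run manifest (config, seed,
#' version, input hash) as JSON, the pair needed to re-derive a published
#' table.
#'
#' @param result An `sd_forecast`.
#' @param dir Output directory (created if absent).
#' @param stem File stem (default `"run"`).
#' @return Invisibly, the two file paths.
#' @export
write_result <- function(result, dir, stem = "run") {
  stopifnot(inherits(result, "sd_forecast"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "-series.csv"))
  js <- file.path(dir, paste0(stem, "-manifest.json"))
  write.csv(result$series, csv, row.names = FALSE)
  jsonlite::write_json(result$manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(series = csv, manifest = js))
}
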