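#' Annual fortified-salt quantity
#'
#' Fortified-salt demand in metric tons for one calendar year:
#' `population x g/person/day x days/year x 1e-6 (g to MT) x compliance`.
#' The compliance fraction is the share of the fortifiable salt supply
#' actually fortified to the national standard.
#'
#' @param demand A [demand_params()].
#' @param year Calendar year (must be present in the population series).
#' @param fortified If `FALSE`, return the total fortifiable quantity
#'   (compliance not applied).
#' @return Metric tons of salt.
#' @examples
#' d <- demand_params(c("2024" = 1e8), 6.7, 0.89)
#' annual_fortified_salt_mt(d, 2024) # 217649.5
#' @export
annual_fortified_salt_mt <- function(demand, year, fortified = TRUE) {
  key <- as.character(year)
  if (!key %in% names(demand$population_by_year)) {
    stop(sprintf("demand: no population for year %s", key), call. = FALSE)
  }
  pop <- demand$population_by_year[[key]]
  mt <- pop * demand$per_capita_salt_g_per_day * demand$days_per_year * 1e-6
  if (fortified) mt * demand$compliance_fraction else mt
}

#' Demand series over a book's horizon
#'
#' @param book A `parameter_book`.
#' @return Data frame with `year`, `population`, `total_fortifiable_mt`,
#'   `fortified_mt`.
#' @export
demand_series <- function(book) {
  yrs <- book_years(book)
  data.frame(
    year = yrs,
    population = vapply(yrs, function(y) book$demand$population_by_year[[as.character(y)]],
                        numeric(1)),
    total_fortifiable_mt = vapply(yrs, function(y)
      annual_fortified_salt_mt(book$demand, y, fortified = FALSE), numeric(1)),
    fortified_mt = vapply(yrs, function(y)
      annual_fortified_salt_mt(book$demand, y), numeric(1))
  )
}

#' Write a book's demand series as CSV
#'
#' @param book A `parameter_book`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demand_csv <- function(book, path) {
  utils::write.csv(demand_series(book), path, row.names = FALSE)
  invisible(path)
}
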