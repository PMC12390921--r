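#' Monetary amount tagged with currency and year
#'
#' Cost inputs can be recorded in the currency and year they were observed
#' (historical USD or Ethiopian Birr) and normalized to base-year USD with
#' [to_base_usd()].
#'
#' @param value Non-negative amount.
#' @param currency `"USD"` or `"ETB"`.
#' @param year Calendar year the amount was observed in.
#' @return A `money_amount` object.
#' @examples
#' money_amount(1000, "USD", 2019)
#' @export
money_amount <- function(value, currency = c("USD", "ETB"), year) {
  currency <- match.arg(currency)
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("money_amount: `value` must be a single number", call. = FALSE)
  }
  if (value < 0) stop("money_amount: `value` must be >= 0", call. = FALSE)
  structure(
    list(value = as.numeric(value), currency = currency, year = as.integer(year)),
    class = "money_amount"
  )
}

#' @export
print.money_amount <- function(x, ...) {
  cat(sprintf("%.2f %s (%d)\n", x$value, x$currency, x$year))
  invisible(x)
}

# look up a year-indexed series (named numeric, names = years)
index_lookup <- function(index, year, what) {
  key <- as.character(year)
  if (is.null(index) || !key %in% names(index)) {
    stop(sprintf("finance: no %s index available for year %s", what, key),
         call. = FALSE)
  }
  v <- as.numeric(index[[key]])
  if (!is.finite(v) || v <= 0) {
    stop(sprintf("finance: %s index for year %s must be > 0", what, key),
         call. = FALSE)
  }
  v
}

#' Normalize a monetary amount to base-year USD
#'
#' USD amounts are re-expressed with the GDP implicit price deflator
#' (`deflator(base) / deflator(year)`); Birr amounts are first inflated to the
#' base year with the local consumer price index and then converted at the
#' base-year average exchange rate.
#'
#' @param amount A [money_amount()].
#' @param finance A `finance_params` block (see [finance_params()]).
#' @return Amount in base-year USD (a number).
#' @examples
#' fin <- finance_params(
#'   discount_rate = 0.03, equipment_life_years = 10, base_currency_year = 2021,
#'   usd_deflator_by_year = c("2019" = 100, "2021" = 105),
#'   etb_cpi_by_year = c("2021" = 100), etb_per_usd_base_year = 44
#' )
#' to_base_usd(money_amount(1000, "USD", 2019), fin) # 1050
#' to_base_usd(money_amount(4400, "ETB", 2021), fin) # 100
#' @export
to_base_usd <- function(amount, finance) {
  stopifnot(inherits(amount, "money_amount"))
  base <- finance$base_currency_year
  if (amount$currency == "USD") {
    if (amount$year == base) return(amount$value)
    d_base <- index_lookup(finance$usd_deflator_by_year, base, "USD deflator")
    d_year <- index_lookup(finance$usd_deflator_by_year, amount$year, "USD deflator")
    amount$value * d_base / d_year
  } else {
    cpi_base <- index_lookup(finance$etb_cpi_by_year, base, "ETB CPI")
    cpi_year <- index_lookup(finance$etb_cpi_by_year, amount$year, "ETB CPI")
    (amount$value * cpi_base / cpi_year) / finance$etb_per_usd_base_year
  }
}

#' Annuity factor
#'
#' Present value of a 1-per-year annuity over `life_years` at `rate`;
#' `life_years` when `rate` is zero.
#'
#' @param rate Discount rate (fraction per year), >= 0.
#' @param life_years Asset life in years, >= 1.
#' @return The annuity factor (years).
#' @export
annuity_factor <- function(rate, life_years) {
  stopifnot(is.numeric(rate), is.numeric(life_years))
  if (rate < 0) stop("annuity_factor: `rate` must be >= 0", call. = FALSE)
  if (life_years < 1) stop("annuity_factor: `life_years` must be >= 1", call. = FALSE)
  if (rate == 0) return(as.numeric(life_years))
  (1 - (1 + rate)^(-life_years)) / rate
}

#' Equivalent annual cost of a capital outlay
#'
#' The constant annual payment whose discounted sum over the asset's useful
#' life equals the capital cost: `capital * rate / (1 - (1 + rate)^-life)`
#' (straight-line `capital / life` in the zero-rate limit). This is the
#' standard annualization used for fortification equipment (3% discount rate,
#' 10-year useful life by default in the shipped parameter books).
#'
#' @param capital Capital cost in base-year USD, >= 0.
#' @inheritParams annuity_factor
#' @return Annual cost in USD/year.
#' @examples
#' equivalent_annual_cost(10000, 0.03, 10) # 1172.305
#' @export
equivalent_annual_cost <- function(capital, rate, life_years) {
  if (!is.numeric(capital) || capital < 0) {
    stop("equivalent_annual_cost: `capital` must be >= 0", call. = FALSE)
  }
  if (capital == 0) return(0)
  capital / annuity_factor(rate, life_years)
}
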