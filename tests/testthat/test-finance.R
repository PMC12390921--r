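fin <- finance_params(
  discount_rate = 0.03, equipment_life_years = 10, base_currency_year = 2021,
  usd_deflator_by_year = c("2019" = 100, "2020" = 102, "2021" = 105),
  etb_cpi_by_year = c("2019" = 184, "2021" = 281), etb_per_usd_base_year = 44
)

test_that("currency normalization follows the deflator/CPI/FX paths", {
  # identity at base year regardless of indices
  expect_equal(to_base_usd(money_amount(100, "USD", 2021), fin), 100)
  # USD path: value x deflator(base)/deflator(year)
  expect_equal(to_base_usd(money_amount(1000, "USD", 2019), fin), 1050)
  # ETB path: CPI-adjust then convert at base-year FX
  expect_equal(to_base_usd(money_amount(4400, "ETB", 2021), fin), 100)
  expect_equal(to_base_usd(money_amount(4400, "ETB", 2019), fin),
               4400 * 281 / 184 / 44)
  # missing index year is an explicit error naming the year
  expect_error(to_base_usd(money_amount(1, "USD", 2010), fin), "2010")
  expect_error(money_amount(-5, "USD", 2021), ">= 0")
})

test_that("currency adjustment is multiplicative-linear", {
  a <- to_base_usd(money_amount(123.4, "USD", 2019), fin)
  b <- to_base_usd(money_amount(876.6, "USD", 2019), fin)
  ab <- to_base_usd(money_amount(1000, "USD", 2019), fin)
  expect_equal(a + b, ab)
})

test_that("equivalent annual cost matches its NPV definition", {
  eac <- equivalent_annual_cost(10000, 0.03, 10)
  # oracle: discounting the annuity over the asset life recovers the capital
  expect_equal(sum(eac / 1.03^(1:10)), 10000, tolerance = 1e-12)
  expect_lt(abs(eac - 1172.31), 0.01)
  expect_identical(equivalent_annual_cost(0, 0.03, 10), 0)
  # zero-rate limit is straight-line depreciation
  expect_equal(equivalent_annual_cost(500, 0, 10), 50)
  expect_error(equivalent_annual_cost(-1, 0.03, 10))
  expect_error(equivalent_annual_cost(1, -0.01, 10))
  expect_error(equivalent_annual_cost(1, 0.03, 0.5))
})

test_that("EAC round-trips through NPV on randomized inputs", {
  set.seed(42)
  for (i in 1:50) {
    capital <- runif(1, 1, 1e7)
    rate <- runif(1, 0.001, 0.2)
    life <- sample(1:30, 1)
    eac <- equivalent_annual_cost(capital, rate, life)
    npv <- sum(eac / (1 + rate)^(1:life))
    expect_lt(abs(npv - capital) / capital, 1e-8)
  }
})

test_that("EAC is monotone increasing in rate and decreasing in life", {
  rates <- seq(0.005, 0.2, by = 0.005)
  eacs <- vapply(rates, function(r) equivalent_annual_cost(1e5, r, 10), numeric(1))
  expect_true(all(diff(eacs) > 0))
  lives <- 1:30
  eacs <- vapply(lives, function(l) equivalent_annual_cost(1e5, 0.03, l), numeric(1))
  expect_true(all(diff(eacs) < 0))
})
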