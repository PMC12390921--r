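test_that("compound mass per MT converts nutrient dose through the mass fraction", {
  expect_equal(compound_mass_per_mt(1000, 1), 1)
  # molar-mass oracle: KIO3 carries iodine at 126.90/214.00 of compound mass
  kio3 <- 126.90 / 214.00
  expect_lt(abs(compound_mass_per_mt(30, kio3) - 0.0506), 2e-4)
  expect_equal(compound_mass_per_mt(17.2, 1), 0.0172)
  expect_error(compound_mass_per_mt(30, 0), "> 0")
})

test_that("sprayed premix cost sums catalog-priced compound masses", {
  std <- fortification_standard("iodized", c(iodine = 30))
  cat20 <- data.frame(nutrient = "iodine", compound = "potassium iodate",
                      nutrient_mass_fraction = 0.5931, price_per_kg_compound = 20)
  spec <- premix_spec("iodine", catalog = cat20)
  expect_lt(abs(sprayed_premix_cost_per_mt(std, spec) - 1.012), 0.01)
  # linear in prices
  cat40 <- cat20; cat40$price_per_kg_compound <- 40
  spec2 <- premix_spec("iodine", catalog = cat40)
  expect_equal(sprayed_premix_cost_per_mt(std, spec2),
               2 * sprayed_premix_cost_per_mt(std, spec))
  # empty sprayed set costs nothing (and takes no shipping)
  spec0 <- premix_spec(character(), catalog = cat20)
  expect_identical(sprayed_premix_cost_per_mt(std, spec0), 0)
  # a sprayed nutrient without a catalog entry is an error naming it
  spec_fa <- premix_spec(c("iodine", "folic_acid"),
                         catalog = rbind(cat20, data.frame(
                           nutrient = "folic_acid", compound = "folic acid",
                           nutrient_mass_fraction = 1, price_per_kg_compound = 90)))
  spec_fa$catalog <- cat20
  std_dual <- fortification_standard("dual", c(iodine = 30, folic_acid = 17.2))
  expect_error(sprayed_premix_cost_per_mt(std_dual, spec_fa), "folic_acid")
})

test_that("extruded premix is inclusion rate times delivered price", {
  spec <- premix_spec("iodine", "folic_acid",
                      extruded_inclusion_rate_kg_per_mt = 10,
                      extruded_price_per_kg = 4)
  expect_equal(extruded_premix_cost_per_mt(spec), 40)
  spec0 <- premix_spec(c("iodine", "folic_acid"))
  expect_identical(extruded_premix_cost_per_mt(spec0), 0)
})

test_that("the shipping adder splits pro rata and never changes the total", {
  std <- fortification_standard("triple",
                                c(iodine = 30, folic_acid = 17.2, vitamin_b12 = 0.39))
  spec <- premix_spec("iodine", c("folic_acid", "vitamin_b12"),
                      extruded_inclusion_rate_kg_per_mt = 10,
                      extruded_price_per_kg = 5,
                      shipping_handling_per_mt_salt = 0.8)
  spec_noship <- spec
  spec_noship$shipping_handling_per_mt_salt <- 0
  sprayed_raw <- sprayed_premix_cost_per_mt(std, spec_noship)
  total <- sprayed_premix_cost_per_mt(std, spec) +
    extruded_premix_cost_per_mt(spec, sprayed_cost_per_mt = sprayed_raw)
  expect_equal(total, sprayed_raw + 50 + 0.8)
})

test_that("premix cost per MT is demand-invariant and annual cost is linear in demand", {
  book <- fx_books()[["ethiopia-s1-dual"]]
  rate <- premix_cost_per_mt(book)
  book2 <- book
  book2$demand$population_by_year <- book$demand$population_by_year * 2
  expect_equal(premix_cost_per_mt(book2), rate)
  expect_equal(annual_premix_cost(book2, 2030), 2 * annual_premix_cost(book, 2030))
})

test_that("expansion books cost iodine-only premix during phase-in years", {
  for (sc in c("s1", "s2")) {
    iod <- fx_books()[[sprintf("ethiopia-%s-iodized", sc)]]
    for (p in c("dual", "triple", "quad")) {
      exp_book <- fx_books()[[sprintf("ethiopia-%s-%s", sc, p)]]
      for (y in 2024:2025) {
        expect_equal(annual_premix_cost(exp_book, y), annual_premix_cost(iod, y))
      }
      expect_gt(annual_premix_cost(exp_book, 2026), annual_premix_cost(iod, 2026))
    }
  }
})

test_that("premix cost per MT is non-decreasing across nested programs", {
  for (sc in c("s1", "s2")) {
    rates <- vapply(program_ids(), function(p)
      premix_cost_per_mt(fx_books()[[sprintf("ethiopia-%s-%s", sc, p)]]), numeric(1))
    expect_true(all(diff(rates) >= 0))
  }
})

test_that("the fixture reproduces the published dual premix average", {
  book <- fx_books()[["ethiopia-s1-dual"]]
  avg <- mean(vapply(2024:2033, function(y) annual_premix_cost(book, y), numeric(1)))
  expect_lt(abs(avg - 1388000), 500)
})
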