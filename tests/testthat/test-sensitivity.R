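test_that("sensitivity spec rejects empty or out-of-range inputs", {
  expect_error(sensitivity_spec(character()), "non-empty")
  expect_error(sensitivity_spec(c("premix_price", "typo")), "unknown component")
  expect_error(sensitivity_spec(fraction = 0), "in \\(0, 1\\)")
  expect_error(sensitivity_spec(fraction = 1), "in \\(0, 1\\)")
})

test_that("one-way variation is symmetric and brackets the base (model linearity)", {
  res <- run_sensitivity(fx_books()[["ethiopia-s1-dual"]])
  ow <- res$one_way
  expect_identical(ow$component, sensitivity_components())
  expect_true(all(ow$low_per_mt <= ow$base_per_mt + 1e-12))
  expect_true(all(ow$base_per_mt <= ow$high_per_mt + 1e-12))
  expect_equal(ow$base_per_mt - ow$low_per_mt, ow$high_per_mt - ow$base_per_mt,
               tolerance = 1e-12)
  # combined extremes dominate every one-way excursion
  expect_true(all(res$best_case_per_mt <= ow$low_per_mt + 1e-12))
  expect_true(all(res$worst_case_per_mt >= ow$high_per_mt - 1e-12))
})

test_that("one-way swing equals fraction times the component's per-MT contribution", {
  book <- fx_books()[["ethiopia-s1-triple"]]
  r <- compute_report(book)
  premix_per_mt <- r$by_stakeholder$annual_average[
    r$by_stakeholder$group == "premix"] / r$mean_fortified_mt
  res <- run_sensitivity(book, sensitivity_spec("premix_price", fraction = 0.3))
  expect_equal(res$one_way$high_per_mt - res$one_way$base_per_mt,
               0.3 * premix_per_mt, tolerance = 1e-9)
})

test_that("worst minus best equals twice the fraction times the varied per-MT cost", {
  # brute-force oracle on a random small book: recompute each component's
  # per-MT contribution from the base report and compare with the full
  # re-run of the scaled engine
  for (seed in c(5, 23)) {
    book <- random_book(seed, 10)
    spec <- sensitivity_spec(fraction = 0.3)
    r <- compute_report(book)
    contrib_cat <- function(cats) {
      sum(r$by_activity$annual_average[r$by_activity$category %in% cats])
    }
    varied <- contrib_cat("premix") + contrib_cat("refinery_fortification") +
      contrib_cat(spec$monitoring_categories)
    res <- run_sensitivity(book, spec)
    expect_equal(res$worst_case_per_mt - res$best_case_per_mt,
                 2 * 0.3 * varied / r$mean_fortified_mt, tolerance = 1e-8)
  }
})

test_that("non-varied activities are bit-identical between base and varied runs", {
  book <- fx_books()[["ethiopia-s1-dual"]]
  scaled <- fortcost:::scale_component(book, "government_monitoring_cost", 1.3,
                                       c("gov_refinery_monitoring",
                                         "gov_import_monitoring",
                                         "gov_household_monitoring"))
  m0 <- compute_report(book)$per_year_by_activity
  m1 <- compute_report(scaled)$per_year_by_activity
  cats <- vapply(book$activities, function(a) a$category, character(1))
  untouched <- !(cats %in% c("gov_refinery_monitoring", "gov_import_monitoring",
                             "gov_household_monitoring"))
  expect_identical(m0[, untouched], m1[, untouched])
  # market monitoring is excluded from the monitoring component by default
  expect_identical(m0[, cats == "gov_market_monitoring"],
                   m1[, cats == "gov_market_monitoring"])
  expect_false(isTRUE(all.equal(m0[, cats == "gov_refinery_monitoring"],
                                m1[, cats == "gov_refinery_monitoring"])))
})

test_that("sensitivity CSV carries one-way rows plus the combined extremes", {
  withr::with_tempdir({
    res <- run_sensitivity(fx_books()[["ethiopia-s2-dual"]])
    write_sensitivity_csv(res, "sens.csv")
    got <- read.csv("sens.csv")
    expect_identical(got$component, c(sensitivity_components(), "combined"))
    expect_identical(names(got),
                     c("component", "low_per_mt", "base_per_mt", "high_per_mt"))
  })
})
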