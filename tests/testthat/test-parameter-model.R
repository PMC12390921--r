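shipped_book <- function(name) {
  path <- system.file("extdata", "ethiopia", name, package = "fortcost")
  expect_true(nzchar(path))
  load_parameter_book(path)
}

test_that("the shipped iodized book loads with 12 recurring and 0 startup activities", {
  b <- shipped_book("ethiopia-s1-iodized.yaml")
  phases <- vapply(b$activities, function(a) a$phase, character(1))
  expect_identical(sum(phases == "recurring"), 12L)
  expect_identical(sum(phases == "startup"), 0L)
  expect_identical(b$phase_in_years, 0L)
  # shipped files are exactly what the generator produces
  expect_equal(b, build_ethiopia_fixture()$books[["ethiopia-s1-iodized"]])
})

test_that("invariant violations raise one categorized error citing the field path", {
  good <- tiny_book()
  bad <- good
  bad$demand$compliance_fraction <- 1.2
  probs <- validate_parameter_book(bad)
  expect_length(probs, 1)
  expect_match(probs, "demand.compliance_fraction", fixed = TRUE)

  bad <- good
  bad$activities[[2]]$active_years <- c(bad$activities[[2]]$active_years, 2040L)
  probs <- validate_parameter_book(bad)
  expect_length(probs, 1)
  expect_match(probs, "activities.qaqc.active_years", fixed = TRUE)

  # loaders reject malformed books with a classed condition
  tmp <- withr::local_tempfile(fileext = ".yaml")
  save_parameter_book(good, tmp)
  raw <- yaml::read_yaml(tmp)
  raw$demand$compliance_fraction <- 1.2
  yaml::write_yaml(raw, tmp)
  expect_error(load_parameter_book(tmp), class = "fortcost_validation_error")
})

test_that("unknown nutrients and categories are rejected", {
  expect_error(fortification_standard("iodized", c(iodine = 30, iron = 2)),
               "unknown nutrient", class = "fortcost_validation_error")
  expect_error(
    activity_schedule("x", "x", "recurring", "industry", "not_a_category",
                      list(kind = "fixed_annual", amount = 1), 2024:2033),
    "category", class = "fortcost_validation_error")
  # cost rules are exclusive: exactly one of amount/rate, matching the kind
  expect_error(
    activity_schedule("x", "x", "recurring", "industry", "gov_admin",
                      list(kind = "fixed_annual", amount = 1, rate = 2), 2024:2033),
    class = "fortcost_validation_error")
  # capital only on startup or equipment activities
  expect_error(
    activity_schedule("x", "x", "recurring", "government", "gov_admin",
                      list(kind = "capital", amount = 1), 2024:2033),
    class = "fortcost_validation_error")
})

test_that("save/load round-trips books field-by-field", {
  withr::with_tempdir({
    for (b in list(tiny_book("triple"), fx_books()[["ethiopia-s2-quad"]],
                   random_book(11, 17))) {
      save_parameter_book(b, "book.yaml")
      expect_equal(load_parameter_book("book.yaml"), b)
    }
  })
})

test_that("program nesting report is empty for the fixture and flags breaks", {
  for (sc in c("s1", "s2")) {
    books <- fx_books()[sprintf("ethiopia-%s-%s", sc, program_ids())]
    expect_identical(validate_program_nesting(unname(books)), character(0))
  }
  books <- unname(fx_books()[sprintf("ethiopia-s1-%s", program_ids())])
  broken <- books
  broken[[2]]$program$concentrations[["folic_acid"]] <- 0
  expect_true(any(grepl("dual lacks folic_acid",
                        validate_program_nesting(broken))))
  broken <- books
  broken[[3]]$demand$population_by_year[1] <- 1
  disc <- validate_program_nesting(broken)
  expect_true(any(grepl("demand block differs", disc)))
})
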