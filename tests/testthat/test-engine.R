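test_that("activity cost rules evaluate per year as specified", {
  book <- fx_books()[["ethiopia-s1-iodized"]]
  qaqc <- Filter(function(a) a$activity_id == "refinery_qaqc", book$activities)[[1]]
  expect_equal(activity_cost_in_year(qaqc, book, 2029), 125000)

  # per-MT rule scales with the year's fortified-salt demand
  per_mt <- activity_schedule("haul", "Per-ton haulage", "recurring", "industry",
                              "refinery_fortification",
                              list(kind = "per_mt", rate = 2), 2024:2033)
  tb <- tiny_book(activities = list(
    activity_schedule("premix", "Premix", "recurring", "industry", "premix",
                      list(kind = "premix"), 2024:2033), per_mt))
  mt <- annual_fortified_salt_mt(tb$demand, 2024)
  expect_equal(activity_cost_in_year(per_mt, tb, 2024), 2 * mt)

  # fixed costs vanish outside active years
  late <- activity_schedule("late", "Late", "recurring", "government", "gov_admin",
                            list(kind = "fixed_annual", amount = 7), 2030:2033)
  expect_identical(activity_cost_in_year(late, book, 2024), 0)

  # capital is annualized over the whole horizon
  cap <- activity_schedule("blend", "Blender", "startup", "industry", "relabeling",
                           list(kind = "capital", amount = 8530.203), 2024:2025)
  dual <- fx_books()[["ethiopia-s1-dual"]]
  for (y in c(2024, 2029, 2033)) {
    expect_equal(activity_cost_in_year(cap, dual, y),
                 equivalent_annual_cost(8530.203, 0.03, 10))
  }
  expect_error(activity_cost_in_year(qaqc, book, 2040), "horizon")
})

test_that("per-year totals conserve the activity-level costs exactly", {
  for (id in names(fx_books())) {
    r <- fx_report(id)
    expect_equal(r$per_year_total, rowSums(r$per_year_by_activity))
    expect_equal(sum(r$by_activity$annual_average), r$annual_average_total,
                 tolerance = 1e-12)
    expect_equal(sum(r$by_stakeholder$annual_average), r$annual_average_total,
                 tolerance = 1e-12)
  }
})

test_that("phase-in years cost the baseline program plus annualized startup", {
  for (sc in c("s1", "s2")) {
    iod <- fx_report(sprintf("ethiopia-%s-iodized", sc))
    for (p in c("dual", "triple", "quad")) {
      r <- fx_report(sprintf("ethiopia-%s-%s", sc, p))
      book <- fx_books()[[sprintf("ethiopia-%s-%s", sc, p)]]
      startup_eac <- sum(vapply(
        Filter(function(a) a$phase == "startup", book$activities),
        function(a) equivalent_annual_cost(a$cost_rule$amount, 0.03, 10),
        numeric(1)))
      for (y in c("2024", "2025")) {
        expect_equal(r$per_year_total[[y]], iod$per_year_total[[y]] + startup_eac)
      }
    }
  }
})

test_that("scaling every monetary input by k scales every monetary output by k", {
  for (seed in c(3, 14)) {
    book <- random_book(seed, 15)
    r1 <- compute_report(book)
    r2 <- compute_report(scale_book_money(book, 2.5))
    expect_equal(r2$per_year_total, 2.5 * r1$per_year_total)
    expect_equal(r2$annual_average_total, 2.5 * r1$annual_average_total)
    expect_equal(r2$annual_average_per_mt, 2.5 * r1$annual_average_per_mt)
    # shares are scale-free
    expect_equal(r2$by_activity$share, r1$by_activity$share)
  }
})

test_that("program costs order monotonically within each scenario", {
  for (sc in c("s1", "s2")) {
    totals <- vapply(program_ids(), function(p)
      fx_report(sprintf("ethiopia-%s-%s", sc, p))$annual_average_total, numeric(1))
    expect_true(all(diff(totals) > 0))
  }
})

test_that("percent shares follow the round-down-below-half-percent rule", {
  acts <- list(
    activity_schedule("a", "a", "recurring", "industry", "refinery_qaqc",
                      list(kind = "fixed_annual", amount = 4), 2024:2033),
    activity_schedule("b", "b", "recurring", "industry", "refinery_admin",
                      list(kind = "fixed_annual", amount = 996), 2024:2033),
    activity_schedule("premix", "Premix", "recurring", "industry", "premix",
                      list(kind = "premix"), 2024:2033))
  book <- tiny_book(activities = acts)
  book$premix$catalog$price_per_kg_compound <- 0 # isolate the fixed activities
  r <- compute_report(book)
  sh <- setNames(r$by_activity$share_pct, r$by_activity$activity_id)
  expect_identical(sh[["a"]], 0)   # 0.4% rounds down to 0, not up to 1
  expect_identical(sh[["b"]], 100) # 99.6% rounds to 100
  # unrounded shares always sum to 100
  for (id in c("ethiopia-s1-iodized", "ethiopia-s1-triple")) {
    expect_equal(sum(fx_report(id)$by_activity$share), 100, tolerance = 1e-9)
  }
  # published share cells: premix 47% of the iodized and 91% of the triple program
  s1i <- fx_report("ethiopia-s1-iodized")
  expect_identical(s1i$by_stakeholder$share_pct[s1i$by_stakeholder$group == "premix"], 47)
  s1t <- fx_report("ethiopia-s1-triple")
  expect_identical(s1t$by_stakeholder$share_pct[s1t$by_stakeholder$group == "premix"], 91)
})

test_that("incremental blocks difference every metric against the baseline", {
  iod <- fx_report("ethiopia-s1-iodized")
  self <- compute_report(fx_books()[["ethiopia-s1-iodized"]], baseline = iod)
  expect_equal(self$incremental$annual_average_total, 0)
  expect_true(all(self$incremental$per_year_total == 0))
  expect_equal(self$incremental$annual_average_per_mt, 0)

  dual <- fx_report("ethiopia-s1-dual", incremental = TRUE)
  expect_equal(dual$incremental$annual_average_total,
               dual$annual_average_total - iod$annual_average_total)

  # horizon mismatch is rejected
  short <- tiny_book()
  short$horizon$end <- 2032L
  short$activities <- lapply(short$activities, function(a) {
    a$active_years <- 2024:2032; a })
  expect_error(compute_report(short, baseline = iod), "horizon")
})

test_that("report writers emit the long CSV and schema-versioned JSON", {
  withr::with_tempdir({
    r <- fx_report("ethiopia-s1-dual", incremental = TRUE)
    write_report_csv(r, "r.csv")
    long <- read.csv("r.csv")
    expect_identical(names(long), c("scenario", "program", "metric", "period", "value"))
    expect_true("incremental_annual_average_total" %in% long$metric)
    expect_identical(sum(long$metric == "total_cost"), 10L)
    write_report_json(r, "r.json")
    j <- jsonlite::read_json("r.json")
    expect_identical(j$schema, "fortcost-report/1")
    expect_equal(j$annual_average$total, r$annual_average_total)
  })
})

test_that("the comparison table lines up programs with incremental columns", {
  reports <- c(list(fx_report("ethiopia-s1-iodized")),
               lapply(c("dual", "triple", "quad"), function(p)
                 fx_report(sprintf("ethiopia-s1-%s", p), incremental = TRUE)))
  tab <- comparison_table(reports)
  expect_identical(names(tab), c("metric", program_ids()))
  row <- tab[tab$metric == "annual_average_total", ]
  expect_equal(unlist(row[-1], use.names = FALSE),
               c(2115000, 2531000, 18009000, 19014000))
  inc <- tab[tab$metric == "incremental_annual_average_total", ]
  expect_true(is.na(inc$iodized))
  expect_equal(inc$dual, 416000)
})
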