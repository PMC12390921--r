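# Build the Ethiopia fixture once per test run; reports are computed lazily
# and cached (incremental reports keyed by "<id>+inc").
.fx_env <- new.env(parent = emptyenv())

fx_books <- function() {
  if (is.null(.fx_env$fx)) .fx_env$fx <- build_ethiopia_fixture()
  .fx_env$fx$books
}

fx_manifest <- function() {
  if (is.null(.fx_env$fx)) .fx_env$fx <- build_ethiopia_fixture()
  .fx_env$fx$manifest
}

fx_report <- function(id, incremental = FALSE) {
  key <- if (incremental) paste0(id, "+inc") else id
  if (is.null(.fx_env$reports)) .fx_env$reports <- list()
  if (is.null(.fx_env$reports[[key]])) {
    books <- fx_books()
    baseline <- NULL
    if (incremental) {
      base_id <- books[[id]]$baseline_book_id
      baseline <- fx_report(base_id)
    }
    .fx_env$reports[[key]] <- compute_report(books[[id]], baseline = baseline)
  }
  .fx_env$reports[[key]]
}

# look up a golden-value metric in a computed report (see ethiopia_golden_values)
golden_metric <- function(report, metric) {
  if (metric == "annual_average_total") return(report$annual_average_total)
  if (metric == "incremental_annual_average_total") {
    return(report$incremental$annual_average_total)
  }
  if (startsWith(metric, "stakeholder.")) {
    g <- sub("stakeholder.", "", metric, fixed = TRUE)
    return(report$by_stakeholder$annual_average[report$by_stakeholder$group == g])
  }
  if (startsWith(metric, "share.")) {
    g <- sub("share.", "", metric, fixed = TRUE)
    return(report$by_stakeholder$share_pct[report$by_stakeholder$group == g])
  }
  parts <- strsplit(metric, ".", fixed = TRUE)[[1]]
  sum(report$by_activity$annual_average[report$by_activity$phase == parts[2] &
                                        report$by_activity$category == parts[3]])
}

# scale every monetary input of a book by k (for linearity properties)
scale_book_money <- function(book, k) {
  book$premix$catalog$price_per_kg_compound <-
    book$premix$catalog$price_per_kg_compound * k
  book$premix$extruded_price_per_kg <- book$premix$extruded_price_per_kg * k
  book$premix$shipping_handling_per_mt_salt <-
    book$premix$shipping_handling_per_mt_salt * k
  book$activities <- lapply(book$activities, function(a) {
    if (!is.null(a$cost_rule$amount)) a$cost_rule$amount <- a$cost_rule$amount * k
    if (!is.null(a$cost_rule$rate)) a$cost_rule$rate <- a$cost_rule$rate * k
    a
  })
  book
}

# a minimal hand-checkable book for unit tests
tiny_book <- function(program = "iodized", activities = NULL,
                      phase_in_years = if (program == "iodized") 0 else 2) {
  yrs <- 2024:2033
  if (is.null(activities)) {
    activities <- list(
      activity_schedule("premix", "Premix", "recurring", "industry", "premix",
                        list(kind = "premix"), yrs),
      activity_schedule("qaqc", "QA/QC", "recurring", "industry", "refinery_qaqc",
                        list(kind = "fixed_annual", amount = 100000), yrs)
    )
  }
  conc <- c(iodine = 30, folic_acid = 17.2, vitamin_b12 = 0.39,
            zinc = 600)[program_nutrients(program)]
  sprayed <- if (program %in% c("iodized", "dual")) program_nutrients(program) else "iodine"
  extruded <- setdiff(program_nutrients(program), sprayed)
  parameter_book(
    book_id = paste0("tiny-", program),
    program = fortification_standard(program, conc),
    demand = demand_params(stats::setNames(rep(1e8, 10), yrs), 6.7, 0.89),
    finance = finance_params(0.03, 10, 2021,
                             c("2019" = 100, "2021" = 105),
                             c("2021" = 100), 44),
    premix = premix_spec(
      sprayed_nutrients = sprayed, extruded_nutrients = extruded,
      extruded_inclusion_rate_kg_per_mt = if (length(extruded)) 10 else 0,
      extruded_price_per_kg = if (length(extruded)) 5 else 0
    ),
    activities = activities,
    horizon = list(start = 2024, end = 2033),
    phase_in_years = phase_in_years
  )
}
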