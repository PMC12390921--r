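# conventional (half-up) rounding, as used in the printed cost tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round to the reporting units of the cost tables
#'
#' Totals are reported to the nearest 1,000 USD and per-MT values to one
#' decimal; internal arithmetic is never rounded.
#'
#' @param x Numeric vector of USD amounts.
#' @return Rounded values.
#' @export
round_thousand <- function(x) round_half_up(x / 1000) * 1000

#' Cost of one activity in one year
#'
#' Applies the activity's cost rule:
#' * `fixed_annual`: the amount in each active year, 0 otherwise;
#' * `capital`: the equivalent annual cost of the lump sum (at the book's
#'   discount rate and equipment life) charged in every horizon year — capital
#'   outlays incurred during phase-in are annualized over the whole horizon;
#' * `per_mt`: rate x fortified-salt demand of the year, in active years;
#' * `premix`: delegated to [annual_premix_cost()], which uses the
#'   iodine-only baseline formulation during phase-in years.
#'
#' @param activity An [activity_schedule()].
#' @param book The `parameter_book` the activity belongs to.
#' @param year Calendar year within the horizon.
#' @return USD.
#' @export
activity_cost_in_year <- function(activity, book, year) {
  if (!year %in% book_years(book)) {
    stop(sprintf("engine: year %d outside horizon", year), call. = FALSE)
  }
  rule <- activity$cost_rule
  switch(rule$kind,
    fixed_annual = if (year %in% activity$active_years) rule$amount else 0,
    capital = equivalent_annual_cost(rule$amount, book$finance$discount_rate,
                                     book$finance$equipment_life_years),
    per_mt = if (year %in% activity$active_years) {
      rule$rate * annual_fortified_salt_mt(book$demand, year)
    } else 0,
    premix = annual_premix_cost(book, year),
    stop(sprintf("unknown cost rule '%s'", rule$kind), call. = FALSE)
  )
}

# years x activities cost matrix
activity_cost_matrix <- function(book) {
  yrs <- book_years(book)
  ids <- vapply(book$activities, function(a) a$activity_id, character(1))
  m <- matrix(0, nrow = length(yrs), ncol = length(ids),
              dimnames = list(as.character(yrs), ids))
  for (j in seq_along(book$activities)) {
    for (i in seq_along(yrs)) {
      m[i, j] <- activity_cost_in_year(book$activities[[j]], book, yrs[i])
    }
  }
  m
}

#' Compute the cost report for a parameter book
#'
#' Aggregates activity costs into per-year totals and 10-year annual-average
#' metrics. Annual averages are plain undiscounted means over the horizon
#' years (discounting enters only through the equivalent annual cost of
#' capital). Per-capita uses the mean population over the horizon; per-MT
#' uses the mean annual fortified-salt quantity (switchable to total
#' fortifiable salt via `per_mt_denominator`). When a baseline report is
#' supplied, an incremental block holds metric-wise differences.
#'
#' @param book A validated `parameter_book`.
#' @param baseline Optional `cost_report` of the comparator program over the
#'   same horizon.
#' @param per_mt_denominator `"fortified"` (demand after compliance; default)
#'   or `"fortifiable"` (before compliance).
#' @return A `cost_report` with per-year totals, annual-average total /
#'   per-capita / per-MT metrics, per-activity and per-stakeholder-group
#'   breakdowns with percent shares, and an optional incremental block.
#' @export
compute_report <- function(book, baseline = NULL,
                           per_mt_denominator = c("fortified", "fortifiable")) {
  per_mt_denominator <- match.arg(per_mt_denominator)
  yrs <- book_years(book)
  m <- activity_cost_matrix(book)
  per_year_total <- rowSums(m)
  avg_total <- mean(per_year_total)
  mean_pop <- mean(vapply(yrs, function(y)
    book$demand$population_by_year[[as.character(y)]], numeric(1)))
  mean_mt <- mean(vapply(yrs, function(y)
    annual_fortified_salt_mt(book$demand, y,
                             fortified = per_mt_denominator == "fortified"),
    numeric(1)))
  by_activity <- data.frame(
    activity_id = colnames(m),
    label = vapply(book$activities, function(a) a$label, character(1)),
    phase = vapply(book$activities, function(a) a$phase, character(1)),
    category = vapply(book$activities, function(a) a$category, character(1)),
    stakeholder = vapply(book$activities, function(a) a$stakeholder, character(1)),
    annual_average = colMeans(m),
    row.names = NULL, stringsAsFactors = FALSE
  )
  by_activity$group <- stakeholder_group(by_activity$category)
  groups <- c("premix", "refinery_related", "government_related")
  by_group <- data.frame(
    group = groups,
    annual_average = vapply(groups, function(g)
      sum(by_activity$annual_average[by_activity$group == g]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  premix_avg <- by_group$annual_average[by_group$group == "premix"]
  report <- structure(list(
    book_id = book$book_id,
    program_id = book$program$program_id,
    scenario = book$scenario,
    horizon = book$horizon,
    per_mt_denominator = per_mt_denominator,
    mean_population = mean_pop,
    mean_fortified_mt = mean_mt,
    per_year_total = per_year_total,
    per_year_by_activity = m,
    annual_average_total = avg_total,
    annual_average_per_capita = avg_total / mean_pop,
    annual_average_per_mt = avg_total / mean_mt,
    annual_average_premix_per_mt = premix_avg / mean_mt,
    by_activity = by_activity,
    by_stakeholder = by_group,
    incremental = NULL
  ), class = "cost_report")
  report <- percent_shares(report)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "cost_report"))
    if (!identical(unlist(baseline$horizon), unlist(book$horizon))) {
      stop("compute_report: baseline horizon differs from the book's horizon",
           call. = FALSE)
    }
    report$incremental <- list(
      baseline_book_id = baseline$book_id,
      per_year_total = per_year_total - baseline$per_year_total,
      annual_average_total = avg_total - baseline$annual_average_total,
      annual_average_per_capita =
        report$annual_average_per_capita - baseline$annual_average_per_capita,
      annual_average_per_mt =
        report$annual_average_per_mt - baseline$annual_average_per_mt,
      annual_average_premix_per_mt =
        report$annual_average_premix_per_mt - baseline$annual_average_premix_per_mt,
      by_stakeholder = data.frame(
        group = by_group$group,
        annual_average = by_group$annual_average - baseline$by_stakeholder$annual_average,
        row.names = NULL, stringsAsFactors = FALSE
      )
    )
  }
  report
}

#' Percent-of-total shares with the tables' rounding rule
#'
#' Shares are `100 x component / total` computed before any rounding; the
#' rounded column then rounds to the nearest whole percent, except that
#' values below 0.5% round down to 0.
#'
#' @param report A `cost_report`.
#' @return The report with `share` (unrounded) and `share_pct` (rounded)
#'   columns on the per-activity and per-stakeholder tables.
#' @export
percent_shares <- function(report) {
  total <- report$annual_average_total
  if (!is.finite(total) || total <= 0) {
    stop("percent_shares: annual average total must be > 0", call. = FALSE)
  }
  add_shares <- function(df) {
    df$share <- 100 * df$annual_average / total
    df$share_pct <- ifelse(df$share < 0.5, 0, round_half_up(df$share))
    df
  }
  report$by_activity <- add_shares(report$by_activity)
  report$by_stakeholder <- add_shares(report$by_stakeholder)
  report
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s (%s, %s), horizon %d-%d\n",
              x$book_id, x$program_id, x$scenario, x$horizon$start, x$horizon$end))
  cat(sprintf("  annual average total cost : %s USD\n",
              format(round_thousand(x$annual_average_total), big.mark = ",",
                     scientific = FALSE)))
  cat(sprintf("  per capita                : %.3f USD/person/y\n",
              x$annual_average_per_capita))
  cat(sprintf("  per MT fortified salt     : %.1f USD/MT\n", x$annual_average_per_mt))
  cat("  stakeholder groups (annual average, share):\n")
  for (i in seq_len(nrow(x$by_stakeholder))) {
    cat(sprintf("    %-20s %14s  %3d%%\n", x$by_stakeholder$group[i],
                format(round_thousand(x$by_stakeholder$annual_average[i]),
                       big.mark = ",", scientific = FALSE),
                x$by_stakeholder$share_pct[i]))
  }
  if (!is.null(x$incremental)) {
    cat(sprintf("  incremental vs %s         : %s USD/y\n",
                x$incremental$baseline_book_id,
                format(round_thousand(x$incremental$annual_average_total),
                       big.mark = ",", scientific = FALSE)))
  }
  invisible(x)
}

# ---- report writers ------------------------------------------------------

#' Cost report as a long data frame
#'
#' Long format suitable for CSV export: one row per
#' (scenario, program, metric, period) with `period` either a calendar year
#' or `"average"`.
#'
#' @param report A `cost_report`.
#' @return A data frame.
#' @export
report_long <- function(report) {
  rows <- list()
  add <- function(metric, period, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      scenario = report$scenario, program = report$program_id,
      metric = metric, period = as.character(period), value = value,
      stringsAsFactors = FALSE)
  }
  for (y in names(report$per_year_total)) add("total_cost", y, report$per_year_total[[y]])
  add("annual_average_total", "average", report$annual_average_total)
  add("annual_average_per_capita", "average", report$annual_average_per_capita)
  add("annual_average_per_mt", "average", report$annual_average_per_mt)
  add("annual_average_premix_per_mt", "average", report$annual_average_premix_per_mt)
  for (i in seq_len(nrow(report$by_activity))) {
    add(paste0("activity.", report$by_activity$activity_id[i]), "average",
        report$by_activity$annual_average[i])
  }
  for (i in seq_len(nrow(report$by_stakeholder))) {
    add(paste0("stakeholder.", report$by_stakeholder$group[i]), "average",
        report$by_stakeholder$annual_average[i])
  }
  if (!is.null(report$incremental)) {
    add("incremental_annual_average_total", "average",
        report$incremental$annual_average_total)
    add("incremental_annual_average_per_mt", "average",
        report$incremental$annual_average_per_mt)
  }
  do.call(rbind, rows)
}

#' Write a cost report as CSV (long format)
#' @param report A `cost_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report_long(report), path, row.names = FALSE)
  invisible(path)
}

#' Write a cost report as schema-versioned JSON
#' @param report A `cost_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema = "fortcost-report/1",
    book_id = report$book_id,
    program = report$program_id,
    scenario = report$scenario,
    horizon = report$horizon,
    per_mt_denominator = report$per_mt_denominator,
    per_year_total = as.list(report$per_year_total),
    annual_average = list(
      total = report$annual_average_total,
      per_capita = report$annual_average_per_capita,
      per_mt = report$annual_average_per_mt,
      premix_per_mt = report$annual_average_premix_per_mt
    ),
    by_activity = report$by_activity,
    by_stakeholder = report$by_stakeholder
  )
  if (!is.null(report$incremental)) {
    inc <- report$incremental
    out$incremental <- list(
      baseline_book_id = inc$baseline_book_id,
      per_year_total = as.list(inc$per_year_total),
      annual_average_total = inc$annual_average_total,
      annual_average_per_capita = inc$annual_average_per_capita,
      annual_average_per_mt = inc$annual_average_per_mt,
      annual_average_premix_per_mt = inc$annual_average_premix_per_mt,
      by_stakeholder = inc$by_stakeholder
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Side-by-side comparison of program reports
#'
#' A comparison table across programs in the layout of the published
#' total-and-incremental cost table: annual-average total, per-capita,
#' premix-per-MT and total-per-MT rows, plus the same metrics as differences
#' from the baseline program. Totals are rounded to the nearest 1,000 USD and
#' per-MT values to one decimal unless `rounding = FALSE`.
#'
#' @param reports List of `cost_report`s sharing a horizon (typically the
#'   four programs of one scenario).
#' @param rounding Apply the tables' reporting rounding (default `TRUE`).
#' @return A data frame with one column per program.
#' @export
comparison_table <- function(reports, rounding = TRUE) {
  progs <- vapply(reports, function(r) r$program_id, character(1))
  reports <- reports[order(match(progs, program_ids()))]
  progs <- progs[order(match(progs, program_ids()))]
  rnd_usd <- if (rounding) round_thousand else identity
  rnd_mt <- if (rounding) function(x) round_half_up(x, 1) else identity
  rnd_cap <- if (rounding) function(x) round_half_up(x, 2) else identity
  metric <- function(f) vapply(reports, f, numeric(1))
  inc_metric <- function(f) vapply(reports, function(r) {
    if (is.null(r$incremental)) NA_real_ else f(r$incremental)
  }, numeric(1))
  tab <- rbind(
    annual_average_total = rnd_usd(metric(function(r) r$annual_average_total)),
    annual_average_per_capita = rnd_cap(metric(function(r) r$annual_average_per_capita)),
    annual_average_premix_per_mt = rnd_mt(metric(function(r) r$annual_average_premix_per_mt)),
    annual_average_per_mt = rnd_mt(metric(function(r) r$annual_average_per_mt)),
    incremental_annual_average_total = rnd_usd(inc_metric(function(i) i$annual_average_total)),
    incremental_per_capita = rnd_cap(inc_metric(function(i) i$annual_average_per_capita)),
    incremental_premix_per_mt = rnd_mt(inc_metric(function(i) i$annual_average_premix_per_mt)),
    incremental_per_mt = rnd_mt(inc_metric(function(i) i$annual_average_per_mt))
  )
  out <- data.frame(metric = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("metric", progs)
  out
}
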