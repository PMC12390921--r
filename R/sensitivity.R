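#' Sensitivity components
#'
#' The three uncertain cost components varied in the deterministic
#' sensitivity analysis, and the activity categories they scale:
#' * `premix_price` — every premix monetary input (fortificant catalog
#'   prices, extruded premix delivered price, shipping adder, and any
#'   premix-category activity amounts), i.e. including the potassium iodate;
#' * `refinery_fortification_cost` — the `refinery_fortification` category
#'   only (labor, power/fuel, annualized equipment, maintenance) — not
#'   QA/QC, training or administration;
#' * `government_monitoring_cost` — refinery, import and household
#'   monitoring (market monitoring excluded by default; override via
#'   `monitoring_categories`).
#'
#' @return Character vector of component names.
#' @export
sensitivity_components <- function() {
  c("premix_price", "refinery_fortification_cost", "government_monitoring_cost")
}

#' Specification of a deterministic sensitivity analysis
#'
#' @param varied_components Subset of [sensitivity_components()].
#' @param fraction Symmetric variation, in (0, 1); default 0.30.
#' @param monitoring_categories Activity categories making up the government
#'   monitoring component.
#' @return A `sensitivity_spec` object.
#' @export
sensitivity_spec <- function(varied_components = sensitivity_components(),
                             fraction = 0.30,
                             monitoring_categories = c("gov_refinery_monitoring",
                                                       "gov_import_monitoring",
                                                       "gov_household_monitoring")) {
  if (!length(varied_components)) {
    stop("sensitivity_spec: `varied_components` must be non-empty", call. = FALSE)
  }
  bad <- setdiff(varied_components, sensitivity_components())
  if (length(bad)) {
    stop(sprintf("sensitivity_spec: unknown component(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("sensitivity_spec: `fraction` must be in (0, 1)", call. = FALSE)
  }
  bad_cat <- setdiff(monitoring_categories, activity_categories())
  if (length(bad_cat)) {
    stop(sprintf("sensitivity_spec: unknown categor(ies): %s",
                 paste(bad_cat, collapse = ", ")), call. = FALSE)
  }
  structure(list(varied_components = varied_components,
                 fraction = as.numeric(fraction),
                 monitoring_categories = monitoring_categories),
            class = "sensitivity_spec")
}

# scale the monetary inputs of one component by `factor`, returning a new book
scale_component <- function(book, component, factor, monitoring_categories) {
  categories <- switch(component,
    premix_price = "premix",
    refinery_fortification_cost = "refinery_fortification",
    government_monitoring_cost = monitoring_categories,
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  )
  if (component == "premix_price") {
    book$premix$catalog$price_per_kg_compound <-
      book$premix$catalog$price_per_kg_compound * factor
    book$premix$extruded_price_per_kg <- book$premix$extruded_price_per_kg * factor
    book$premix$shipping_handling_per_mt_salt <-
      book$premix$shipping_handling_per_mt_salt * factor
  }
  book$activities <- lapply(book$activities, function(a) {
    if (a$category %in% categories) {
      if (!is.null(a$cost_rule$amount)) a$cost_rule$amount <- a$cost_rule$amount * factor
      if (!is.null(a$cost_rule$rate)) a$cost_rule$rate <- a$cost_rule$rate * factor
    }
    a
  })
  book
}

#' Run a deterministic one-way and combined sensitivity analysis
#'
#' For each varied component, the full cost model is recomputed with that
#' component's monetary inputs scaled by `(1 - fraction)` and
#' `(1 + fraction)` (no closed-form shortcut), and the annual-average cost
#' per MT of fortified salt is reported. The combined best case scales all
#' varied components down simultaneously; the worst case scales them all up.
#'
#' @param book A validated `parameter_book`.
#' @param spec A [sensitivity_spec()].
#' @param per_mt_denominator Passed to [compute_report()].
#' @return A `sensitivity_result`: data frame `one_way` with
#'   `(component, low_per_mt, base_per_mt, high_per_mt)`, scalars
#'   `best_case_per_mt` / `worst_case_per_mt`, and `base_per_mt`.
#' @export
run_sensitivity <- function(book, spec = sensitivity_spec(),
                            per_mt_denominator = "fortified") {
  stopifnot(inherits(book, "parameter_book"), inherits(spec, "sensitivity_spec"))
  per_mt_of <- function(b) {
    compute_report(b, per_mt_denominator = per_mt_denominator)$annual_average_per_mt
  }
  base <- per_mt_of(book)
  one_way <- do.call(rbind, lapply(spec$varied_components, function(comp) {
    low <- per_mt_of(scale_component(book, comp, 1 - spec$fraction,
                                     spec$monitoring_categories))
    high <- per_mt_of(scale_component(book, comp, 1 + spec$fraction,
                                      spec$monitoring_categories))
    data.frame(component = comp, low_per_mt = low, base_per_mt = base,
               high_per_mt = high, stringsAsFactors = FALSE)
  }))
  scale_all <- function(b, factor) {
    for (comp in spec$varied_components) {
      b <- scale_component(b, comp, factor, spec$monitoring_categories)
    }
    b
  }
  structure(list(
    book_id = book$book_id,
    fraction = spec$fraction,
    one_way = one_way,
    base_per_mt = base,
    best_case_per_mt = per_mt_of(scale_all(book, 1 - spec$fraction)),
    worst_case_per_mt = per_mt_of(scale_all(book, 1 + spec$fraction))
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s, +/-%.0f%% variation\n",
              x$book_id, 100 * x$fraction))
  cat(sprintf("  base cost per MT : %.2f USD/MT\n", x$base_per_mt))
  for (i in seq_len(nrow(x$one_way))) {
    cat(sprintf("  %-30s %7.2f .. %7.2f USD/MT\n", x$one_way$component[i],
                x$one_way$low_per_mt[i], x$one_way$high_per_mt[i]))
  }
  cat(sprintf("  best case  : %.2f USD/MT\n", x$best_case_per_mt))
  cat(sprintf("  worst case : %.2f USD/MT\n", x$worst_case_per_mt))
  invisible(x)
}

#' Sensitivity result as a tornado-plot-ready data frame
#'
#' One row per varied component plus `combined` best/worst rows.
#'
#' @param result A `sensitivity_result`.
#' @return A data frame `(component, low_per_mt, base_per_mt, high_per_mt)`.
#' @export
sensitivity_long <- function(result) {
  rbind(result$one_way,
        data.frame(component = "combined",
                   low_per_mt = result$best_case_per_mt,
                   base_per_mt = result$base_per_mt,
                   high_per_mt = result$worst_case_per_mt,
                   stringsAsFactors = FALSE))
}

#' Write a sensitivity result as CSV
#' @param result A `sensitivity_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(result, path) {
  utils::write.csv(sensitivity_long(result), path, row.names = FALSE)
  invisible(path)
}
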