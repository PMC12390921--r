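#' @keywords internal
"_PACKAGE"

# ---- closed vocabularies ------------------------------------------------

#' Closed vocabularies of the parameter model
#'
#' Program identifiers, nutrient names, activity categories, phases,
#' stakeholders and cost-rule kinds form closed sets so that reports can be
#' reconstructed with stable keys.
#'
#' @name vocabularies
#' @return Character vectors.
#' @export
program_ids <- function() c("iodized", "dual", "triple", "quad")

#' @rdname vocabularies
#' @export
nutrient_names <- function() c("iodine", "folic_acid", "vitamin_b12", "zinc")

#' @rdname vocabularies
#' @export
activity_categories <- function() {
  c("premix", "refinery_fortification", "refinery_qaqc", "refinery_training",
    "refinery_admin", "gov_refinery_monitoring", "gov_import_monitoring",
    "gov_market_monitoring", "gov_household_monitoring", "social_marketing",
    "gov_capacity_building", "gov_admin", "planning", "relabeling")
}

#' @rdname vocabularies
#' @export
cost_rule_kinds <- function() c("fixed_annual", "capital", "per_mt", "premix")

# nutrient set each program must fortify (monotone nesting)
program_nutrients <- function(program_id) {
  switch(program_id,
    iodized = "iodine",
    dual    = c("iodine", "folic_acid"),
    triple  = c("iodine", "folic_acid", "vitamin_b12"),
    quad    = c("iodine", "folic_acid", "vitamin_b12", "zinc"),
    stop(sprintf("unknown program '%s'", program_id), call. = FALSE)
  )
}

#' Stakeholder reporting group of an activity category
#'
#' Maps each activity category onto the three reporting groups used in the
#' cost tables: `premix`, `refinery_related` (fortification, QA/QC, training,
#' administration, relabeling) and `government_related` (monitoring, social
#' marketing, planning, capacity building, administration).
#'
#' @param category Character vector of activity categories.
#' @return Character vector of group names.
#' @export
stakeholder_group <- function(category) {
  refinery <- c("refinery_fortification", "refinery_qaqc", "refinery_training",
                "refinery_admin", "relabeling")
  ifelse(category == "premix", "premix",
         ifelse(category %in% refinery, "refinery_related", "government_related"))
}

# ---- validation plumbing ------------------------------------------------

# A "problems" collector: validators return character vectors of
# "field.path: message" strings; empty means valid.
problem <- function(path, msg) sprintf("%s: %s", path, msg)

validation_stop <- function(problems, what) {
  stop(structure(
    class = c("fortcost_validation_error", "error", "condition"),
    list(message = sprintf("invalid %s:\n%s", what,
                           paste0("  - ", problems, collapse = "\n")),
         call = NULL, problems = problems)
  ))
}

chk_enum <- function(x, allowed, path) {
  if (!is.character(x) || length(x) != 1L || !x %in% allowed) {
    problem(path, sprintf("must be one of %s", paste(allowed, collapse = ", ")))
  } else character()
}

chk_num <- function(x, path, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    return(problem(path, "must be a single number"))
  }
  if (x < min) return(problem(path, sprintf("must be >= %s", format(min))))
  if (x > max) return(problem(path, sprintf("must be <= %s", format(max))))
  character()
}

as_year_series <- function(x) {
  # accept named list or named numeric; normalize to named double sorted by year
  v <- unlist(x, use.names = TRUE)
  v <- as.numeric(v)
  names(v) <- names(unlist(x))
  v[order(as.integer(names(v)))]
}

# ---- fortification standard ---------------------------------------------

#' Fortification standard for one program
#'
#' Target concentrations in mg of nutrient per kg of salt. Concentrations are
#' nutrient (elemental/vitamin) mass, not fortificant compound mass; the
#' conversion to compound mass happens in the premix module via catalog mass
#' fractions. Non-zero nutrients must be exactly the program's set: iodine for
#' iodized salt, plus folic acid (dual), plus vitamin B-12 (triple), plus
#' zinc (quad).
#'
#' @param program_id One of `"iodized"`, `"dual"`, `"triple"`, `"quad"`.
#' @param concentrations Named numeric vector, names in [nutrient_names()],
#'   values in mg/kg.
#' @return A `fortification_standard` object.
#' @examples
#' fortification_standard("dual", c(iodine = 30, folic_acid = 17.2))
#' @export
fortification_standard <- function(program_id, concentrations) {
  conc <- rep(0, length(nutrient_names()))
  names(conc) <- nutrient_names()
  supplied <- as_named_numeric(concentrations)
  std <- structure(list(program_id = program_id, concentrations = conc),
                   class = "fortification_standard")
  unknown <- setdiff(names(supplied), nutrient_names())
  probs <- character()
  if (length(unknown)) {
    probs <- c(probs, problem("program.concentrations",
                              sprintf("unknown nutrient(s): %s",
                                      paste(unknown, collapse = ", "))))
  } else {
    std$concentrations[names(supplied)] <- unname(supplied)
    probs <- c(probs, validate_standard(std))
  }
  probs <- c(chk_enum(program_id, program_ids(), "program.program_id"), probs)
  if (length(probs)) validation_stop(probs, "fortification standard")
  std
}

as_named_numeric <- function(x) {
  v <- unlist(x, use.names = TRUE)
  stats::setNames(as.numeric(v), names(v))
}

validate_standard <- function(std, path = "program") {
  probs <- character()
  conc <- std$concentrations
  if (any(!is.finite(conc)) || any(conc < 0)) {
    probs <- c(probs, problem(paste0(path, ".concentrations"),
                              "all concentrations must be finite and >= 0"))
    return(probs)
  }
  if (!"iodine" %in% names(conc) || conc[["iodine"]] <= 0) {
    probs <- c(probs, problem(paste0(path, ".concentrations.iodine"),
                              "iodine must be present and > 0 for every program"))
  }
  want <- program_nutrients(std$program_id)
  have <- names(conc)[conc > 0]
  if (!setequal(want, have)) {
    probs <- c(probs, problem(
      paste0(path, ".concentrations"),
      sprintf("non-zero nutrients {%s} must be exactly {%s} for program '%s'",
              paste(sort(have), collapse = ", "),
              paste(sort(want), collapse = ", "), std$program_id)))
  }
  probs
}

# ---- demand params -------------------------------------------------------

#' Demand-side parameters
#'
#' @param population_by_year Named numeric vector (names = calendar years) of
#'   total population.
#' @param per_capita_salt_g_per_day Grams of fortifiable (discretionary +
#'   manufactured-food) salt per person per day.
#' @param compliance_fraction Fraction of the salt supply actually fortified
#'   to the standard, in \[0, 1\].
#' @param days_per_year Days per year (default 365).
#' @return A `demand_params` object.
#' @export
demand_params <- function(population_by_year, per_capita_salt_g_per_day,
                          compliance_fraction, days_per_year = 365) {
  d <- structure(list(
    population_by_year = as_year_series(population_by_year),
    per_capita_salt_g_per_day = as.numeric(per_capita_salt_g_per_day),
    compliance_fraction = as.numeric(compliance_fraction),
    days_per_year = as.numeric(days_per_year)
  ), class = "demand_params")
  probs <- validate_demand(d)
  if (length(probs)) validation_stop(probs, "demand parameters")
  d
}

validate_demand <- function(d, path = "demand", horizon_years = NULL) {
  probs <- c(
    chk_num(d$per_capita_salt_g_per_day, paste0(path, ".per_capita_salt_g_per_day"),
            min = .Machine$double.eps),
    chk_num(d$compliance_fraction, paste0(path, ".compliance_fraction"), 0, 1),
    chk_num(d$days_per_year, paste0(path, ".days_per_year"), 1, 366)
  )
  pop <- d$population_by_year
  if (!length(pop) || any(!is.finite(pop)) || any(pop <= 0)) {
    probs <- c(probs, problem(paste0(path, ".population_by_year"),
                              "population must be > 0 for every year"))
  }
  if (!is.null(horizon_years)) {
    missing_years <- setdiff(as.character(horizon_years), names(pop))
    if (length(missing_years)) {
      probs <- c(probs, problem(paste0(path, ".population_by_year"),
                                sprintf("missing year(s): %s",
                                        paste(missing_years, collapse = ", "))))
    }
  }
  probs
}

# ---- finance params ------------------------------------------------------

#' Finance constants
#'
#' Discount rate and equipment life drive capital annualization; the deflator,
#' CPI and exchange-rate tables normalize historical amounts to base-year USD.
#'
#' @param discount_rate Fraction per year, >= 0 (0.03 in the shipped books).
#' @param equipment_life_years Useful life for annualization, >= 1.
#' @param base_currency_year Base year all costs are expressed in (2021).
#' @param usd_deflator_by_year,etb_cpi_by_year Named numeric index series.
#' @param etb_per_usd_base_year Average exchange rate in the base year.
#' @return A `finance_params` object.
#' @export
finance_params <- function(discount_rate, equipment_life_years,
                           base_currency_year, usd_deflator_by_year,
                           etb_cpi_by_year, etb_per_usd_base_year) {
  f <- structure(list(
    discount_rate = as.numeric(discount_rate),
    equipment_life_years = as.numeric(equipment_life_years),
    base_currency_year = as.integer(base_currency_year),
    usd_deflator_by_year = as_year_series(usd_deflator_by_year),
    etb_cpi_by_year = as_year_series(etb_cpi_by_year),
    etb_per_usd_base_year = as.numeric(etb_per_usd_base_year)
  ), class = "finance_params")
  probs <- validate_finance(f)
  if (length(probs)) validation_stop(probs, "finance parameters")
  f
}

validate_finance <- function(f, path = "finance") {
  probs <- c(
    chk_num(f$discount_rate, paste0(path, ".discount_rate"), 0),
    chk_num(f$equipment_life_years, paste0(path, ".equipment_life_years"), 1),
    chk_num(f$etb_per_usd_base_year, paste0(path, ".etb_per_usd_base_year"),
            .Machine$double.eps)
  )
  for (nm in c("usd_deflator_by_year", "etb_cpi_by_year")) {
    idx <- f[[nm]]
    if (length(idx) && (any(!is.finite(idx)) || any(idx <= 0))) {
      probs <- c(probs, problem(paste0(path, ".", nm), "all indices must be > 0"))
    }
  }
  probs
}

# ---- activity schedule ---------------------------------------------------

#' One costed activity
#'
#' An activity is the unit of the activity-based cost model: a labelled line
#' item with a phase (`startup` during the phase-in years, `recurring`
#' otherwise), a paying stakeholder, a reporting category, the calendar years
#' it is active, and a cost rule:
#'
#' * `fixed_annual` — `amount` (base-year USD) in each active year;
#' * `capital` — `amount` is a lump sum annualized over the horizon as an
#'   equivalent annual cost at the book's discount rate and equipment life;
#' * `per_mt` — `rate` USD per metric ton of fortified salt in active years;
#' * `premix` — cost delegated to the premix module (see
#'   [annual_premix_cost()]).
#'
#' @param activity_id Identifier, unique within a book.
#' @param label Human-readable label.
#' @param phase `"startup"` or `"recurring"`.
#' @param stakeholder `"industry"`, `"government"` or `"partner"`.
#' @param category One of [activity_categories()].
#' @param cost_rule List with `kind` and `amount` (fixed_annual, capital) or
#'   `rate` (per_mt); `list(kind = "premix")` carries no amount.
#' @param active_years Integer vector of calendar years.
#' @return An `activity_schedule` object.
#' @examples
#' activity_schedule("qaqc", "Refinery QA/QC", "recurring", "industry",
#'                   "refinery_qaqc", list(kind = "fixed_annual", amount = 125000),
#'                   2024:2033)
#' @export
activity_schedule <- function(activity_id, label, phase, stakeholder, category,
                              cost_rule, active_years) {
  a <- structure(list(
    activity_id = as.character(activity_id),
    label = as.character(label),
    phase = phase,
    stakeholder = stakeholder,
    category = category,
    cost_rule = normalize_cost_rule(cost_rule),
    active_years = sort(unique(as.integer(active_years)))
  ), class = "activity_schedule")
  probs <- validate_activity(a, path = paste0("activities.", a$activity_id))
  if (length(probs)) validation_stop(probs, "activity schedule")
  a
}

normalize_cost_rule <- function(rule) {
  rule <- as.list(rule)
  out <- list(kind = rule$kind %||% NA_character_)
  if (!is.null(rule$amount)) out$amount <- as.numeric(rule$amount)
  if (!is.null(rule$rate)) out$rate <- as.numeric(rule$rate)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_activity <- function(a, path = "activity") {
  probs <- c(
    chk_enum(a$phase, c("startup", "recurring"), paste0(path, ".phase")),
    chk_enum(a$stakeholder, c("industry", "government", "partner"),
             paste0(path, ".stakeholder")),
    chk_enum(a$category, activity_categories(), paste0(path, ".category"))
  )
  rule <- a$cost_rule
  rpath <- paste0(path, ".cost_rule")
  if (!is.character(rule$kind) || !rule$kind %in% cost_rule_kinds()) {
    return(c(probs, problem(rpath, sprintf("kind must be one of %s",
                                           paste(cost_rule_kinds(), collapse = ", ")))))
  }
  has_amount <- !is.null(rule$amount)
  has_rate <- !is.null(rule$rate)
  switch(rule$kind,
    fixed_annual = ,
    capital = {
      if (!has_amount || has_rate) {
        probs <- c(probs, problem(rpath, sprintf("'%s' rule needs exactly `amount`", rule$kind)))
      } else {
        probs <- c(probs, chk_num(rule$amount, paste0(rpath, ".amount"), 0))
      }
    },
    per_mt = {
      if (!has_rate || has_amount) {
        probs <- c(probs, problem(rpath, "'per_mt' rule needs exactly `rate`"))
      } else {
        probs <- c(probs, chk_num(rule$rate, paste0(rpath, ".rate"), 0))
      }
    },
    premix = {
      if (has_amount || has_rate) {
        probs <- c(probs, problem(rpath, "'premix' rule carries no amount; costs come from the premix spec"))
      }
      if (a$category != "premix") {
        probs <- c(probs, problem(rpath, "'premix' rule is only valid on a premix-category activity"))
      }
    }
  )
  if (a$category == "premix" && rule$kind != "premix") {
    probs <- c(probs, problem(rpath, "premix-category activities must use the 'premix' rule"))
  }
  if (rule$kind == "capital" && a$phase != "startup" &&
      a$category != "refinery_fortification") {
    probs <- c(probs, problem(rpath,
      "'capital' rule only on startup or equipment (refinery_fortification) activities"))
  }
  if (!length(a$active_years)) {
    probs <- c(probs, problem(paste0(path, ".active_years"), "must be non-empty"))
  }
  probs
}

# ---- premix spec ---------------------------------------------------------

#' Premix specification for a program
#'
#' Splits the program's nutrients between the two delivery technologies:
#' sprayed solution (potassium iodate, optionally with folic acid) and
#' extruded, encapsulated salt-like grains blended into iodized salt (used
#' for triple and quadruple fortified salt, costed as delivered
#' price x inclusion rate). Shipping/handling is a per-MT-of-salt adder; no
#' overage is applied by default (stable formulations).
#'
#' @param sprayed_nutrients,extruded_nutrients Character vectors of nutrient
#'   names; their union must be exactly the program's non-zero nutrients.
#' @param extruded_inclusion_rate_kg_per_mt Kilograms of extruded premix
#'   blended per MT of salt (0 when nothing is extruded).
#' @param extruded_price_per_kg Delivered price of the extruded premix, USD/kg.
#' @param shipping_handling_per_mt_salt USD/MT-of-salt adder, split between
#'   the sprayed and extruded streams in proportion to their cost.
#' @param overage_fraction Deliberate fortificant excess, fraction (default 0).
#' @param catalog Fortificant catalog: data frame with columns `nutrient`,
#'   `compound`, `nutrient_mass_fraction`, `price_per_kg_compound`.
#' @return A `premix_spec` object.
#' @export
premix_spec <- function(sprayed_nutrients, extruded_nutrients = character(),
                        extruded_inclusion_rate_kg_per_mt = 0,
                        extruded_price_per_kg = 0,
                        shipping_handling_per_mt_salt = 0,
                        overage_fraction = 0,
                        catalog = default_fortificant_catalog()) {
  p <- structure(list(
    sprayed_nutrients = as.character(sprayed_nutrients),
    extruded_nutrients = as.character(extruded_nutrients),
    extruded_inclusion_rate_kg_per_mt = as.numeric(extruded_inclusion_rate_kg_per_mt),
    extruded_price_per_kg = as.numeric(extruded_price_per_kg),
    shipping_handling_per_mt_salt = as.numeric(shipping_handling_per_mt_salt),
    overage_fraction = as.numeric(overage_fraction),
    catalog = as_catalog(catalog)
  ), class = "premix_spec")
  probs <- validate_premix_spec(p)
  if (length(probs)) validation_stop(probs, "premix spec")
  p
}

as_catalog <- function(catalog) {
  if (is.data.frame(catalog)) {
    df <- catalog
  } else {
    df <- do.call(rbind, lapply(catalog, function(e) {
      data.frame(nutrient = as.character(e$nutrient),
                 compound = as.character(e$compound),
                 nutrient_mass_fraction = as.numeric(e$nutrient_mass_fraction),
                 price_per_kg_compound = as.numeric(e$price_per_kg_compound),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(df) <- NULL
  df[c("nutrient", "compound", "nutrient_mass_fraction", "price_per_kg_compound")]
}

validate_premix_spec <- function(p, path = "premix", standard = NULL) {
  probs <- c(
    chk_num(p$extruded_inclusion_rate_kg_per_mt,
            paste0(path, ".extruded_inclusion_rate_kg_per_mt"), 0),
    chk_num(p$extruded_price_per_kg, paste0(path, ".extruded_price_per_kg"), 0),
    chk_num(p$shipping_handling_per_mt_salt,
            paste0(path, ".shipping_handling_per_mt_salt"), 0),
    chk_num(p$overage_fraction, paste0(path, ".overage_fraction"), 0)
  )
  unknown <- setdiff(c(p$sprayed_nutrients, p$extruded_nutrients), nutrient_names())
  if (length(unknown)) {
    probs <- c(probs, problem(path, sprintf("unknown nutrient(s): %s",
                                            paste(unknown, collapse = ", "))))
  }
  if (length(intersect(p$sprayed_nutrients, p$extruded_nutrients))) {
    probs <- c(probs, problem(path, "a nutrient cannot be both sprayed and extruded"))
  }
  if (length(p$extruded_nutrients) && p$extruded_inclusion_rate_kg_per_mt <= 0) {
    probs <- c(probs, problem(paste0(path, ".extruded_inclusion_rate_kg_per_mt"),
                              "must be > 0 when nutrients are extruded"))
  }
  if (!length(p$extruded_nutrients) && p$extruded_inclusion_rate_kg_per_mt > 0) {
    probs <- c(probs, problem(paste0(path, ".extruded_inclusion_rate_kg_per_mt"),
                              "must be 0 when no nutrients are extruded"))
  }
  cat_probs <- with(p$catalog, !is.finite(nutrient_mass_fraction) |
                      nutrient_mass_fraction <= 0 | nutrient_mass_fraction > 1 |
                      !is.finite(price_per_kg_compound) | price_per_kg_compound < 0)
  if (any(cat_probs)) {
    probs <- c(probs, problem(paste0(path, ".catalog"),
      "mass fractions must be in (0, 1] and prices >= 0"))
  }
  missing_cat <- setdiff(p$sprayed_nutrients, p$catalog$nutrient)
  if (length(missing_cat)) {
    probs <- c(probs, problem(paste0(path, ".catalog"),
      sprintf("no catalog entry for sprayed nutrient(s): %s",
              paste(missing_cat, collapse = ", "))))
  }
  if (!is.null(standard)) {
    want <- names(standard$concentrations)[standard$concentrations > 0]
    have <- c(p$sprayed_nutrients, p$extruded_nutrients)
    if (!setequal(want, have)) {
      probs <- c(probs, problem(path,
        sprintf("sprayed+extruded nutrients {%s} must cover exactly the program's non-zero nutrients {%s}",
                paste(sort(have), collapse = ", "), paste(sort(want), collapse = ", "))))
    }
  }
  probs
}

#' Default fortificant catalog
#'
#' Compound identities and nutrient mass fractions are from molar masses
#' (potassium iodate delivers iodine at 126.90/214.00 = 0.5931 of compound
#' mass; folic acid and cyanocobalamin are dosed as themselves; zinc oxide
#' delivers zinc at 65.38/81.38); prices are placeholder delivered prices in
#' base-year USD/kg and are overridden by calibrated values in the shipped
#' parameter books.
#'
#' @return A data frame with one row per nutrient.
#' @export
default_fortificant_catalog <- function() {
  data.frame(
    nutrient = c("iodine", "folic_acid", "vitamin_b12", "zinc"),
    compound = c("potassium iodate", "folic acid", "cyanocobalamin", "zinc oxide"),
    nutrient_mass_fraction = c(126.90 / 214.00, 1.0, 1.0, 65.38 / 81.38),
    price_per_kg_compound = c(65, 91, 6000, 3),
    stringsAsFactors = FALSE
  )
}

# ---- parameter book ------------------------------------------------------

#' Assemble and validate a parameter book
#'
#' A parameter book is the complete declarative model for one program under
#' one consumption scenario: the fortification standard, demand and finance
#' blocks, the premix specification and the costed activity list, over a
#' fixed calendar horizon. Expansion programs (dual/triple/quad) carry
#' `phase_in_years` initial years during which salt iodization continues as
#' usual while startup activities occur; the iodized baseline has none.
#'
#' @param book_id Identifier.
#' @param program A [fortification_standard()].
#' @param demand A [demand_params()].
#' @param finance A [finance_params()].
#' @param premix A [premix_spec()].
#' @param activities List of [activity_schedule()] objects.
#' @param horizon `list(start =, end =)` calendar years.
#' @param phase_in_years Number of initial baseline years (0 for iodized).
#' @param scenario Free-text scenario label.
#' @param baseline_book_id Optional id of the comparator (baseline) book.
#' @return A validated `parameter_book`.
#' @export
parameter_book <- function(book_id, program, demand, finance, premix,
                           activities, horizon, phase_in_years = 0,
                           scenario = "", baseline_book_id = NULL) {
  book <- structure(list(
    book_id = as.character(book_id),
    scenario = as.character(scenario),
    baseline_book_id = if (is.null(baseline_book_id)) NULL else as.character(baseline_book_id),
    horizon = list(start = as.integer(horizon$start), end = as.integer(horizon$end)),
    phase_in_years = as.integer(phase_in_years),
    program = program,
    demand = demand,
    finance = finance,
    premix = premix,
    activities = activities
  ), class = "parameter_book")
  probs <- validate_parameter_book(book)
  if (length(probs)) validation_stop(probs, sprintf("parameter book '%s'", book$book_id))
  book
}

#' Calendar years of a book's horizon
#' @param book A `parameter_book`.
#' @return Integer vector of years.
#' @export
book_years <- function(book) book$horizon$start:book$horizon$end

#' Phase-in years of a book
#' @param book A `parameter_book`.
#' @return Integer vector (possibly empty) of initial baseline years.
#' @export
phase_in_years_of <- function(book) {
  yrs <- book_years(book)
  if (book$phase_in_years > 0) yrs[seq_len(book$phase_in_years)] else integer()
}

#' Validate a parameter book
#'
#' Checks every invariant of the book and its blocks and returns all
#' violations as "field.path: message" strings (empty when valid). The
#' constructors and [load_parameter_book()] stop with a
#' `fortcost_validation_error` carrying this list.
#'
#' @param book A `parameter_book` (not necessarily valid).
#' @return Character vector of problems.
#' @export
validate_parameter_book <- function(book) {
  probs <- character()
  h <- book$horizon
  if (!is.finite(h$start) || !is.finite(h$end) || h$end < h$start) {
    return(problem("horizon", "end must be >= start"))
  }
  yrs <- book_years(book)
  if (book$phase_in_years < 0 || book$phase_in_years > length(yrs)) {
    probs <- c(probs, problem("phase_in_years",
                              "must be between 0 and the horizon length"))
  }
  if (book$program$program_id == "iodized" && book$phase_in_years != 0) {
    probs <- c(probs, problem("phase_in_years", "must be 0 for the iodized program"))
  }
  probs <- c(probs,
             validate_standard(book$program),
             validate_demand(book$demand, horizon_years = yrs),
             validate_finance(book$finance),
             validate_premix_spec(book$premix, standard = book$program))
  ids <- vapply(book$activities, function(a) a$activity_id, character(1))
  if (anyDuplicated(ids)) {
    probs <- c(probs, problem("activities",
                              sprintf("duplicated activity_id(s): %s",
                                      paste(unique(ids[duplicated(ids)]), collapse = ", "))))
  }
  phase_in <- phase_in_years_of(book)
  for (a in book$activities) {
    apath <- paste0("activities.", a$activity_id)
    probs <- c(probs, validate_activity(a, apath))
    if (length(setdiff(a$active_years, yrs))) {
      probs <- c(probs, problem(paste0(apath, ".active_years"),
        sprintf("year(s) outside horizon %d-%d: %s", h$start, h$end,
                paste(setdiff(a$active_years, yrs), collapse = ", "))))
    }
    if (identical(a$phase, "startup") && length(setdiff(a$active_years, phase_in))) {
      probs <- c(probs, problem(paste0(apath, ".active_years"),
                                "startup activities appear only in phase-in years"))
    }
  }
  probs
}

#' @export
print.parameter_book <- function(x, ...) {
  cat(sprintf("<parameter_book> %s\n", x$book_id))
  cat(sprintf("  program: %s  scenario: %s\n", x$program$program_id, x$scenario))
  cat(sprintf("  horizon: %d-%d  phase-in years: %d\n",
              x$horizon$start, x$horizon$end, x$phase_in_years))
  cat(sprintf("  activities: %d (%d startup, %d recurring)\n",
              length(x$activities),
              sum(vapply(x$activities, function(a) a$phase == "startup", logical(1))),
              sum(vapply(x$activities, function(a) a$phase == "recurring", logical(1)))))
  invisible(x)
}

# ---- YAML IO -------------------------------------------------------------

BOOK_SCHEMA <- "fortcost-parameter-book/1"

#' Load a parameter book from YAML
#'
#' Reads the documented single-file YAML schema, assembles the book through
#' the type constructors and validates every invariant. Any violation raises
#' one `fortcost_validation_error` naming the offending field path(s).
#'
#' @param path Path to a YAML parameter book.
#' @return A validated `parameter_book`.
#' @seealso [save_parameter_book()], [write_ethiopia_fixture()]
#' @export
load_parameter_book <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  parameter_book_from_list(raw)
}

# build a book from the plain-list (YAML) representation
parameter_book_from_list <- function(raw) {
  need <- c("book_id", "horizon", "program", "demand", "finance", "premix", "activities")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    validation_stop(sprintf("%s: required block missing", miss), "parameter book")
  }
  std <- structure(list(
    program_id = raw$program$program_id %||% NA_character_,
    concentrations = {
      conc <- rep(0, length(nutrient_names()))
      names(conc) <- nutrient_names()
      supplied <- as_named_numeric(raw$program$concentrations)
      unknown <- setdiff(names(supplied), nutrient_names())
      if (length(unknown)) {
        validation_stop(problem("program.concentrations",
                                sprintf("unknown nutrient(s): %s",
                                        paste(unknown, collapse = ", "))),
                        "parameter book")
      }
      conc[names(supplied)] <- unname(supplied)
      conc
    }), class = "fortification_standard")
  if (!isTRUE(std$program_id %in% program_ids())) {
    validation_stop(problem("program.program_id",
                            sprintf("must be one of %s", paste(program_ids(), collapse = ", "))),
                    "parameter book")
  }
  d <- raw$demand
  demand <- structure(list(
    population_by_year = as_year_series(d$population_by_year),
    per_capita_salt_g_per_day = as.numeric(d$per_capita_salt_g_per_day %||% NA),
    compliance_fraction = as.numeric(d$compliance_fraction %||% NA),
    days_per_year = as.numeric(d$days_per_year %||% 365)
  ), class = "demand_params")
  f <- raw$finance
  finance <- structure(list(
    discount_rate = as.numeric(f$discount_rate %||% NA),
    equipment_life_years = as.numeric(f$equipment_life_years %||% NA),
    base_currency_year = as.integer(f$base_currency_year %||% NA),
    usd_deflator_by_year = as_year_series(f$usd_deflator_by_year %||% list()),
    etb_cpi_by_year = as_year_series(f$etb_cpi_by_year %||% list()),
    etb_per_usd_base_year = as.numeric(f$etb_per_usd_base_year %||% NA)
  ), class = "finance_params")
  p <- raw$premix
  premix <- structure(list(
    sprayed_nutrients = as.character(unlist(p$sprayed_nutrients %||% character())),
    extruded_nutrients = as.character(unlist(p$extruded_nutrients %||% character())),
    extruded_inclusion_rate_kg_per_mt = as.numeric(p$extruded_inclusion_rate_kg_per_mt %||% 0),
    extruded_price_per_kg = as.numeric(p$extruded_price_per_kg %||% 0),
    shipping_handling_per_mt_salt = as.numeric(p$shipping_handling_per_mt_salt %||% 0),
    overage_fraction = as.numeric(p$overage_fraction %||% 0),
    catalog = as_catalog(p$catalog %||% list())
  ), class = "premix_spec")
  activities <- lapply(raw$activities, function(a) {
    structure(list(
      activity_id = as.character(a$activity_id %||% NA),
      label = as.character(a$label %||% a$activity_id %||% ""),
      phase = a$phase %||% NA_character_,
      stakeholder = a$stakeholder %||% NA_character_,
      category = a$category %||% NA_character_,
      cost_rule = normalize_cost_rule(a$cost_rule %||% list()),
      active_years = parse_active_years(a$active_years)
    ), class = "activity_schedule")
  })
  book <- structure(list(
    book_id = as.character(raw$book_id),
    scenario = as.character(raw$scenario %||% ""),
    baseline_book_id = if (is.null(raw$baseline_book_id)) NULL else as.character(raw$baseline_book_id),
    horizon = list(start = as.integer(raw$horizon$start), end = as.integer(raw$horizon$end)),
    phase_in_years = as.integer(raw$phase_in_years %||% 0),
    program = std,
    demand = demand,
    finance = finance,
    premix = premix,
    activities = activities
  ), class = "parameter_book")
  probs <- validate_parameter_book(book)
  if (length(probs)) validation_stop(probs, sprintf("parameter book '%s'", book$book_id))
  book
}

parse_active_years <- function(x) {
  if (is.null(x)) return(integer())
  if (is.list(x) && !is.null(x$from)) return(as.integer(x$from):as.integer(x$to))
  sort(unique(as.integer(unlist(x))))
}

#' Save a parameter book to YAML
#'
#' Writes the same schema [load_parameter_book()] reads; a save/load
#' round-trip reproduces the book field-by-field.
#'
#' @param book A validated `parameter_book`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_parameter_book <- function(book, path) {
  stopifnot(inherits(book, "parameter_book"))
  to_map <- function(v) as.list(stats::setNames(as.numeric(v), names(v)))
  out <- list(
    schema = BOOK_SCHEMA,
    book_id = book$book_id,
    scenario = book$scenario,
    baseline_book_id = book$baseline_book_id,
    horizon = list(start = book$horizon$start, end = book$horizon$end),
    phase_in_years = book$phase_in_years,
    program = list(
      program_id = book$program$program_id,
      concentrations = to_map(book$program$concentrations)
    ),
    demand = list(
      population_by_year = to_map(book$demand$population_by_year),
      per_capita_salt_g_per_day = book$demand$per_capita_salt_g_per_day,
      compliance_fraction = book$demand$compliance_fraction,
      days_per_year = book$demand$days_per_year
    ),
    finance = list(
      discount_rate = book$finance$discount_rate,
      equipment_life_years = book$finance$equipment_life_years,
      base_currency_year = book$finance$base_currency_year,
      usd_deflator_by_year = to_map(book$finance$usd_deflator_by_year),
      etb_cpi_by_year = to_map(book$finance$etb_cpi_by_year),
      etb_per_usd_base_year = book$finance$etb_per_usd_base_year
    ),
    premix = list(
      sprayed_nutrients = as.list(book$premix$sprayed_nutrients),
      extruded_nutrients = as.list(book$premix$extruded_nutrients),
      extruded_inclusion_rate_kg_per_mt = book$premix$extruded_inclusion_rate_kg_per_mt,
      extruded_price_per_kg = book$premix$extruded_price_per_kg,
      shipping_handling_per_mt_salt = book$premix$shipping_handling_per_mt_salt,
      overage_fraction = book$premix$overage_fraction,
      catalog = lapply(seq_len(nrow(book$premix$catalog)), function(i) {
        as.list(book$premix$catalog[i, ])
      })
    ),
    activities = lapply(book$activities, function(a) {
      yrs <- a$active_years
      list(
        activity_id = a$activity_id, label = a$label, phase = a$phase,
        stakeholder = a$stakeholder, category = a$category,
        cost_rule = a$cost_rule,
        active_years = if (identical(yrs, yrs[1]:yrs[length(yrs)])) {
          list(from = yrs[1], to = yrs[length(yrs)])
        } else as.list(yrs)
      )
    })
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# ---- program nesting report ---------------------------------------------

#' Check nutrient nesting and shared blocks across a scenario's books
#'
#' For the books of one consumption scenario, confirms that the non-zero
#' nutrient sets nest monotonically (iodized < dual < triple < quad, each
#' adding its defining nutrient) and that demand and finance blocks are
#' identical across books. Report-only: returns discrepancies, never errors.
#'
#' @param books List of `parameter_book` objects (>= 2 programs).
#' @return Character vector of discrepancies (empty when consistent).
#' @export
validate_program_nesting <- function(books) {
  stopifnot(length(books) >= 2)
  disc <- character()
  progs <- vapply(books, function(b) b$program$program_id, character(1))
  ord <- order(match(progs, program_ids()))
  books <- books[ord]; progs <- progs[ord]
  if (anyDuplicated(progs)) {
    disc <- c(disc, sprintf("duplicate program(s): %s",
                            paste(unique(progs[duplicated(progs)]), collapse = ", ")))
  }
  nonzero <- lapply(books, function(b) {
    conc <- b$program$concentrations
    names(conc)[conc > 0]
  })
  for (i in seq_along(books)) {
    want <- program_nutrients(progs[i])
    lack <- setdiff(want, nonzero[[i]])
    for (nut in lack) disc <- c(disc, sprintf("%s lacks %s", progs[i], nut))
    if (i > 1 && length(setdiff(nonzero[[i - 1]], nonzero[[i]]))) {
      disc <- c(disc, sprintf("%s does not nest %s's nutrients", progs[i], progs[i - 1]))
    }
  }
  ref <- books[[1]]
  for (b in books[-1]) {
    if (!isTRUE(all.equal(unclass(ref$demand), unclass(b$demand)))) {
      disc <- c(disc, sprintf("%s: demand block differs from %s", b$book_id, ref$book_id))
    }
    if (!isTRUE(all.equal(unclass(ref$finance), unclass(b$finance)))) {
      disc <- c(disc, sprintf("%s: finance block differs from %s", b$book_id, ref$book_id))
    }
  }
  disc
}
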