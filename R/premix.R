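#' Fortificant compound mass per metric ton of salt
#'
#' A target concentration of `c` mg of nutrient per kg of salt is `c` g of
#' nutrient per MT of salt; dividing by the compound's nutrient mass fraction
#' and converting g to kg gives kg of fortificant compound per MT:
#' `c * 1e-3 / fraction`. E.g. iodine at 30 mg/kg delivered as potassium
#' iodate (mass fraction 126.90/214.00) needs ~0.0506 kg of KIO3 per MT.
#'
#' @param concentration_mg_per_kg Nutrient concentration, mg/kg salt, > 0.
#' @param nutrient_mass_fraction Fraction of compound mass that is nutrient,
#'   in (0, 1].
#' @return kg of compound per MT of salt.
#' @export
compound_mass_per_mt <- function(concentration_mg_per_kg, nutrient_mass_fraction) {
  if (!is.numeric(nutrient_mass_fraction) || nutrient_mass_fraction <= 0) {
    stop("compound_mass_per_mt: `nutrient_mass_fraction` must be > 0", call. = FALSE)
  }
  if (!is.numeric(concentration_mg_per_kg) || concentration_mg_per_kg < 0) {
    stop("compound_mass_per_mt: concentration must be >= 0", call. = FALSE)
  }
  concentration_mg_per_kg * 1e-3 / nutrient_mass_fraction
}

# fortificant-only cost of the sprayed stream, USD per MT of salt
sprayed_fortificant_cost_per_mt <- function(standard, spec, catalog = spec$catalog) {
  nutrients <- spec$sprayed_nutrients
  if (!length(nutrients)) return(0)
  total <- 0
  for (nut in nutrients) {
    row <- catalog[catalog$nutrient == nut, , drop = FALSE]
    if (nrow(row) == 0) {
      stop(sprintf("premix: no fortificant catalog entry for nutrient '%s'", nut),
           call. = FALSE)
    }
    conc <- standard$concentrations[[nut]]
    mass <- compound_mass_per_mt(conc, row$nutrient_mass_fraction[1])
    total <- total + mass * row$price_per_kg_compound[1] * (1 + spec$overage_fraction)
  }
  total
}

# raw cost of the extruded stream (inclusion x delivered price), USD/MT salt
extruded_raw_cost_per_mt <- function(spec) {
  spec$extruded_inclusion_rate_kg_per_mt * spec$extruded_price_per_kg
}

# split the per-MT shipping/handling adder between streams, pro rata to cost
shipping_split <- function(spec, sprayed, extruded) {
  total <- sprayed + extruded
  if (total <= 0) return(c(sprayed = 0, extruded = 0))
  c(sprayed = spec$shipping_handling_per_mt_salt * sprayed / total,
    extruded = spec$shipping_handling_per_mt_salt * extruded / total)
}

#' Cost per MT of the sprayed premix stream
#'
#' Sum over sprayed nutrients of compound mass x catalog price x
#' (1 + overage), plus the sprayed share of the shipping/handling adder.
#'
#' @param standard A [fortification_standard()].
#' @param spec A [premix_spec()].
#' @param catalog Fortificant catalog (defaults to the spec's own).
#' @return USD per MT of fortified salt.
#' @export
sprayed_premix_cost_per_mt <- function(standard, spec, catalog = spec$catalog) {
  sprayed <- sprayed_fortificant_cost_per_mt(standard, spec, catalog)
  ship <- shipping_split(spec, sprayed, extruded_raw_cost_per_mt(spec))
  sprayed + ship[["sprayed"]]
}

#' Cost per MT of the extruded premix stream
#'
#' The extruded, encapsulated premix is costed as a delivered black box:
#' inclusion rate (kg per MT of salt) times delivered price (USD/kg), plus
#' the extruded share of the shipping/handling adder.
#'
#' @param spec A [premix_spec()].
#' @param sprayed_cost_per_mt Fortificant cost of the sprayed stream, used
#'   only to prorate the shipping adder (default 0: all shipping to the
#'   extruded stream when it is the only one).
#' @return USD per MT of fortified salt.
#' @export
extruded_premix_cost_per_mt <- function(spec, sprayed_cost_per_mt = 0) {
  extruded <- extruded_raw_cost_per_mt(spec)
  if (extruded <= 0) return(0)
  ship <- shipping_split(spec, sprayed_cost_per_mt, extruded)
  extruded + ship[["extruded"]]
}

# iodine-only premix spec used during the phase-in years of expansion books
baseline_premix_spec <- function(spec) {
  base <- spec
  base$sprayed_nutrients <- "iodine"
  base$extruded_nutrients <- character()
  base$extruded_inclusion_rate_kg_per_mt <- 0
  base$extruded_price_per_kg <- 0
  base
}

#' Total premix cost per MT of fortified salt
#'
#' @param book A `parameter_book`.
#' @param phase `"full"` for the full program formulation, `"baseline"` for
#'   the iodine-only formulation used during phase-in years.
#' @return USD per MT of fortified salt.
#' @export
premix_cost_per_mt <- function(book, phase = c("full", "baseline")) {
  phase <- match.arg(phase)
  spec <- book$premix
  standard <- book$program
  if (phase == "baseline") spec <- baseline_premix_spec(spec)
  sprayed <- sprayed_fortificant_cost_per_mt(standard, spec)
  extruded <- extruded_raw_cost_per_mt(spec)
  # total is invariant to how the shipping adder is split
  sprayed + extruded +
    if (sprayed + extruded > 0) spec$shipping_handling_per_mt_salt else 0
}

#' Annual premix cost
#'
#' Premix cost per MT times the fortified-salt demand of the year. During an
#' expansion book's phase-in years, salt iodization continues as usual: the
#' iodine-only baseline formulation is costed instead of the full program
#' formulation.
#'
#' @param book A `parameter_book`.
#' @param year Calendar year within the horizon.
#' @return USD.
#' @export
annual_premix_cost <- function(book, year) {
  if (!year %in% book_years(book)) {
    stop(sprintf("premix: year %d outside horizon", year), call. = FALSE)
  }
  phase <- if (year %in% phase_in_years_of(book)) "baseline" else "full"
  premix_cost_per_mt(book, phase) * annual_fortified_salt_mt(book$demand, year)
}
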