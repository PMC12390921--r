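---
title: "Costing methods for salt fortification programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing methods for salt fortification programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortcost)
```

## The costing model

`fortcost` implements a deterministic, activity-based cost model for
large-scale salt fortification programs from a societal perspective: every
cost is counted regardless of whether industry, government or development
partners pay it. A program — iodized salt, or its expansion to dual
(+ folic acid), triple (+ vitamin B-12) or quadruple (+ zinc) fortified
salt — is described declaratively in a *parameter book*, and the engine
turns the book into per-year costs and annual-average metrics over a fixed
calendar horizon (2024–2033, ten years, in the shipped books).

The unit of the model is the *activity*: a line item such as premix supply,
refinery fortification operations, QA/QC, internal training, government
monitoring of refineries/imports/markets/households, social marketing, or
administration. Each activity has a phase (`startup` or `recurring`), a
paying stakeholder, a closed-vocabulary category used for reporting, the
years it is active, and one of four cost rules:

* `fixed_annual` — a constant base-year USD amount in each active year;
* `capital` — a lump sum annualized to an equivalent annual cost (EAC);
* `per_mt` — a USD rate per metric ton of fortified salt;
* `premix` — delegation to the premix module, which prices the formulation
  from the fortification standard.

All amounts inside a book are base-year (2021) USD. Historical amounts are
normalized at entry with `to_base_usd()`: USD via the GDP implicit price
deflator ratio, Ethiopian Birr via the local CPI ratio followed by the
base-year average exchange rate. The model produces real (2021) dollars
throughout; nominal-Birr projections are out of scope.

## Demand

Fortified-salt demand in year $t$ is

$$Q_t = \text{pop}_t \times g \times d \times 10^{-6} \times c$$

with $g$ the per-capita fortifiable salt intake in g/day (discretionary plus
manufactured-food salt; 6.7 g/d in the current-consumption scenario, 5 g/d
in the reduced-consumption scenario — the 90% fortifiable share of total
intake is already folded into these values), $d$ the days per year
(365, configurable; a sub-0.1% convention), $10^{-6}$ the g→MT conversion,
and $c$ the compliance fraction (0.89): the share of the salt supply
actually fortified to the national standard. Demand is linear in each
input, which several property tests exploit.

## Premix

Fortification standards quote *nutrient* mass (mg of iodine per kg of
salt), while fortificants are bought as *compounds*. The catalog records
each compound's nutrient mass fraction — potassium iodate carries iodine at
$126.90/214.00 = 0.5931$ of its mass, from molar masses — so a dose of $x$
mg/kg needs $x \cdot 10^{-3}/f$ kg of compound per MT of salt.

Two delivery technologies are modelled, reflecting stability chemistry:
iodine (and for dual fortified salt, folic acid in a sodium-carbonate
solution) is *sprayed*; vitamin B-12 and zinc are incompatible with spray
solutions, so triple and quadruple programs deliver the extra nutrients as
*extruded, encapsulated* salt-like grains blended into iodized salt. The
extruded premix is costed as a delivered black box — inclusion rate (kg per
MT of salt) × delivered price (USD/kg) — rather than rebuilding
semolina/oil/extrusion economics; the reported fortificant shares of the
extruded premix cost are carried as fixture metadata for consistency
checking only. A per-MT-of-salt shipping/handling adder is split between
the sprayed and extruded streams pro rata to their cost (the split is a
reporting convention; the total is invariant to it). Overage defaults to
zero: the modelled formulations are stable for at least six months at high
temperature, so no deliberate excess is added.

During an expansion book's *phase-in years* (the first two horizon years),
salt iodization continues as usual: the premix rule prices the iodine-only
baseline formulation, and full-program premix begins in year 3.

## Capital and startup costs

Capital is annualized as the equivalent annual cost
$K \cdot r / \left(1 - (1+r)^{-n}\right)$ with $r = 3\%$ and $n = 10$ years
(straight-line in the $r = 0$ limit). The EAC is charged in every horizon
year: a startup outlay incurred during phase-in is spread over the whole
10-year horizon, matching how such costs are conventionally reported as a
constant "annualized cost". Non-equipment startup costs (relabeling,
planning, training) use the same rate and life; at their magnitude
(≤ $3,000/y) the choice between this and any alternative convention is
smaller than the reporting rounding. Discounting appears *only* inside the
EAC — reported annual averages are undiscounted means of per-year totals.

## Phase-in accounting

The engine evaluates one book at a time, so phase-in is expressed in the
book itself rather than by cross-referencing the baseline book at run time:

* the `premix` rule switches to the iodine-only formulation in phase-in
  years (the engine knows this from `phase_in_years` alone);
* recurring activities whose level changes with the program split into two
  `fixed_annual` entries — a baseline-level entry active in years 1–2 and a
  full-program entry active in years 3–10;
* `startup` activities are constrained to phase-in years and use the
  `capital` rule.

A consequence the tests verify exactly: in years 1–2 an expansion book's
total equals the iodized book's total plus the annualized startup costs.

## Reporting conventions

* Annual averages are plain means over the horizon years.
* Per-capita divides by the mean population over the horizon.
* Per-MT divides by the mean annual *fortified* salt quantity; a
  `per_mt_denominator = "fortifiable"` switch uses the pre-compliance
  quantity instead. Published per-MT figures do not state their denominator
  convention and are not mutually consistent with any single series, so the
  convention is explicit and switchable here.
* Percent shares are computed from unrounded averages; the rounded column
  rounds half-up to whole percents *except* that shares below 0.5% round
  down to 0 (the convention of the published tables). Totals are reported
  to the nearest 1,000 USD and per-MT values to one decimal; internal
  arithmetic is never rounded.
* Stakeholder groups aggregate categories: `premix`; `refinery_related`
  (fortification operations, QA/QC, training, administration, relabeling);
  `government_related` (all monitoring, planning, capacity building, social
  marketing, administration). Social marketing sits with government, as in
  the published grouping.

Degenerate inputs are rejected rather than silently handled: a zero total
makes percent shares an error, missing index or population years name the
year, and every book invariant violation is reported with its field path in
one classed validation error.

## Sensitivity analysis

The deterministic sensitivity analysis varies three uncertain components by
a symmetric fraction (default ±30%): the premix price (all catalog prices,
the extruded delivered price and the shipping adder — including the
potassium iodate), refinery fortification costs (that category only, not
QA/QC/training/administration), and government monitoring costs. Market
monitoring is excluded from the monitoring component by default because the
stated composition covers refinery, import and household monitoring; the
mapping is overridable (`monitoring_categories`). Each variation re-runs
the full engine on scaled inputs — no closed-form shortcut — so the exact
symmetry of the one-way excursions and the identity
$\text{worst} - \text{best} = 2f \sum_k c_k$ (with $c_k$ the varied
components' per-MT contributions) act as independent oracles in the tests.
No probabilistic analysis is offered; the model is strictly deterministic.

## The Ethiopia fixture and its calibration

The shipped fixture covers eight books (four programs × two consumption
scenarios). The published evidence base reports activity-level 10-year
annual averages, not the underlying unit quantities and prices (those come
from stakeholder interviews), so the fixture deliberately calibrates at the
activity level:

* non-premix activity amounts are entered as `fixed_annual` values chosen
  so the 10-year average equals the published cell, with phase-in splits as
  above (full-program amount = (10·average − 2·baseline)/8);
* premix prices are *backed out* at generation time from the published
  premix averages given the demand series: delivered KIO₃ and folic-acid
  prices for the sprayed stream, and a delivered extruded-premix price at a
  10 kg/MT inclusion rate for triple/quad. Shipping and storage are folded
  into these delivered prices (the shipping adder is 0 in the fixture), and
  the calibrated values are realistic for delivered fortificants;
* startup capital equals the published annualized average times the annuity
  factor;
* the population series is synthetic, in the style of a UN World Population
  Prospects medium-variant projection for Ethiopia (126.2M in 2024 growing
  2.1%/y), with its level calibrated so the scenario-1 iodized program
  costs ≈ 7.0 USD/MT of fortified salt. It is labelled replaceable: swap in
  a real projection series for policy use.

What golden tests against this fixture do show: the engine's aggregation,
phasing, annualization, incremental and share logic reproduce every
published activity cell, grand total, incremental total and percent share
within the tables' own rounding unit (±1,000 USD; a few published columns
are internally inconsistent by exactly that unit). What they cannot show:
correctness of the unpublished unit-level inputs, or the published
per-capita/per-MT rows, which are not mutually reproducible from any single
demand series and are therefore reported under this package's explicit
conventions instead. Unit-level costing (quantities × unit prices feeding
`fixed_annual`/`per_mt`/`capital` rules) is exercised by the randomized
book generator rather than the fixture.

`random_book(seed, size)` generates structurally valid books — nested
standards, plausible demand/finance blocks, 5–30 activities across
categories, phases and rules — for property-based testing (conservation,
linearity, round-trips). Generation is deterministic in the seed and
restores the caller's RNG state.

## Problem sizes

All shipped computations are small by construction: 10 horizon years, 12–21
activities per book, eight fixture books; the full golden-value sweep runs
in well under a second, and the property suites use dozens of randomized
books of ≤ 30 activities.

## Known limitations

* Salt-market structure (artisanal vs refined supply, imports vs domestic
  production) is reduced to one compliance fraction.
* The extruded premix is a delivered price, not a production model; a local
  production scenario would need its own costing.
* No cost-effectiveness or cost-benefit layer (cost per DALY or NTD
  averted), and no consumer-price pass-through modelling.
* Currency normalization uses index tables supplied in the book; there is
  no inflation forecasting.
* Published tornado-diagram extremes for the sensitivity analysis are not
  exactly derivable from the published per-MT components; the package
  reports its own internally consistent values and tests their linearity
  identities instead.
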