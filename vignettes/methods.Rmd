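---
title: "Methods: from commodity balances to age-sex nutrient supplies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from commodity balances to age-sex nutrient supplies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrisupply)
```

`nutrisupply` estimates dietary nutrient supplies — availability, not
intake — from commodity-balance data. This vignette is the package's own
account of the model, its assumptions, the choices made where the design
was genuinely open, and what the tests do and do not demonstrate.

## The supply model stage by stage

### Disaggregation

Balance sheets publish broad residual categories ("Fruits, other",
"Cereals, other") whose constituents differ widely in nutrient density.
The pipeline replicates the balance-sheet method at the level of the
constituent foods: per food, domestic supply is production plus imports
minus exports, with processed trade forms first converted back to their
primary equivalent via multiplicative factors. Stock changes and non-food
utilisation are *not* reported per constituent, so each food receives
food supply through the parent's food-to-domestic-supply ratio. Two
assumptions follow: (i) all constituents of a category share the parent's
non-food utilisation fraction, and (ii) processed trade is fully captured
by the primary-equivalent conversion. Offal categories disaggregate
poorly from production data, so offal supply is instead re-derived from
meat: carcass weight × carcass-to-live factor × live-to-offal factor per
animal type, summed. Categories with little internal nutritional
variability can be passed through aggregated via a per-category
`disaggregate: no` flag.

Agreement between summed constituents and the parent is scored with a
1:1-line coefficient of determination,
`1 − Σ(ref − model)² / Σ(ref − mean(ref))²`. This is a residual statistic
about the identity line, not a squared correlation; it is negative
whenever the disagreement exceeds the reference variance, and it is
reported as computed rather than floored at zero.

A computed domestic supply can be negative when exports (including
re-exports) exceed production plus imports. Downstream steps are
multiplicative and require non-negative masses, so negative supplies are
clamped to zero with a logged warning rather than propagated.

### Residual fruit and vegetable correction

Residual "nes" categories hold either genuinely unclassified foods or
the balance of discordant sources. The data-quality flag distinguishes
them: *official* nes is kept as its own food (tagged
`<group>_nes_retained`); *estimated*/*imputed* nes is a balancing
artifact and is redistributed over the reported foods in proportion to
their supplies, conserving group mass. *Unofficial* nes is retained with
a warning by default — the flag asserts a real observation, just not a
government one — with a configuration switch to treat it as
redistributable. Where a country has census production shares, the whole
group (residual plus reported) is re-split by those shares for the most
recent year, and earlier years are dropped for that country only.
Countries reporting five or fewer non-residual categories in a group are
excluded outright; the threshold is configurable
(`exclusion_threshold`, default 5) and exclusion is monotone in it.

### Edible conversion and processed foods

Nutrient densities are per 100 g of *edible* portion, so supplies must
leave the primary basis: carcass-to-retail factors (meat and seafood
only; plant farm-to-retail losses are already embedded in balance data)
followed by discard fractions (peels, shells, bones). Both factors are
at most 1, so edible ≤ retail ≤ primary, and a per-food loss ledger is
returned for audit. Seafood uses one averaged factor per category
(fish classes, crustaceans, cephalopods, molluscs), supplied in the
factor table rather than code.

Refined flours have distinct nutrient profiles, so for wheat, maize,
millet and sorghum the regionally processed fraction of the grain is
milled to a new `<grain>_flour` food at a configured extraction rate;
the remainder keeps the whole-grain identity. Rice is excluded — it is
reported at milled weight already. The split is applied on the
edible-basis supply (the order relative to edible conversion is not
dictated by the method; applying it post-conversion keeps flour and
whole grain on a common basis, and the choice is isolated in
`edible_convert()`). Grain-to-flour extraction rates and regional
processed fractions are configuration inputs; the synthetic defaults
(0.78 for wheat, a widely cited straight-run extraction figure, 0.9 for
maize) are placeholders that every test supplies explicitly. Cheese is
folded into the milk pool by dividing its densities by a milkfat
conversion factor; soft fresh cheeses are instead rescaled so their fat
density matches the configured whole-milk fat content.

### Monte Carlo nutrient estimation

A single food category rarely matches one composition entry. All
equally good candidate entries are kept, resolved per country through an
ordered chain of composition tables (e.g. a regional table first, a
reference national table next); a food absent from the whole chain but
present elsewhere receives one synthetic candidate equal to the
per-nutrient mean over all tables. On each iteration one candidate per
food is drawn uniformly, independently across foods and iterations, and
contributions `supply × density / 100` are summed; medians and
2.5th/97.5th percentiles over iterations (default `n_iter = 1000`) give
the estimate and its 95% uncertainty interval. The interval reflects
composition-table ambiguity only — it is not sampling error and not
dietary variance.

Numerical choices, each centralised: percentiles use the type-7
order-statistic definition with linear interpolation; a nutrient missing
from a chosen candidate falls back to the candidate pool's mean for that
nutrient (absent from the whole pool, zero, logged); the RNG substream
for each country (and each food within a run) is derived from the base
seed plus a 31-bit FNV-1a hash of the identifier, so processing order
cannot change any result and results are bit-for-bit reproducible given
a seed. The default nutrient set has 23 entries including selenium and
excluding sodium; sodium from added salt is out of scope by
construction (balance data carry no added-salt information), and the
set is an argument, not a constant.

### Fortification

Guideline fortificant ranges are resolved to their *lower* bound —
part of the added nutrient is lost in processing, storage and transport
— and applied as `vehicle supply (kg/day) × amount × industrially
milled fraction`, the last factor defaulting to 1 for non-flour
vehicles. Because guideline levels are fixed values rather than sampled
quantities, fortification is a deterministic shift applied after the
Monte Carlo stage, moving the median and both interval bounds equally;
it therefore never narrows or widens an interval, and removing all
rules reproduces the unfortified output exactly. The overlay applies to
the most recent year only (configurable), and mandatory and voluntary
rules are both applied by default with a status filter. For flour
vehicles the fortified supply is the flour row only — fortificants are
added at milling, not to grain later ground at home.

### Age-sex disaggregation

National supplies are normalised to a 2,000-kcal reference diet
(`reference_kcal`, configurable), multiplied by each group's relative
intake ratio for the food's category, and converted back to absolute
amounts using group calorie supplies allocated in proportion to energy
requirements (national energy ÷ population-weighted mean requirement =
a surplus factor shared by all groups). Foods without a matching intake
category — starchy vegetables, sweeteners, eggs — take the national
energy-adjusted value in every group (`uniform`); foods consumed
essentially only by adults — alcohol, stimulants, spices — are zero
under age 20 (`adult_only`); oils and oilseeds map to fatty-acid proxy
categories, treated exactly like food-group ratios (an interpretation:
the ratio multiplies the food's adjusted supply either way). Groups
without an intake estimate — children and adolescents in the 34-group
layout of 26 adult plus 8 child brackets — take the national average
value.

Ratios average to 1 over adult groups by construction, but the chain
above still does not make population-weighted group supplies reproduce
the national values exactly (child groups take averages; ratios are
estimates), so a final explicit stage rescales every food's group
supplies by the common factor `national / weighted mean`. This is the
simplest mechanism that satisfies the totalling property, and it is a
separate, inspectable function (`enforce_population_consistency`)
rather than a hidden correction. Note the canonical worked example
(20 → 22 → 2,640 → 29) is the chain *before* this rescale.

Group nutrient summaries reuse the Monte Carlo machinery with one
candidate draw per food per iteration shared across all groups, keeping
group totals coupled to the national totals within each iteration.

## The synthetic world

`generate_world()` emulates every input table: child commodity flows
whose parents are exact sums by construction (so disaggregation recovery
is testable against an exact oracle), log-normal quantities to exercise
wide magnitude ranges, configurable residual-category scenarios
(`none`, `official`, `estimated`, `sparse` — the last producing a
country that trips the exclusion rule), composition tables with 1–3
candidates per food and deliberate regional gaps to exercise the
fallback chain, intake ratios population-weighted to 1, demographics
over 34 groups with requirements in the 1,300–2,900 kcal/day range, and
flour fortification rules with industrial fractions. Defaults describe
a normally reporting world: 3 countries, 8 foods per disaggregated
category (comfortably above the exclusion threshold, as real category
inventories are), 2 years.

What the generator does *not* emulate: realistic dietary magnitudes or
correlations between foods, real country inventories, reporting-quality
gradients, or trend structure over years. Passing tests therefore
demonstrate the correctness of the accounting — conservation,
recovery, coupling, determinism — not calibration against any real
national diet.

## Problem sizes and degenerate inputs

The test suite runs the pipeline at 2–3 countries, 1–2 years and 20–200
Monte Carlo iterations, with one 10,000-iteration run for the
enumeration comparison on a 2-food × 2-candidate instance; these sizes
were chosen so the whole suite exercises every stage in seconds while
the Monte Carlo checks retain narrow sampling error. Degenerate cases
are defined behaviour, not errors: a single candidate per food gives a
zero-width interval; `n_iter = 1` is a valid run; zero supplies
propagate as zeros; an empty table round-trips as an empty table.
Errors are reserved for contract violations — negative masses, unknown
flags, undefined ratios (zero parent domestic supply with positive food
supply), constant references in the r² statistic, a food absent from
every composition table.

## Limitations

Estimates are supplies, not consumption: no home waste, cooking or
preparation losses, so values upper-bound intake. Added salt is not
modelled. Fortification uses lower-bound guideline levels, not measured
fortificant content. The consistency rescale distributes the
child-average discrepancy proportionally over all groups, which is one
of several defensible allocations. And the uncertainty interval captures
composition ambiguity only — input-data quality, the dominant error
source in poorly reporting countries, is outside the model.
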