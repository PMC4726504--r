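# nutrisupply

Estimation of national and demographic-group dietary nutrient supplies
from food-balance-sheet style commodity data.

Food balance sheets account for the production, trade and utilisation of
food commodities and yield per-capita *availability* — not intake — of a
limited set of broad categories, with no micronutrient information and no
age or sex detail. `nutrisupply` implements a pipeline that expands such
data into per-capita edible supplies of individual foods and propagates
them into supply distributions for 23 nutrients, nationally and for 34
age-sex demographic groups, for researchers in global nutrition and food
security who need nutrient-level, subpopulation-level estimates where only
commodity balances exist.

## The model

For each broad category *P* with constituent foods *i*, the balance-sheet
method is replicated from production and trade data:

- domestic supply `D_i = production_i + imports_i − exports_i` (processed
  trade forms folded back to primary equivalents first), and each food
  receives food supply in proportion to the parent's food ratio:
  `F_i = D_i · (F_P / D_P)`. Agreement is scored with the 1:1-line
  statistic `r² = 1 − Σ(D_P − ΣD_i)² / Σ(D_P − mean(D_P))²`.
- Residual *nes* ("not elsewhere specified") fruit and vegetable amounts
  flagged *estimated*/*imputed* are redistributed proportionally over the
  reported foods (or re-split by agricultural-census shares where
  available); *official* nes is retained as its own category; countries
  reporting five or fewer categories in a group are excluded.
- Primary weights become edible weights via carcass→retail factors and
  discard fractions; for wheat, maize, millet and sorghum a regionally
  processed fraction is milled to refined flour at a configured extraction
  rate (rice is already reported milled); cheese densities divide by a
  milkfat factor to join the milk pool.
- Nutrient supplies are estimated by Monte Carlo: on each of *n*
  iterations one candidate composition entry is drawn uniformly per food
  from a regional table chain (with a global-average fallback), the
  totals `Σ_i supply_i · density_i / 100` are accumulated, and the median
  and 2.5/97.5 percentiles over iterations form the estimate and its 95%
  uncertainty interval.
- Fortification adds `supply(kg/day) · lower guideline amount · industrial
  milling fraction` as a deterministic shift for the most recent year.
- Age-sex supplies: national supplies are normalised to a 2,000 kcal
  diet, multiplied by each group's relative intake ratio, converted back
  to absolute amounts with calories allocated in proportion to group
  energy requirements, and finally rescaled so population-weighted group
  supplies reproduce the national values exactly.

A seeded generator (`generate_world()`) emulates every input table so the
full pipeline runs and is tested without external data.

## Worked example

The canonical single-country example, built into `country_x_fixture()`:
a country supplies 30 g/day of apples at a national energy supply of
3,000 kcal/day; women aged 50–54 consume 10% more fruit than average,
require 2,200 kcal/day in a population averaging 2,500 kcal/day.

```r
library(nutrisupply)
fx <- country_x_fixture()

energy_adjust(30, 3000)                        # 20   g/day per 2,000 kcal
apply_group_ratio(20, "mapped", 1.10, TRUE)    # 22   g/day (10% more fruit)
group_energy_supply(3000, fx$groups)[1]        # 2640 kcal/day for the group
deadjust(22, 2640)                             # 29.04 g/day absolute, ~29
```

The potato contribution on one Monte Carlo iteration — 114 g/day at a
70 kcal/100 g candidate — is 79.8 ≈ 80 kcal/day:

```r
mc_nutrient_supply(fx$supplies[2, ], fx$candidates["potatoes"],
                   n_iter = 1000, seed = 1)
#> # A tibble: 1 × 5
#>   nutrient median lower_95 upper_95 n_iterations
#>   <chr>     <dbl>    <dbl>    <dbl>        <int>
#> 1 calories   79.8     79.8     79.8         1000
```

A full synthetic run (parents equal the sum of their children by
construction, so disaggregation recovers them with r² = 1):

```r
b   <- generate_world(fixture_spec(seed = 1, n_countries = 2, years = 2011L))
res <- run_pipeline(b, pipeline_config(n_iter = 200, seed = 1))
res$validation
#>   parent_category     r2 n_points
#> 1 cereals_other        1        2
#> 2 fruit_other          1        2
#> 3 meat_other           1        2
#> 4 vegetables_other     1        2
head(res$nutrient_summaries, 3)
#>   country  year nutrient  median lower_95 upper_95 n_iterations
#> 1 C01      2011 calories    1.73     1.64     1.88          200
#> 2 C01      2011 vitamin_a   2.34     2.04     2.49          200
#> 3 C01      2011 iron        2.83     2.49     2.99          200
```

Each nutrient row is the median supply per person per day in that
nutrient's unit, with its 95% uncertainty interval from the composition
ambiguity (synthetic composition tables here, so magnitudes are
arbitrary). `res` also carries the corrected and edible supply tables,
exclusion and validation reports, fortified summaries, and per-group food
and nutrient supplies.

A thin command-line wrapper is installed as `exec/nutrisupply`
(subcommands `fixtures` and `run`).

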