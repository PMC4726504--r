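# Conversion of primary-equivalent weights to edible weights, and the
# processed-food transforms (refined-flour split, cheese-to-milk
# normalisation).

#' Convert primary (carcass/fresh) weight to retail weight
#'
#' Meat and seafood are reported at slaughterhouse or landed weight;
#' the carcass-to-retail factor removes bones, fat, guts or shells
#' discarded at sale. Plant commodities carry no such factor (farm-to-
#' retail losses are already in the source data) and pass through
#' unchanged: supply `NA` as the factor.
#'
#' @param primary Supply at primary basis (g/person/day), >= 0.
#' @param carcass_to_retail Factor in (0, 1], or `NA` for pass-through.
#' @return Retail-basis supply (g/person/day); vectorised.
#' @export
#' @examples
#' to_retail(100, 0.7) # 70
#' to_retail(100, NA)  # 100 (plant food)
to_retail <- function(primary, carcass_to_retail) {
  assert_nonneg(primary, "primary")
  f <- carcass_to_retail
  use <- !is.na(f)
  if (any(use) && (any(f[use] <= 0) || any(f[use] > 1) || any(!is.finite(f[use])))) {
    stop_input("`carcass_to_retail` must lie in (0, 1].")
  }
  ifelse(use, primary * f, primary)
}

#' Convert retail weight to edible weight
#'
#' Removes the discarded fraction by weight (peels, shells, bones left at
#' retail) so that supplies are on the same edible-portion basis as food
#' composition densities.
#'
#' @param retail Retail-basis supply (g/person/day), >= 0.
#' @param discard_fraction Fraction in [0, 1) discarded; `NA` means 0.
#' @return Edible-basis supply (g/person/day); vectorised.
#' @export
#' @examples
#' to_edible(100, 0.28) # 72
to_edible <- function(retail, discard_fraction) {
  assert_nonneg(retail, "retail")
  d <- ifelse(is.na(discard_fraction), 0, discard_fraction)
  if (any(!is.finite(d)) || any(d < 0) || any(d >= 1)) {
    stop_input("`discard_fraction` must lie in [0, 1).")
  }
  retail * (1 - d)
}

#' Split a grain supply into refined flour and whole grain
#'
#' For wheat, maize, millet and sorghum, the regionally processed fraction
#' of the grain is milled to flour at the given extraction rate, leaving a
#' whole-grain remainder that keeps the whole-grain nutrient identity.
#' Rice is excluded: it is already reported at milled weight.
#'
#' @param grain_supply Grain supply (g/person/day), >= 0.
#' @param grain Grain identifier; `"rice"` is rejected.
#' @param processed_fraction Fraction of the grain that is industrially
#'   processed, in [0, 1].
#' @param extraction_rate Flour mass obtained per unit milled grain,
#'   in (0, 1].
#' @return A list with `flour` and `whole` supplies (g/person/day).
#' @export
#' @examples
#' split_grain(100, "wheat", 0.8, 0.78) # flour 62.4, whole 20
split_grain <- function(grain_supply, grain, processed_fraction,
                        extraction_rate) {
  assert_nonneg(grain_supply, "grain_supply")
  if (any(tolower(grain) == "rice")) {
    stop_input("Rice is excluded from the flour split: it is reported at milled weight.")
  }
  assert_fraction(processed_fraction, "processed_fraction")
  assert_fraction(extraction_rate, "extraction_rate", lo_open = TRUE)
  list(
    flour = grain_supply * processed_fraction * extraction_rate,
    whole = grain_supply * (1 - processed_fraction)
  )
}

#' Convert cheese nutrient densities to whole-milk equivalents
#'
#' Milk supplies subsume all dairy; cheese entries join the milk
#' candidate pool after their densities are divided by the milkfat
#' conversion factor (the milk mass required per unit cheese).
#'
#' @param cheese_density Named numeric vector of nutrient densities per
#'   100 g cheese.
#' @param milkfat_factor Conversion factor, > 0 (typically > 1).
#' @return Densities per 100 g milk equivalent.
#' @export
#' @examples
#' cheese_to_milk_equivalent(c(calcium = 720), 6) # calcium 120
cheese_to_milk_equivalent <- function(cheese_density, milkfat_factor) {
  assert_nonneg(cheese_density, "cheese_density")
  assert_finite(milkfat_factor, "milkfat_factor")
  if (milkfat_factor <= 0) stop_input("`milkfat_factor` must be > 0.")
  cheese_density / milkfat_factor
}

#' Rescale soft-cheese densities to a target milk fat content
#'
#' Soft fresh cheeses (channa, khoa) are normalised so that their fat
#' density matches the configured whole-milk fat density; all nutrients
#' are scaled by the same factor.
#'
#' @param cheese_density Named numeric densities per 100 g; must include
#'   `fat`.
#' @param target_fat Whole-milk fat density (g/100 g), > 0.
#' @return Rescaled densities per 100 g milk equivalent.
#' @export
soft_cheese_to_milk <- function(cheese_density, target_fat) {
  assert_nonneg(cheese_density, "cheese_density")
  if (!"fat" %in% names(cheese_density)) {
    stop_input("`cheese_density` must include a `fat` entry.")
  }
  if (!is.finite(target_fat) || target_fat <= 0) {
    stop_input("`target_fat` must be > 0.")
  }
  if (cheese_density[["fat"]] <= 0) {
    stop_input("Cheese fat density must be > 0 to normalise.")
  }
  scale <- cheese_density[["fat"]] / target_fat
  cheese_density / scale
}

#' Convert a primary-basis supply table to edible basis
#'
#' Applies [to_retail()] then [to_edible()] per food using a factor
#' table, then splits the four refined-grain supplies into flour rows via
#' [split_grain()] (applied on the edible basis). Flour rows are new
#' foods named `"<grain>_flour"`; the grain row keeps the whole-grain
#' remainder. Returns the supply table at `basis = "edible"` together
#' with a mass-loss ledger.
#'
#' @param supplies Supply tibble at `basis = "primary"`.
#' @param edible_factors Tibble `food,carcass_to_retail,discard_fraction`
#'   (`carcass_to_retail` is `NA` for plant foods). Foods absent from the
#'   table pass through with no discard.
#' @param grain_processing Optional tibble
#'   `grain,region,processed_fraction,extraction_rate`.
#' @param region_map Optional tibble `country,region` used to pick the
#'   grain-processing row.
#' @return A list: `supplies` (edible basis, incl. flour rows), `ledger`
#'   (tibble `food,primary,edible,loss`).
#' @export
edible_convert <- function(supplies, edible_factors,
                           grain_processing = NULL, region_map = NULL) {
  supplies <- validate_supply_table(supplies)
  if (!all(supplies$basis == "primary")) {
    stop_input("`supplies` must be on the primary basis.")
  }
  assert_columns(edible_factors,
                 c("food", "carcass_to_retail", "discard_fraction"),
                 "edible factor table")
  df <- dplyr::left_join(supplies, edible_factors, by = "food")
  retail <- to_retail(df$amount_g_day, df$carcass_to_retail)
  edible <- to_edible(retail, df$discard_fraction)
  out <- tibble(
    country = df$country, year = df$year, food = df$food,
    amount_g_day = edible, basis = "edible"
  )
  ledger <- tibble(
    food = df$food, primary = df$amount_g_day, edible = edible,
    loss = df$amount_g_day - edible
  )

  if (!is.null(grain_processing)) {
    assert_columns(grain_processing,
                   c("grain", "region", "processed_fraction", "extraction_rate"),
                   "grain processing table")
    if (is.null(region_map)) {
      stop_input("`region_map` is required when `grain_processing` is given.")
    }
    assert_columns(region_map, c("country", "region"), "region map")
    gp <- dplyr::inner_join(region_map, grain_processing, by = "region",
                            relationship = "many-to-many")
    hit <- dplyr::inner_join(out, gp, by = c("country", food = "grain"))
    if (nrow(hit) > 0) {
      split <- split_grain(hit$amount_g_day, hit$food,
                           hit$processed_fraction, hit$extraction_rate)
      flour_rows <- tibble(
        country = hit$country, year = hit$year,
        food = paste0(hit$food, "_flour"),
        amount_g_day = split$flour, basis = "edible"
      )
      whole <- tibble(
        country = hit$country, year = hit$year, food = hit$food,
        amount_g_day = split$whole, basis = "edible"
      )
      key <- paste(out$country, out$year, out$food)
      out <- out[!key %in% paste(whole$country, whole$year, whole$food), ]
      out <- dplyr::bind_rows(out, whole, flour_rows)
    }
  }
  list(supplies = validate_supply_table(out), ledger = ledger)
}
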