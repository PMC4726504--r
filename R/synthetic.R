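# Seeded synthetic input bundles. Every table the pipeline consumes is
# generated here, schema-valid by construction, so the complete pipeline
# can run and be tested without any external data. Quantities are drawn
# log-normally to mimic the heavy-tailed spread of real commodity
# supplies.

#' Specification for a synthetic input bundle
#'
#' @param n_countries Number of countries, >= 1.
#' @param n_foods Number of foods per disaggregated category, >= 1.
#' @param years Integer vector of years covered.
#' @param seed Integer seed; bundles are deterministic given the seed.
#' @param nes_scenario Residual-category scenario: `"none"` (no nes
#'   supply), `"official"` (nes flagged official), `"estimated"` (nes
#'   flagged estimated/imputed), or `"sparse"` (first country reports
#'   few named fruit categories, triggering exclusion).
#' @param max_candidates Upper bound of the per-food candidate count
#'   (candidate multiplicity is uniform on 1..max_candidates).
#' @param ratio_dispersion Log-scale dispersion of the group intake
#'   ratios around 1.
#' @return A classed list of settings for [generate_world()].
#' @export
fixture_spec <- function(n_countries = 3L, n_foods = 8L,
                         years = 2010:2011, seed = 1L,
                         nes_scenario = c("estimated", "none", "official",
                                          "sparse"),
                         max_candidates = 3L, ratio_dispersion = 0.15) {
  nes_scenario <- match.arg(nes_scenario)
  n_countries <- as.integer(n_countries)
  n_foods <- as.integer(n_foods)
  if (is.na(n_countries) || n_countries < 1) {
    stop_input("`n_countries` must be >= 1.")
  }
  if (is.na(n_foods) || n_foods < 1) stop_input("`n_foods` must be >= 1.")
  if (length(years) < 1) stop_input("`years` must be non-empty.")
  if (max_candidates < 1) stop_input("`max_candidates` must be >= 1.")
  structure(
    list(n_countries = n_countries, n_foods = n_foods,
         years = as.integer(years), seed = as.integer(seed),
         nes_scenario = nes_scenario,
         max_candidates = as.integer(max_candidates),
         ratio_dispersion = ratio_dispersion),
    class = "fixture_spec"
  )
}

ADULT_BRACKETS <- c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49",
                    "50-54", "55-59", "60-64", "65-69", "70-74", "75-79",
                    "80+")
CHILD_BRACKETS <- c("0-4", "5-9", "10-14", "15-19")

#' Generate a complete synthetic input bundle
#'
#' Builds every table the pipeline consumes: child and parent commodity
#' flows (parents equal the sum of their children by construction, so
#' disaggregation recovers them exactly), category map, population,
#' fruit/vegetable group map with residual categories and flags, edible
#' factors, grain-processing rates, composition tables with 1 to
#' `max_candidates` candidate entries per food, a composition region map,
#' intake-category map and group ratios (population-weighted to 1 over
#' adult groups), demographics with energy requirements, and
#' fortification rules. Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A named list of tibbles (`flows_children`, `flows_parents`,
#'   `category_map`, `population`, `group_map`, `nes_flags`,
#'   `offal_factors`, `edible_factors`, `grain_processing`,
#'   `grain_region_map`, `composition`, `comp_region_map`, `gdd_map`,
#'   `gdd_ratios`, `demographics`, `fortification_rules`,
#'   `industrial_fractions`), plus the `spec`.
#' @export
generate_world <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop_input("`spec` must be a fixture_spec.")
  withr::with_seed(spec$seed, generate_world_impl(spec))
}

generate_world_impl <- function(spec) {
  countries <- sprintf("C%02d", seq_len(spec$n_countries))
  years <- spec$years
  nf <- spec$n_foods

  fruit_foods <- paste0("fruit_", letters[seq_len(nf)])
  veg_foods <- paste0("veg_", letters[seq_len(nf)])
  cereal_foods <- paste0("cereal_", letters[seq_len(nf)])
  meat_foods <- c("bovine_meat", "pig_meat", "poultry_meat")
  passthrough <- c("wheat", "maize", "sweeteners_other")
  children <- c(fruit_foods, "fruit_nes", veg_foods, "vegetable_nes",
                cereal_foods, meat_foods)

  category_map <- dplyr::bind_rows(
    tibble(parent_category = "fruit_other",
           child = c(fruit_foods, "fruit_nes"), disaggregate = "yes"),
    tibble(parent_category = "vegetables_other",
           child = c(veg_foods, "vegetable_nes"), disaggregate = "yes"),
    tibble(parent_category = "cereals_other",
           child = cereal_foods, disaggregate = "yes"),
    tibble(parent_category = "meat_other",
           child = meat_foods, disaggregate = "yes"),
    tibble(parent_category = passthrough, child = passthrough,
           disaggregate = "no")
  )

  grid <- tidyr::expand_grid(country = countries, year = years,
                             commodity = children)
  n <- nrow(grid)
  production <- stats::rlnorm(n, meanlog = 9, sdlog = 1)
  imports <- stats::rlnorm(n, meanlog = 7, sdlog = 1)
  exports <- pmin(stats::rlnorm(n, meanlog = 6.5, sdlog = 1),
                  0.8 * (production + imports))

  nes_rows <- grid$commodity %in% c("fruit_nes", "vegetable_nes")
  nes_flag <- switch(
    spec$nes_scenario,
    none = "official", official = "",
    estimated = NA_character_, sparse = NA_character_
  )
  if (spec$nes_scenario == "none") production[nes_rows] <- 0
  if (spec$nes_scenario == "none") imports[nes_rows] <- 0
  if (spec$nes_scenario == "none") exports[nes_rows] <- 0
  if (spec$nes_scenario == "sparse") {
    # first country reports almost nothing but residual fruit
    sparse_rows <- grid$country == countries[1] &
      grid$commodity %in% fruit_foods[-1]
    production[sparse_rows] <- 0
    imports[sparse_rows] <- 0
    exports[sparse_rows] <- 0
  }

  flag_for <- function(rows) {
    out <- rep("", nrow(grid))
    flagged <- sample(c("", "E", "I"), nrow(grid), replace = TRUE,
                      prob = c(0.7, 0.2, 0.1))
    out[] <- flagged
    if (spec$nes_scenario %in% c("estimated", "sparse")) {
      out[rows] <- sample(c("E", "I"), sum(rows), replace = TRUE)
    } else if (spec$nes_scenario == "none") {
      out[rows] <- ""
    } else if (spec$nes_scenario == "official") {
      out[rows] <- ""
    }
    out
  }
  prod_flags <- flag_for(nes_rows)

  flows_children <- dplyr::bind_rows(
    tibble(country = grid$country, year = grid$year,
           commodity = grid$commodity, element = "production",
           value = production, flag = prod_flags),
    tibble(country = grid$country, year = grid$year,
           commodity = grid$commodity, element = "imports",
           value = imports, flag = ""),
    tibble(country = grid$country, year = grid$year,
           commodity = grid$commodity, element = "exports",
           value = exports, flag = "")
  )

  # parents are exact sums of their children, with a food share of the
  # domestic supply; passthrough categories get their own flows
  child_dom <- tibble(
    country = grid$country, year = grid$year, commodity = grid$commodity,
    dom = pmax(production + imports - exports, 0)
  )
  child_dom <- dplyr::left_join(child_dom, category_map,
                                by = c(commodity = "child"))
  parent_dom <- dplyr::summarise(
    dplyr::group_by(child_dom, .data$country, .data$year,
                    .data$parent_category),
    dom = sum(.data$dom), .groups = "drop"
  )
  parent_dom <- dplyr::filter(parent_dom,
                              !.data$parent_category %in% passthrough)
  food_ratio <- stats::runif(nrow(parent_dom), 0.5, 0.95)

  pass_grid <- tidyr::expand_grid(country = countries, year = years,
                                  commodity = passthrough)
  pass_prod <- stats::rlnorm(nrow(pass_grid), meanlog = 10, sdlog = 0.7)

  flows_parents <- dplyr::bind_rows(
    tibble(country = parent_dom$country, year = parent_dom$year,
           commodity = parent_dom$parent_category, element = "production",
           value = parent_dom$dom, flag = ""),
    tibble(country = parent_dom$country, year = parent_dom$year,
           commodity = parent_dom$parent_category, element = "food",
           value = parent_dom$dom * food_ratio, flag = ""),
    tibble(country = pass_grid$country, year = pass_grid$year,
           commodity = pass_grid$commodity, element = "production",
           value = pass_prod, flag = ""),
    tibble(country = pass_grid$country, year = pass_grid$year,
           commodity = pass_grid$commodity, element = "food",
           value = pass_prod * 0.8, flag = "")
  )

  population <- tidyr::expand_grid(country = countries, year = years)
  population$population <- round(stats::rlnorm(nrow(population),
                                               meanlog = 16, sdlog = 0.5))

  group_map <- dplyr::bind_rows(
    tibble(food = c(fruit_foods, "fruit_nes"), food_group = "fruit",
           is_nes = c(rep(FALSE, nf), TRUE)),
    tibble(food = c(veg_foods, "vegetable_nes"), food_group = "vegetable",
           is_nes = c(rep(FALSE, nf), TRUE))
  )

  nes_flags <- dplyr::filter(
    flows_children, .data$element == "production",
    .data$commodity %in% c("fruit_nes", "vegetable_nes")
  )
  nes_flags <- tibble(
    country = nes_flags$country, year = nes_flags$year,
    food = nes_flags$commodity,
    flag = unname(default_flag_map()[nes_flags$flag])
  )

  offal_factors <- tibble(
    animal_type = meat_foods,
    carcass_to_live = c(2.0, 1.7, 1.3),
    live_to_offal = c(0.05, 0.06, 0.04)
  )

  all_foods <- c(fruit_foods, veg_foods, cereal_foods, meat_foods,
                 passthrough, "offals")
  edible_factors <- tibble(
    food = all_foods,
    carcass_to_retail = ifelse(
      all_foods %in% c(meat_foods, "offals"),
      stats::runif(length(all_foods), 0.6, 0.8), NA_real_
    ),
    discard_fraction = ifelse(
      all_foods %in% c(fruit_foods, veg_foods),
      stats::runif(length(all_foods), 0.05, 0.4),
      ifelse(all_foods %in% c(meat_foods, "offals"),
             stats::runif(length(all_foods), 0.1, 0.3), 0)
    )
  )

  grain_region_map <- tibble(country = countries, region = "region_1")
  grain_processing <- tibble(
    grain = c("wheat", "maize"), region = "region_1",
    processed_fraction = c(0.8, 0.6), extraction_rate = c(0.78, 0.9)
  )

  comp_foods <- c(all_foods, "wheat_flour", "maize_flour",
                  "fruit_nes_retained", "vegetable_nes_retained")
  nutrients <- nutrient_set()$nutrient
  comp <- list()
  for (f in comp_foods) {
    for (tab in c("regional", "usda")) {
      if (tab == "regional" && stats::runif(1) < 0.3) next # force fallbacks
      k <- sample.int(spec$max_candidates, 1)
      base <- stats::rlnorm(length(nutrients), meanlog = 1, sdlog = 1)
      for (j in seq_len(k)) {
        dens <- base * stats::rlnorm(length(nutrients), 0, 0.2)
        comp[[length(comp) + 1]] <- tibble(
          table_id = tab, food = f, entry = sprintf("%s_%s_%d", f, tab, j),
          nutrient = nutrients, density_per_100g = dens,
          unit = nutrient_set()$unit
        )
      }
    }
  }
  composition <- dplyr::bind_rows(comp)

  comp_region_map <- dplyr::bind_rows(
    tibble(country = countries, rank = 1L, table_id = "regional"),
    tibble(country = countries, rank = 2L, table_id = "usda")
  )

  gdd_map <- dplyr::bind_rows(
    tibble(food = c(fruit_foods, "fruit_nes_retained"),
           gdd_category = "fruit", handling = "mapped"),
    tibble(food = c(veg_foods, "vegetable_nes_retained"),
           gdd_category = "vegetables", handling = "mapped"),
    tibble(food = c(cereal_foods, "wheat", "maize", "wheat_flour",
                    "maize_flour"),
           gdd_category = "grains", handling = "mapped"),
    tibble(food = c(meat_foods, "offals"), gdd_category = "meat",
           handling = "mapped"),
    tibble(food = "sweeteners_other", gdd_category = NA_character_,
           handling = "uniform")
  )

  demographics <- tidyr::expand_grid(
    country = countries, sex = c("female", "male"),
    age_bracket = c(CHILD_BRACKETS, ADULT_BRACKETS)
  )
  demographics$group <- paste(demographics$sex, demographics$age_bracket,
                              sep = "_")
  demographics$is_adult <- demographics$age_bracket %in% ADULT_BRACKETS
  demographics$population <- round(stats::rlnorm(nrow(demographics),
                                                 meanlog = 12, sdlog = 0.3))
  demographics$energy_requirement <- round(ifelse(
    demographics$is_adult,
    stats::runif(nrow(demographics), 1900, 2900),
    stats::runif(nrow(demographics), 1300, 2400)
  ))

  gdd_categories <- stats::na.omit(unique(gdd_map$gdd_category))
  ratio_rows <- list()
  for (cc in countries) {
    dem <- demographics[demographics$country == cc & demographics$is_adult, ]
    for (cat in gdd_categories) {
      raw <- stats::rlnorm(nrow(dem), 0, spec$ratio_dispersion)
      wmean <- sum(dem$population * raw) / sum(dem$population)
      ratio_rows[[length(ratio_rows) + 1]] <- tibble(
        country = cc, gdd_category = cat, group = dem$group,
        ratio = raw / wmean
      )
    }
  }
  gdd_ratios <- dplyr::bind_rows(ratio_rows)

  fortification_rules <- tibble(
    country = rep(countries, each = 2),
    vehicle = "wheat_flour",
    nutrient = rep(c("iron", "folate"), spec$n_countries),
    amount_low = rep(c(30, 1.5), spec$n_countries),
    amount_high = rep(c(45, 2.6), spec$n_countries),
    status = rep(c("mandatory", "voluntary"), spec$n_countries)
  )
  industrial_fractions <- tibble(
    country = countries, vehicle = "wheat_flour",
    fraction = stats::runif(spec$n_countries, 0.3, 0.9)
  )

  list(
    spec = spec,
    flows_children = flows_children, flows_parents = flows_parents,
    category_map = category_map, population = population,
    group_map = group_map, nes_flags = nes_flags,
    offal_factors = offal_factors, edible_factors = edible_factors,
    grain_processing = grain_processing,
    grain_region_map = grain_region_map,
    composition = composition, comp_region_map = comp_region_map,
    gdd_map = gdd_map, gdd_ratios = gdd_ratios,
    demographics = demographics,
    fortification_rules = fortification_rules,
    industrial_fractions = industrial_fractions
  )
}

#' Write a synthetic bundle to a directory of CSV files
#'
#' Emits every table of a [generate_world()] bundle in the same CSV
#' dialect the readers consume.
#'
#' @param bundle Bundle list from [generate_world()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(bundle), "spec")) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' The Country X worked-example fixture
#'
#' A minimal hard-coded bundle encoding the canonical worked example:
#' a country with an apple supply of 30 g/day and a national energy
#' supply of 3,000 kcal/day; women aged 50-54 with a fruit intake ratio
#' of 1.10 and an energy requirement of 2,200 kcal/day in a population
#' whose weighted average requirement is 2,500 kcal/day; and a potato
#' supply of 114 g/day with a single 70 kcal/100 g composition
#' candidate. Used as a permanent regression fixture for the demographic
#' disaggregation chain.
#'
#' @return A list: `supplies`, `national_energy`, `groups`, `gdd_map`,
#'   `gdd_ratios`, `candidates`.
#' @export
country_x_fixture <- function() {
  groups <- tibble(
    group = c("female_50-54", "male_50-54"),
    sex = c("female", "male"),
    age_bracket = "50-54",
    is_adult = TRUE,
    population = c(1e6, 1e6),
    energy_requirement = c(2200, 2800) # weighted average 2500
  )
  list(
    supplies = tibble(food = c("apples", "potatoes"),
                      amount_g_day = c(30, 114)),
    national_energy = 3000,
    groups = groups,
    gdd_map = tibble(food = c("apples", "potatoes"),
                     gdd_category = c("fruit", "starchy_vegetables"),
                     handling = c("mapped", "uniform")),
    gdd_ratios = tibble(gdd_category = "fruit", group = "female_50-54",
                        ratio = 1.10),
    candidates = list(
      apples = matrix(52, 1, 1, dimnames = list("apple_usda", "calories")),
      potatoes = matrix(70, 1, 1,
                        dimnames = list("potato_white", "calories"))
    )
  )
}
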