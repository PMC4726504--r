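# Disaggregation of national per-capita supplies into age-sex groups:
# 2000-kcal normalisation, relative intake ratios, energy-requirement
# proportional calorie allocation, de-adjustment, and a final
# population-consistency rescale.

#' Normalise a food supply to a reference-calorie diet
#'
#' National per-capita supplies are put on a common 2,000-kcal basis so
#' they can be combined with relative intake ratios:
#' `adjusted = supply x reference / national_energy`.
#'
#' @param food_supply Per-capita supply (g/person/day), >= 0.
#' @param national_energy National energy supply (kcal/person/day), > 0.
#' @param reference_kcal Reference diet (kcal/day), default 2000.
#' @return Energy-adjusted supply (g/day per reference diet); vectorised.
#' @export
#' @examples
#' energy_adjust(30, 3000) # 20
energy_adjust <- function(food_supply, national_energy,
                          reference_kcal = 2000) {
  assert_nonneg(food_supply, "food_supply")
  assert_finite(national_energy, "national_energy")
  if (any(national_energy <= 0)) {
    stop_input("`national_energy` must be positive.")
  }
  food_supply * reference_kcal / national_energy
}

GDD_HANDLING <- c("mapped", "uniform", "adult_only")

#' Apply a group's relative intake ratio to an adjusted supply
#'
#' For a food mapped to an intake category, the group's energy-adjusted
#' supply is the national adjusted supply times the group's ratio to the
#' national average. Foods handled as `uniform` (starchy vegetables,
#' sweeteners, eggs — no matching category) are unchanged for every
#' group. Foods handled as `adult_only` (alcohol, stimulants, spices) are
#' zero for groups under 20 and ratio-scaled (or unchanged without a
#' ratio) for adults. Groups without an intake estimate (children and
#' adolescents) take the national average value.
#'
#' @param adjusted_supply Energy-adjusted supply (g/day per reference
#'   diet), >= 0.
#' @param handling One of `mapped`, `uniform`, `adult_only`.
#' @param ratio Group-to-average intake ratio (> 0), or `NA` when the
#'   group has no estimate.
#' @param is_adult Is the group an adult (age 20+) group?
#' @return Group energy-adjusted supply (g/day per reference diet).
#' @export
#' @examples
#' apply_group_ratio(20, "mapped", 1.10, TRUE) # 22
apply_group_ratio <- function(adjusted_supply, handling, ratio = NA_real_,
                              is_adult = TRUE) {
  assert_nonneg(adjusted_supply, "adjusted_supply")
  if (!handling %in% GDD_HANDLING) {
    stop_input(sprintf("Unknown intake-category handling: `%s`.", handling))
  }
  if (!is.na(ratio) && ratio <= 0) stop_input("`ratio` must be > 0.")
  if (handling == "uniform") return(adjusted_supply)
  if (handling == "adult_only" && !is_adult) return(0 * adjusted_supply)
  if (is.na(ratio)) adjusted_supply else adjusted_supply * ratio
}

#' Allocate national calories to age-sex groups by requirement
#'
#' Each group receives calories in proportion to its energy requirement:
#' the national surplus factor is `national_energy / weighted-average
#' requirement`, and each group's supply is its requirement times that
#' factor. The population-weighted mean of group supplies equals the
#' national energy supply exactly.
#'
#' @param national_energy National energy supply (kcal/person/day), > 0.
#' @param groups Tibble with columns `population` (> 0 total) and
#'   `energy_requirement` (kcal/person/day, > 0).
#' @return Numeric vector of group energy supplies (kcal/person/day),
#'   one per row of `groups`.
#' @export
#' @examples
#' g <- tibble::tibble(population = c(1, 1), energy_requirement = c(2200, 2800))
#' group_energy_supply(3000, g) # 2640, 3360
group_energy_supply <- function(national_energy, groups) {
  assert_columns(groups, c("population", "energy_requirement"), "groups")
  assert_finite(national_energy, "national_energy")
  if (national_energy <= 0) stop_input("`national_energy` must be positive.")
  if (any(groups$population < 0) || sum(groups$population) <= 0) {
    stop_input("Group populations must be non-negative with a positive total.")
  }
  if (any(groups$energy_requirement <= 0)) {
    stop_input("Energy requirements must be positive.")
  }
  avg_req <- sum(groups$population * groups$energy_requirement) /
    sum(groups$population)
  groups$energy_requirement * (national_energy / avg_req)
}

#' Convert an energy-adjusted supply back to an absolute supply
#'
#' Inverse of [energy_adjust()] at the group's own calorie supply:
#' `absolute = adjusted x group_energy / reference`.
#'
#' @param group_adjusted Group energy-adjusted supply (g/day per
#'   reference diet), >= 0.
#' @param group_energy Group calorie supply (kcal/person/day), > 0.
#' @param reference_kcal Reference diet (kcal/day), default 2000.
#' @return Absolute group supply (g/person/day); vectorised.
#' @export
#' @examples
#' deadjust(22, 2640) # 29.04
deadjust <- function(group_adjusted, group_energy, reference_kcal = 2000) {
  assert_nonneg(group_adjusted, "group_adjusted")
  assert_finite(group_energy, "group_energy")
  if (any(group_energy <= 0)) stop_input("`group_energy` must be positive.")
  group_adjusted * group_energy / reference_kcal
}

#' Rescale group supplies so their weighted mean matches the national value
#'
#' The ratio-and-energy pipeline does not automatically make
#' population-weighted group supplies total the national per-capita
#' supply (children take average values, ratios are estimated), so each
#' food's group supplies are multiplied by a common factor
#' `national / weighted mean` as an explicit final stage.
#'
#' @param group_supplies Tibble `food,group,amount_g_day`.
#' @param populations Tibble `group,population`.
#' @param national_supply Tibble `food,amount_g_day` of national
#'   per-capita supplies.
#' @return `group_supplies` with rescaled `amount_g_day`; after the
#'   rescale the population-weighted mean per food equals the national
#'   supply to machine precision.
#' @export
enforce_population_consistency <- function(group_supplies, populations,
                                           national_supply) {
  assert_columns(group_supplies, c("food", "group", "amount_g_day"),
                 "group supplies")
  assert_columns(populations, c("group", "population"), "populations")
  assert_columns(national_supply, c("food", "amount_g_day"),
                 "national supply")
  df <- dplyr::left_join(group_supplies, populations, by = "group")
  if (anyNA(df$population)) stop_input("Missing population for some group.")
  wmean <- dplyr::summarise(
    dplyr::group_by(df, .data$food),
    wmean = sum(.data$population * .data$amount_g_day) /
      sum(.data$population),
    .groups = "drop"
  )
  nat <- national_supply[, c("food", "amount_g_day")]
  names(nat)[2] <- "national"
  wmean <- dplyr::left_join(wmean, nat, by = "food")
  if (anyNA(wmean$national)) stop_input("Missing national supply for some food.")
  bad <- wmean$wmean == 0 & wmean$national > 0
  if (any(bad)) {
    stop_input(sprintf(
      "All-zero group supplies with positive national supply for food(s): %s.",
      paste(wmean$food[bad], collapse = ", ")
    ))
  }
  wmean$factor <- ifelse(wmean$wmean > 0, wmean$national / wmean$wmean, 1)
  out <- dplyr::left_join(group_supplies, wmean[, c("food", "factor")],
                          by = "food")
  out$amount_g_day <- out$amount_g_day * out$factor
  out$factor <- NULL
  out
}

#' Age-sex-specific food supplies for one country-year
#'
#' Chains the full demographic disaggregation: [energy_adjust()] the
#' national supplies, [apply_group_ratio()] per food and group,
#' [group_energy_supply()] for the calorie allocation, [deadjust()] back
#' to absolute supplies, and [enforce_population_consistency()] as the
#' final rescale.
#'
#' @param supplies Tibble `food,amount_g_day` of national edible-basis
#'   per-capita supplies for one country-year.
#' @param national_energy National energy supply (kcal/person/day).
#' @param groups Tibble `group,sex,age_bracket,is_adult,population,
#'   energy_requirement` (one row per age-sex group).
#' @param gdd_map Tibble `food,gdd_category,handling` (handling `mapped`,
#'   `uniform` or `adult_only`; `gdd_category` may name a fatty-acid
#'   proxy, treated identically).
#' @param gdd_ratios Tibble `gdd_category,group,ratio`; absent
#'   group-category pairs take the national average.
#' @param reference_kcal Reference diet (kcal/day), default 2000.
#' @return A list: `food_supplies` (tibble `group,food,amount_g_day`,
#'   absolute g/person/day, population-consistent), `group_energy`
#'   (tibble `group,energy_kcal_day`).
#' @export
agesex_supplies <- function(supplies, national_energy, groups, gdd_map,
                            gdd_ratios, reference_kcal = 2000) {
  assert_columns(supplies, c("food", "amount_g_day"), "supplies")
  assert_columns(groups,
                 c("group", "sex", "age_bracket", "is_adult", "population",
                   "energy_requirement"),
                 "groups")
  assert_columns(gdd_map, c("food", "gdd_category", "handling"), "gdd map")
  assert_columns(gdd_ratios, c("gdd_category", "group", "ratio"),
                 "gdd ratios")
  unmapped <- setdiff(supplies$food, gdd_map$food)
  if (length(unmapped) > 0) {
    stop_input(sprintf(
      "No intake-category mapping for food(s): %s.",
      paste(unmapped, collapse = ", ")
    ))
  }

  adjusted <- energy_adjust(supplies$amount_g_day, national_energy,
                            reference_kcal)
  grid <- tidyr::expand_grid(
    tibble(food = supplies$food, adjusted = adjusted),
    group = groups$group
  )
  grid <- dplyr::left_join(grid, gdd_map, by = "food")
  grid <- dplyr::left_join(
    grid, groups[, c("group", "is_adult")], by = "group"
  )
  grid <- dplyr::left_join(grid, gdd_ratios,
                           by = c("gdd_category", "group"))
  grid$amount_adjusted <- purrr::pmap_dbl(
    list(grid$adjusted, grid$handling, grid$ratio, grid$is_adult),
    function(a, h, r, ad) apply_group_ratio(a, h, r, ad)
  )

  energy <- group_energy_supply(national_energy, groups)
  grid <- dplyr::left_join(
    grid, tibble(group = groups$group, group_energy = energy), by = "group"
  )
  grid$amount_g_day <- deadjust(grid$amount_adjusted, grid$group_energy,
                                reference_kcal)

  consistent <- enforce_population_consistency(
    grid[, c("food", "group", "amount_g_day")],
    groups[, c("group", "population")],
    supplies[, c("food", "amount_g_day")]
  )
  list(
    food_supplies = consistent[, c("group", "food", "amount_g_day")],
    group_energy = tibble(group = groups$group, energy_kcal_day = energy)
  )
}

#' Monte Carlo nutrient summaries per age-sex group
#'
#' Runs the same Monte Carlo contract as [mc_nutrient_supply()] for every
#' group's food supplies. All groups share one set of candidate draws per
#' iteration (a single draw per food, applied to every group), so group
#' totals stay coupled to the national totals iteration by iteration.
#'
#' @param group_food_supplies Tibble `group,food,amount_g_day`.
#' @param candidates Named list of candidate density matrices, as in
#'   [mc_nutrient_supply()].
#' @param n_iter,seed As in [mc_nutrient_supply()].
#' @return A tibble `group,nutrient,median,lower_95,upper_95,
#'   n_iterations`.
#' @export
group_nutrients <- function(group_food_supplies, candidates,
                            n_iter = 1000L, seed = 1L) {
  assert_columns(group_food_supplies, c("group", "food", "amount_g_day"),
                 "group food supplies")
  out <- list()
  for (g in unique(group_food_supplies$group)) {
    sub <- group_food_supplies[group_food_supplies$group == g,
                               c("food", "amount_g_day")]
    summ <- mc_nutrient_supply(sub, candidates, n_iter = n_iter,
                               seed = seed)
    out[[length(out) + 1]] <- dplyr::bind_cols(tibble(group = g), summ)
  }
  dplyr::bind_rows(out)
}
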