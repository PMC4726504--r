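# Nutrient set and food composition matching.

#' The default tracked nutrient set
#'
#' The 23 nutrients tracked by default, with their fixed units: energy and
#' macronutrients, fibre, vitamins, minerals (including selenium) and the
#' three fatty-acid classes. Densities are expressed per 100 g edible
#' portion. Sodium from added salt is deliberately not modelled; only
#' nutrients supplied directly by foods are in scope, and the set is
#' configurable.
#'
#' @return A tibble with columns `nutrient` and `unit` (23 rows).
#' @export
nutrient_set <- function() {
  tibble(
    nutrient = c(
      "calories", "fat", "protein", "carbohydrates", "dietary_fiber",
      "vitamin_c", "thiamin", "riboflavin", "niacin", "vitamin_b6",
      "vitamin_a", "folate", "calcium", "iron", "zinc", "potassium",
      "copper", "magnesium", "phosphorus", "selenium",
      "saturated_fa", "monounsaturated_fa", "polyunsaturated_fa"
    ),
    unit = c(
      "kcal", "g", "g", "g", "g",
      "mg", "mg", "mg", "mg", "mg",
      "ug_rae", "ug", "mg", "mg", "mg", "mg",
      "mg", "mg", "mg", "ug",
      "g", "g", "g"
    )
  )
}

#' Resolve composition candidates for a food in a country
#'
#' Walks the country's ordered chain of food composition tables and
#' returns all candidate entries from the first table that contains the
#' food (equally good matches are all kept for the Monte Carlo step).
#' If no table in the chain has the food but some table outside it does,
#' a single synthetic candidate is built as the per-nutrient mean over
#' every entry of that food across all tables (the global-average
#' fallback). A food absent from every table is an error.
#'
#' @param food Food identifier.
#' @param country Country identifier.
#' @param composition Long composition tibble
#'   (`table_id,food,entry,nutrient,density_per_100g,unit`).
#' @param region_map Tibble `country,rank,table_id` giving each country's
#'   ordered table chain (rank 1 first). Countries absent from the map
#'   fall straight to the global average.
#' @return A long tibble of candidate rows with columns
#'   `table_id,entry,nutrient,density_per_100g`.
#' @export
resolve_candidates <- function(food, country, composition, region_map) {
  composition <- validate_composition_table(composition)
  assert_columns(region_map, c("country", "rank", "table_id"), "region map")
  chain <- region_map[region_map$country == country, ]
  chain <- chain$table_id[order(chain$rank)]
  food_rows <- composition[composition$food == food, ]
  if (nrow(food_rows) == 0) {
    stop_input(sprintf("Food `%s` is absent from every composition table.", food))
  }
  for (tab in chain) {
    hit <- food_rows[food_rows$table_id == tab, ]
    if (nrow(hit) > 0) {
      return(hit[, c("table_id", "entry", "nutrient", "density_per_100g")])
    }
  }
  # global-average fallback: one synthetic candidate, per-nutrient mean
  avg <- dplyr::summarise(
    dplyr::group_by(food_rows, .data$nutrient),
    density_per_100g = mean(.data$density_per_100g),
    .groups = "drop"
  )
  log_note("nutrient_mc",
           "food `%s`: no entry in %s's table chain; global average of %d table(s) used.",
           food, country, length(unique(food_rows$table_id)))
  tibble(
    table_id = "global_average", entry = paste0(food, "_global_average"),
    nutrient = avg$nutrient, density_per_100g = avg$density_per_100g
  )
}

# Convert a long candidate tibble into a candidates x nutrients density
# matrix. Missing nutrients within a candidate fall back to the candidate
# pool's mean for that nutrient (logged); nutrients missing from the whole
# pool are taken as 0.
candidate_matrix <- function(cands, nutrients) {
  entries <- unique(cands$entry)
  m <- matrix(NA_real_, nrow = length(entries), ncol = length(nutrients),
              dimnames = list(entries, nutrients))
  keep <- cands$nutrient %in% nutrients
  idx <- cbind(match(cands$entry[keep], entries),
               match(cands$nutrient[keep], nutrients))
  m[idx] <- cands$density_per_100g[keep]
  if (anyNA(m)) {
    pool_mean <- colMeans(m, na.rm = TRUE)
    pool_mean[!is.finite(pool_mean)] <- 0
    for (j in seq_along(nutrients)) {
      miss <- is.na(m[, j])
      if (any(miss)) m[miss, j] <- pool_mean[j]
    }
  }
  m
}
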