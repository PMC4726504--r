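# End-to-end orchestration: disaggregate -> fv_correct -> edible ->
# nutrient_mc -> fortify -> age_sex, on an in-memory input bundle.

#' Run the full supply-estimation pipeline on an input bundle
#'
#' Executes the stages in order on a bundle of input tables (as produced
#' by [generate_world()] or read from CSVs in the same dialect):
#' disaggregation of broad categories (with offal re-estimation from
#' meat), residual fruit/vegetable correction, edible-weight conversion
#' with the refined-flour split, Monte Carlo nutrient estimation, the
#' fortification overlay for the most recent year, and age-sex
#' disaggregation for the most recent year. Every stage's output is
#' returned for inspection; outputs are pure functions of
#' (bundle, config).
#'
#' @param bundle Named list of input tibbles; see [generate_world()] for
#'   the components.
#' @param config A [pipeline_config()].
#' @return A list with elements `supplies_primary`, `validation`,
#'   `supplies_corrected`, `exclusions`, `supplies_edible`,
#'   `nutrient_summaries`, `nutrient_summaries_fortified`,
#'   `group_food_supplies`, `group_nutrient_summaries`, `group_energy`
#'   and `manifest` (seed, stage record counts).
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_input("`config` must be a pipeline_config.")
  }
  counts <- list()

  # -- stage 1: disaggregation ------------------------------------------
  child_wide <- validate_flow_long(bundle$flows_children,
                                   default_flag_map(), "child flows")
  parent_wide <- validate_flow_long(bundle$flows_parents,
                                    default_flag_map(), "parent flows")
  stage1 <- disaggregate_flows(child_wide, parent_wide,
                               bundle$category_map, bundle$population)
  supplies <- stage1$supplies
  if (!is.null(bundle$offal_factors)) {
    meat <- supplies[supplies$food %in% bundle$offal_factors$animal_type, ]
    if (nrow(meat) > 0) {
      offal <- dplyr::summarise(
        dplyr::group_by(meat, .data$country, .data$year),
        amount_g_day = offal_supply(
          setNames(.data$amount_g_day, .data$food),
          bundle$offal_factors
        )$total,
        .groups = "drop"
      )
      supplies <- dplyr::bind_rows(
        supplies,
        food_supply(offal$country, offal$year, "offals",
                    offal$amount_g_day, basis = "primary")
      )
    }
  }
  counts$supplies_primary <- nrow(supplies)

  # -- stage 2: residual fruit/vegetable correction ---------------------
  stage2 <- fv_correct(
    supplies, bundle$group_map, bundle$nes_flags,
    census_shares = bundle$census_shares,
    threshold = config$exclusion_threshold,
    redistribute_unofficial = config$redistribute_unofficial
  )
  counts$supplies_corrected <- nrow(stage2$supplies)

  # -- stage 3: edible conversion + flour split -------------------------
  stage3 <- edible_convert(stage2$supplies, bundle$edible_factors,
                           grain_processing = bundle$grain_processing,
                           region_map = bundle$grain_region_map)
  counts$supplies_edible <- nrow(stage3$supplies)

  # -- stage 4: Monte Carlo nutrient supplies ---------------------------
  summaries <- nutrient_supplies(
    stage3$supplies, bundle$composition, bundle$comp_region_map,
    n_iter = config$n_iter, seed = config$seed
  )
  counts$nutrient_summaries <- nrow(summaries)

  # -- stage 5: fortification overlay (most recent year) ----------------
  target_year <- config$fortification_year %||% max(stage3$supplies$year)
  fortified <- apply_fortification(
    summaries, stage3$supplies, bundle$fortification_rules,
    industrial_fractions = bundle$industrial_fractions,
    statuses = config$fortification_statuses,
    year = target_year
  )
  counts$nutrient_summaries_fortified <- nrow(fortified)

  # -- stage 6: age-sex disaggregation (most recent year) ---------------
  energy <- summaries[summaries$nutrient == "calories" &
                        summaries$year == target_year, ]
  group_food <- list()
  group_nutr <- list()
  group_energy <- list()
  for (cc in unique(energy$country)) {
    nat_energy <- energy$median[energy$country == cc]
    sub <- stage3$supplies[stage3$supplies$country == cc &
                             stage3$supplies$year == target_year, ]
    dem <- bundle$demographics[bundle$demographics$country == cc, ]
    ratios <- bundle$gdd_ratios[bundle$gdd_ratios$country == cc,
                                c("gdd_category", "group", "ratio")]
    as_out <- agesex_supplies(
      sub[, c("food", "amount_g_day")], nat_energy,
      dem[, c("group", "sex", "age_bracket", "is_adult", "population",
              "energy_requirement")],
      bundle$gdd_map, ratios, reference_kcal = config$reference_kcal
    )
    cseed <- substream_seed(config$seed, cc)
    cands <- lapply(setNames(unique(sub$food), unique(sub$food)),
                    function(f) {
                      candidate_matrix(
                        resolve_candidates(f, cc, bundle$composition,
                                           bundle$comp_region_map),
                        nutrient_set()$nutrient
                      )
                    })
    gn <- group_nutrients(as_out$food_supplies, cands,
                          n_iter = config$n_iter, seed = cseed)
    group_food[[cc]] <- dplyr::bind_cols(
      tibble(country = cc, year = target_year), as_out$food_supplies
    )
    group_energy[[cc]] <- dplyr::bind_cols(
      tibble(country = cc), as_out$group_energy
    )
    group_nutr[[cc]] <- dplyr::bind_cols(tibble(country = cc), gn)
  }
  group_food <- dplyr::bind_rows(group_food)
  group_nutr <- dplyr::bind_rows(group_nutr)
  group_energy <- dplyr::bind_rows(group_energy)
  counts$group_food_supplies <- nrow(group_food)
  counts$group_nutrient_summaries <- nrow(group_nutr)

  list(
    supplies_primary = supplies,
    validation = stage1$validation,
    supplies_corrected = stage2$supplies,
    exclusions = stage2$exclusions,
    supplies_edible = stage3$supplies,
    mass_ledger = stage3$ledger,
    nutrient_summaries = summaries,
    nutrient_summaries_fortified = fortified,
    group_food_supplies = group_food,
    group_nutrient_summaries = group_nutr,
    group_energy = group_energy,
    manifest = list(
      seed = config$seed, n_iter = config$n_iter,
      target_year = target_year,
      stages = c("disaggregate", "fv_correct", "edible", "nutrient_mc",
                 "fortify", "age_sex"),
      record_counts = counts
    )
  )
}

#' Write pipeline outputs to a directory
#'
#' Persists every tabular stage output of [run_pipeline()] as CSV and
#' the manifest as YAML.
#'
#' @param result Result list from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(result), "manifest")) {
    if (is.data.frame(result[[nm]])) {
      readr::write_csv(result[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
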