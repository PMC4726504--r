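# Disaggregation of broad commodity-balance categories into individual
# foods, replicating the balance-sheet method on production/trade data.

#' Domestic supply of a commodity
#'
#' Domestic supply is production + imports - exports. A negative result
#' (exports exceeding production plus imports, possible with re-exports)
#' is clamped to zero with a warning, since downstream steps are
#' multiplicative and require non-negative supplies.
#'
#' @param production,imports,exports Annual masses (tonnes), non-negative.
#' @return Domestic supply in tonnes (vectorised).
#' @export
#' @examples
#' domestic_supply(100, 20, 30) # 90
domestic_supply <- function(production, imports, exports) {
  assert_nonneg(production, "production")
  assert_nonneg(imports, "imports")
  assert_nonneg(exports, "exports")
  out <- production + imports - exports
  neg <- out < 0
  if (any(neg)) {
    log_warning(
      "disaggregation",
      "%d record(s) with exports exceeding production + imports; clamped to 0.",
      sum(neg)
    )
    out[neg] <- 0
  }
  out
}

#' Convert a processed quantity to its primary equivalent
#'
#' Processed trade forms (e.g. dried fruit) are folded back into the raw
#' commodity by multiplying with the primary-equivalent conversion factor.
#'
#' @param processed_amount Mass of the processed form (tonnes), >= 0.
#' @param factor Conversion factor (dimensionless), > 0.
#' @return Primary-equivalent mass in tonnes.
#' @export
#' @examples
#' to_primary_equivalent(10, 3.5) # 35
to_primary_equivalent <- function(processed_amount, factor) {
  assert_nonneg(processed_amount, "processed_amount")
  assert_finite(factor, "factor")
  if (any(factor <= 0)) stop_input("`factor` must be > 0.")
  processed_amount * factor
}

#' Apply the parent category's food ratio to constituent foods
#'
#' Stock changes and non-food uses are reported only at the level of the
#' broad category, so each constituent food receives food supply in
#' proportion to its domestic supply, using the parent's
#' food-to-domestic-supply ratio.
#'
#' @param child_domestic Named numeric vector of child domestic supplies
#'   (tonnes).
#' @param parent_domestic Parent category domestic supply (tonnes), > 0.
#' @param parent_food Parent category food supply (tonnes), >= 0.
#' @return Named numeric vector of child food supplies (tonnes).
#' @export
#' @examples
#' apply_food_ratio(c(A = 60, B = 40), 100, 80) # A 48, B 32
apply_food_ratio <- function(child_domestic, parent_domestic, parent_food) {
  assert_nonneg(child_domestic, "child_domestic")
  assert_nonneg(parent_food, "parent_food")
  assert_finite(parent_domestic, "parent_domestic")
  if (parent_domestic <= 0) {
    if (parent_food > 0) {
      stop_input("`parent_domestic` is 0 with positive `parent_food`: ratio undefined.")
    }
    return(child_domestic * 0)
  }
  child_domestic * (parent_food / parent_domestic)
}

#' Re-estimate offal supply from meat carcass weights
#'
#' Offal categories disaggregate poorly from production data, so offal
#' weight is recalculated from meat: carcass weight is converted back to
#' live weight per animal type, then live weight to offal weight.
#'
#' @param meat_carcass Named numeric vector of carcass weights (tonnes),
#'   names are animal types.
#' @param factors Tibble with columns `animal_type`, `carcass_to_live`
#'   (> 1) and `live_to_offal` (in (0,1)).
#' @return A list with `per_type` (named vector of offal tonnes) and
#'   `total`.
#' @export
#' @examples
#' f <- tibble::tibble(animal_type = "bovine",
#'                     carcass_to_live = 2, live_to_offal = 0.05)
#' offal_supply(c(bovine = 100), f)$total # 10
offal_supply <- function(meat_carcass, factors) {
  assert_nonneg(meat_carcass, "meat_carcass")
  assert_columns(factors, c("animal_type", "carcass_to_live", "live_to_offal"),
                 "offal factor table")
  if (any(!is.finite(factors$carcass_to_live)) ||
      any(factors$carcass_to_live <= 0) ||
      any(!is.finite(factors$live_to_offal)) ||
      any(factors$live_to_offal <= 0)) {
    stop_input("Offal factors must be finite and positive.")
  }
  types <- names(meat_carcass)
  if (is.null(types)) stop_input("`meat_carcass` must be a named vector.")
  missing <- setdiff(types, factors$animal_type)
  if (length(missing) > 0) {
    stop_input(sprintf(
      "No offal factors for animal type(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  idx <- match(types, factors$animal_type)
  per_type <- meat_carcass * factors$carcass_to_live[idx] *
    factors$live_to_offal[idx]
  list(per_type = per_type, total = sum(per_type))
}

#' Coefficient of determination about the 1:1 line
#'
#' Agreement between model estimates and reference totals measured as
#' 1 - sum((ref - model)^2) / sum((ref - mean(ref))^2). This is a
#' residual statistic about the identity line, not a squared correlation,
#' so it is unbounded below and reported as computed (it may be negative).
#'
#' @param model,reference Numeric vectors of equal length >= 2; the
#'   reference must not be constant.
#' @return A number in (-Inf, 1].
#' @export
#' @examples
#' one_to_one_r2(c(1, 2, 3), c(1.1, 2.0, 2.9)) # ~0.98765
one_to_one_r2 <- function(model, reference) {
  assert_finite(model, "model")
  assert_finite(reference, "reference")
  if (length(model) != length(reference) || length(model) < 2) {
    stop_input("`model` and `reference` must have equal length >= 2.")
  }
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) {
    stop_input("`reference` is constant: statistic undefined.")
  }
  1 - sum((reference - model)^2) / ss_tot
}

#' Disaggregate broad categories into individual food supplies
#'
#' Table-level driver. For each parent category flagged for
#' disaggregation, child domestic supplies are computed from child
#' production/trade flows (processed forms folded in via
#' [to_primary_equivalent()] beforehand), the parent's
#' food-to-domestic-supply ratio is applied, and agreement between summed
#' child domestic supplies and the parent's is scored with
#' [one_to_one_r2()] across country-years. Categories with
#' `disaggregate = "no"` are passed through unchanged. Child-level stock
#' or utilisation columns, if present, are ignored with a logged note.
#'
#' @param child_flows Wide flow tibble of child commodities (see
#'   [read_flow_table()]).
#' @param parent_flows Wide flow tibble of parent categories.
#' @param category_map Tibble with columns `parent_category`, `child`,
#'   `disaggregate` ("yes"/"no").
#' @param population Tibble `country,year,population`.
#' @return A list with `supplies` (per-capita supply tibble,
#'   basis = "primary") and `validation` (tibble
#'   `parent_category,r2,n_points`).
#' @export
disaggregate_flows <- function(child_flows, parent_flows, category_map,
                               population) {
  assert_columns(category_map, c("parent_category", "child", "disaggregate"),
                 "category map")
  assert_columns(population, c("country", "year", "population"),
                 "population table")
  if (anyDuplicated(category_map$child)) {
    stop_input("Each child food must belong to exactly one parent category.")
  }
  if (any(rowSums(child_flows[, c("feed", "seed", "processing", "waste",
                                  "other_uses", "stock_change", "food")]) != 0)) {
    log_note("disaggregation",
             "child-level utilisation/stock columns present; ignored (parent ratio governs).")
  }

  child_flows <- dplyr::mutate(
    child_flows,
    child_domestic = domestic_supply(.data$production, .data$imports,
                                     .data$exports)
  )
  joined <- dplyr::inner_join(
    child_flows[, c("country", "year", "commodity", "child_domestic")],
    category_map[, c("parent_category", "child", "disaggregate")],
    by = c(commodity = "child")
  )
  parent <- dplyr::mutate(
    parent_flows,
    parent_domestic = domestic_supply(.data$production, .data$imports,
                                      .data$exports)
  )
  parent <- parent[, c("country", "year", "commodity", "parent_domestic", "food")]
  names(parent)[names(parent) == "food"] <- "parent_food"

  joined <- dplyr::inner_join(
    joined, parent,
    by = c("country", "year", parent_category = "commodity")
  )

  disagg <- dplyr::filter(joined, .data$disaggregate == "yes")
  disagg <- dplyr::group_by(disagg, .data$country, .data$year,
                            .data$parent_category)
  disagg <- dplyr::mutate(
    disagg,
    child_food = apply_food_ratio(
      .data$child_domestic, .data$parent_domestic[1], .data$parent_food[1]
    )
  )
  disagg <- dplyr::ungroup(disagg)

  # pass-through categories keep their aggregate row
  passthrough_cats <- setdiff(
    unique(category_map$parent_category[category_map$disaggregate == "no"]),
    character()
  )
  pass <- dplyr::filter(parent, .data$commodity %in% passthrough_cats)

  supplies <- dplyr::bind_rows(
    tibble(
      country = disagg$country, year = disagg$year,
      food = disagg$commodity, food_tonnes = disagg$child_food
    ),
    tibble(
      country = pass$country, year = pass$year,
      food = pass$commodity, food_tonnes = pass$parent_food
    )
  )
  supplies <- dplyr::inner_join(supplies, population,
                                by = c("country", "year"))
  supplies <- food_supply(
    supplies$country, supplies$year, supplies$food,
    per_capita_supply(supplies$food_tonnes, supplies$population),
    basis = "primary"
  )

  validation <- dplyr::summarise(
    dplyr::group_by(
      dplyr::summarise(
        dplyr::group_by(disagg, .data$parent_category, .data$country,
                        .data$year),
        model = sum(.data$child_domestic),
        reference = .data$parent_domestic[1],
        .groups = "drop"
      ),
      .data$parent_category
    ),
    r2 = if (dplyr::n() >= 2 && stats::var(.data$reference) > 0) {
      one_to_one_r2(.data$model, .data$reference)
    } else NA_real_,
    n_points = dplyr::n(),
    .groups = "drop"
  )
  list(supplies = supplies, validation = validation)
}
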