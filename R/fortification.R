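# Fortification overlay: deterministic nutrient additions on top of the
# unfortified Monte Carlo summaries for a target year.

#' Nutrient added through fortification of one vehicle
#'
#' The addition is `vehicle supply (kg/day) x lower guideline amount
#' (per kg) x industrially milled fraction`. The lower bound of the
#' guideline range is used throughout, since part of the added nutrient
#' is lost in processing, storage and transport. The industrial fraction
#' applies to cereal-flour vehicles (home and local mills add no
#' fortificant); for any other vehicle it defaults to 1.
#'
#' @param vehicle_supply Supply of the vehicle food (g/person/day), >= 0.
#' @param amount_low Lower bound of the fortificant amount (nutrient unit
#'   per kg of vehicle), >= 0.
#' @param industrial_fraction Fraction in [0, 1] of the vehicle produced
#'   industrially; default 1.
#' @return Nutrient added per person per day, in the nutrient's unit.
#' @export
#' @examples
#' fortified_addition(200, 30, 0.5) # 3 mg/day of iron
fortified_addition <- function(vehicle_supply, amount_low,
                               industrial_fraction = 1) {
  assert_nonneg(vehicle_supply, "vehicle_supply")
  assert_nonneg(amount_low, "amount_low")
  assert_fraction(industrial_fraction, "industrial_fraction")
  (vehicle_supply / 1000) * amount_low * industrial_fraction
}

#' Apply fortification rules to nutrient supply summaries
#'
#' Computes the total fortificant addition per country and nutrient from
#' the rule table and shifts the unfortified median and both uncertainty
#' bounds by that amount (fortificant levels are fixed guideline values,
#' not sampled, so the whole distribution translates). Applied to the
#' configured target year only; other years pass through unchanged.
#'
#' @param summaries Nutrient summary tibble
#'   (`country,year,nutrient,median,lower_95,upper_95,...`).
#' @param supplies Edible-basis supply tibble providing vehicle supplies.
#' @param rules Tibble `country,vehicle,nutrient,amount_low,amount_high,
#'   status` with `amount_low <= amount_high` and status
#'   `mandatory`/`voluntary`.
#' @param industrial_fractions Optional tibble `country,vehicle,fraction`
#'   for flour vehicles; missing pairs default to 1.
#' @param statuses Which rule statuses to apply (default both).
#' @param year Target year; `NULL` means the most recent year in
#'   `summaries`.
#' @return The summaries tibble with shifted values and a logical
#'   `fortified` column.
#' @export
apply_fortification <- function(summaries, supplies, rules,
                                industrial_fractions = NULL,
                                statuses = c("mandatory", "voluntary"),
                                year = NULL) {
  assert_columns(summaries,
                 c("country", "year", "nutrient", "median", "lower_95",
                   "upper_95"),
                 "summaries")
  assert_columns(rules,
                 c("country", "vehicle", "nutrient", "amount_low",
                   "amount_high", "status"),
                 "fortification rules")
  if (any(rules$amount_low < 0) || any(rules$amount_low > rules$amount_high)) {
    stop_input("Rules must satisfy 0 <= amount_low <= amount_high.")
  }
  supplies <- validate_supply_table(supplies)
  target_year <- year %||% max(summaries$year)

  rules <- rules[rules$status %in% statuses, ]
  fr <- if (is.null(industrial_fractions)) {
    tibble(country = character(), vehicle = character(), fraction = numeric())
  } else {
    assert_columns(industrial_fractions, c("country", "vehicle", "fraction"),
                   "industrial fractions")
    industrial_fractions
  }

  veh <- supplies[supplies$year == target_year,
                  c("country", "food", "amount_g_day")]
  names(veh)[names(veh) == "food"] <- "vehicle"
  add <- dplyr::inner_join(rules, veh, by = c("country", "vehicle"))
  add <- dplyr::left_join(add, fr, by = c("country", "vehicle"))
  add$fraction[is.na(add$fraction)] <- 1
  add$addition <- fortified_addition(add$amount_g_day, add$amount_low,
                                     add$fraction)
  add <- dplyr::summarise(
    dplyr::group_by(add, .data$country, .data$nutrient),
    addition = sum(.data$addition), .groups = "drop"
  )
  add$year <- target_year

  out <- dplyr::left_join(summaries, add,
                          by = c("country", "year", "nutrient"))
  out$addition[is.na(out$addition)] <- 0
  out$median <- out$median + out$addition
  out$lower_95 <- out$lower_95 + out$addition
  out$upper_95 <- out$upper_95 + out$addition
  out$fortified <- out$addition > 0
  out$addition <- NULL
  out
}
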