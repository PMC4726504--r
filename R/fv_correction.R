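# Resolution of residual "not elsewhere specified" (nes) fruit and
# vegetable supplies. Data-quality flags distinguish genuinely reported
# residual foods (official) from balancing artifacts (estimated/imputed),
# which are redistributed over the named foods of the group.

#' Classify a country-group's nes supply by data-quality flag
#'
#' Residual (nes) amounts tagged `estimated` or `imputed` are balancing
#' artifacts and marked redistributable. `official` nes is a genuinely
#' reported food and retained as its own category. `unofficial` nes is
#' retained with a warning by default; set `redistribute_unofficial` to
#' treat it as redistributable.
#'
#' @param nes_supply Numeric vector of nes amounts (tonnes), >= 0.
#' @param flag Parallel vector of flags
#'   (`official`/`unofficial`/`estimated`/`imputed`).
#' @param group_domestic Total domestic supply of the food group (tonnes),
#'   used for the nes share; may be `NA` to skip.
#' @param n_reported_categories Count of non-nes foods with positive
#'   supply in the group.
#' @param redistribute_unofficial Logical; treat unofficial as
#'   redistributable.
#' @return A list: `redistributable`, `retained` (tonnes), `nes_share`
#'   (fraction of group domestic supply, `NA` if unknown),
#'   `dominant_flag`, `n_reported_categories`.
#' @export
#' @examples
#' classify_nes(c(10, 40), c("official", "imputed"),
#'              group_domestic = 100, n_reported_categories = 7)
classify_nes <- function(nes_supply, flag, group_domestic = NA,
                         n_reported_categories = NA_integer_,
                         redistribute_unofficial = FALSE) {
  assert_nonneg(nes_supply, "nes_supply")
  flag <- as.character(flag)
  bad <- setdiff(unique(flag), FLAG_LEVELS)
  if (length(bad) > 0) {
    stop_input(sprintf("Unknown flag value(s): %s.", paste(bad, collapse = ", ")))
  }
  redist_flags <- c("estimated", "imputed",
                    if (redistribute_unofficial) "unofficial")
  redistributable <- sum(nes_supply[flag %in% redist_flags])
  retained <- sum(nes_supply) - redistributable
  if (!redistribute_unofficial && any(flag == "unofficial" & nes_supply > 0)) {
    log_warning("fv_correction",
                "unofficial-flagged nes supply retained, not redistributed.")
  }
  total <- sum(nes_supply)
  dominant <- if (total > 0) {
    by_flag <- tapply(nes_supply, factor(flag, levels = FLAG_LEVELS), sum,
                      default = 0)
    FLAG_LEVELS[which.max(by_flag)]
  } else {
    "official"
  }
  list(
    redistributable = redistributable,
    retained = retained,
    nes_share = if (is.na(group_domestic) || group_domestic <= 0) NA_real_
                else total / group_domestic,
    dominant_flag = dominant,
    n_reported_categories = as.integer(n_reported_categories)
  )
}

#' Redistribute a group total according to census production shares
#'
#' For countries with an agricultural census, the group's total supply
#' (residual plus reported foods) is re-split entirely according to the
#' census production shares, replacing the within-group split.
#'
#' @param total Group total to split (tonnes), >= 0.
#' @param shares Named numeric vector of census shares, summing to 1
#'   within `tol`, all >= 0.
#' @param tol Tolerance on the share sum (default 1e-9).
#' @return Named numeric vector of per-food amounts summing exactly to
#'   `total` (the last food absorbs any floating-point residual).
#' @export
#' @examples
#' redistribute_census(100, c(mango = 0.5, banana = 0.3, papaya = 0.2))
redistribute_census <- function(total, shares, tol = 1e-9) {
  assert_nonneg(total, "total")
  assert_nonneg(shares, "shares")
  if (length(shares) == 0) stop_input("`shares` must be non-empty.")
  if (abs(sum(shares) - 1) > tol) {
    stop_input(sprintf("Census shares sum to %.12g, not 1.", sum(shares)))
  }
  out <- total * shares
  n <- length(out)
  out[n] <- total - sum(out[-n])
  out
}

#' Redistribute an nes amount proportionally over reported foods
#'
#' Each reported food gains a share of the residual amount proportional to
#' its existing supply; total group mass is conserved.
#'
#' @param nes_amount Residual amount to distribute (tonnes), >= 0.
#' @param existing Named numeric vector of reported food supplies
#'   (tonnes); must have a positive sum when `nes_amount > 0`.
#' @return Named numeric vector of updated supplies.
#' @export
#' @examples
#' redistribute_proportional(50, c(A = 30, B = 20)) # A 60, B 40
redistribute_proportional <- function(nes_amount, existing) {
  assert_nonneg(nes_amount, "nes_amount")
  assert_nonneg(existing, "existing")
  total <- sum(existing)
  if (total == 0) {
    if (nes_amount > 0) {
      stop_input(
        "All reported supplies are zero with a positive nes amount; the country should have been excluded."
      )
    }
    return(existing)
  }
  existing + nes_amount * existing / total
}

#' Country-exclusion rule for sparse reporting
#'
#' A country-group reporting `threshold` or fewer non-residual categories
#' is excluded from the database over precision-of-reporting concerns.
#'
#' @param n_reported_categories Count of non-nes foods with positive
#'   supply, >= 0.
#' @param threshold Exclusion threshold (default 5).
#' @return `"exclude"` or `"retain"` (vectorised).
#' @export
#' @examples
#' exclusion_rule(5) # "exclude"
#' exclusion_rule(6) # "retain"
exclusion_rule <- function(n_reported_categories, threshold = 5L) {
  n <- as.integer(n_reported_categories)
  if (any(is.na(n)) || any(n < 0)) {
    stop_input("`n_reported_categories` must be a non-negative integer.")
  }
  ifelse(n <= threshold, "exclude", "retain")
}

#' Correct residual fruit/vegetable supplies in a supply table
#'
#' Table-level driver over one or more country-years. For each country
#' and food group, residual (nes) amounts flagged estimated/imputed are
#' redistributed proportionally over the reported foods (or, where census
#' shares are supplied, the whole group is re-split by census shares for
#' the most recent year and earlier years dropped for those countries);
#' official nes is retained as a `"<group>_nes_retained"` category. The
#' exclusion rule then drops sparsely reporting countries.
#'
#' @param supplies Supply tibble (basis = "primary") covering the foods of
#'   the groups.
#' @param group_map Tibble `food,food_group,is_nes` assigning each food to
#'   `fruit` or `vegetable` and marking residual categories.
#' @param nes_flags Tibble `country,year,food,flag` with the data-quality
#'   flag of each nes supply row.
#' @param census_shares Optional tibble `country,food_group,food,share`.
#' @param threshold Exclusion threshold passed to [exclusion_rule()].
#' @param redistribute_unofficial See [classify_nes()].
#' @return A list: `supplies` (corrected tibble), `exclusions` (tibble
#'   `country,food_group,n_categories,decision`).
#' @export
fv_correct <- function(supplies, group_map, nes_flags,
                       census_shares = NULL, threshold = 5L,
                       redistribute_unofficial = FALSE) {
  supplies <- validate_supply_table(supplies)
  assert_columns(group_map, c("food", "food_group", "is_nes"), "group map")
  assert_columns(nes_flags, c("country", "year", "food", "flag"), "nes flags")

  df <- dplyr::left_join(supplies, group_map, by = "food")
  grouped <- dplyr::filter(df, !is.na(.data$food_group))
  other <- dplyr::filter(df, is.na(.data$food_group))
  grouped <- dplyr::left_join(grouped, nes_flags,
                              by = c("country", "year", "food"))
  grouped$flag[is.na(grouped$flag)] <- "official"

  census_countries <- if (is.null(census_shares)) character() else {
    assert_columns(census_shares, c("country", "food_group", "food", "share"),
                   "census shares")
    unique(census_shares$country)
  }

  out <- list()
  excl <- list()
  keys <- dplyr::distinct(grouped, .data$country, .data$year,
                          .data$food_group)
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, ]
    g <- dplyr::filter(
      grouped,
      .data$country == key$country, .data$year == key$year,
      .data$food_group == key$food_group
    )
    nes <- g[g$is_nes, ]
    named <- g[!g$is_nes, ]
    n_cat <- sum(named$amount_g_day > 0)
    decision <- exclusion_rule(n_cat, threshold)
    excl[[length(excl) + 1]] <- tibble(
      country = key$country, year = key$year, food_group = key$food_group,
      n_categories = n_cat, decision = decision
    )
    if (decision == "exclude") next

    if (key$country %in% census_countries) {
      cs <- dplyr::filter(census_shares, .data$country == key$country,
                          .data$food_group == key$food_group)
      max_year <- max(grouped$year[grouped$country == key$country])
      if (key$year < max_year) next # earlier years dropped for census countries
      shares <- setNames(cs$share, cs$food)
      split <- redistribute_census(sum(g$amount_g_day), shares)
      out[[length(out) + 1]] <- tibble(
        country = key$country, year = key$year, food = names(split),
        amount_g_day = unname(split), basis = g$basis[1]
      )
      next
    }

    cl <- classify_nes(nes$amount_g_day, nes$flag,
                       n_reported_categories = n_cat,
                       redistribute_unofficial = redistribute_unofficial)
    updated <- redistribute_proportional(
      cl$redistributable, setNames(named$amount_g_day, named$food)
    )
    rows <- tibble(
      country = key$country, year = key$year, food = names(updated),
      amount_g_day = unname(updated), basis = g$basis[1]
    )
    if (cl$retained > 0) {
      rows <- dplyr::bind_rows(rows, tibble(
        country = key$country, year = key$year,
        food = paste0(key$food_group, "_nes_retained"),
        amount_g_day = cl$retained, basis = g$basis[1]
      ))
    }
    out[[length(out) + 1]] <- rows
  }

  exclusions <- dplyr::bind_rows(excl)
  excluded <- dplyr::filter(exclusions, .data$decision == "exclude")
  # exclusion removes the whole country from the database
  drop_countries <- unique(excluded$country)
  corrected <- dplyr::bind_rows(
    other[, c("country", "year", "food", "amount_g_day", "basis")],
    dplyr::bind_rows(out)
  )
  corrected <- dplyr::filter(corrected,
                             !.data$country %in% drop_countries)
  list(
    supplies = validate_supply_table(corrected),
    exclusions = exclusions
  )
}
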