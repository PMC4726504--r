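# Tabular I/O for the commodity-balance CSV dialect.
#
# All tables are UTF-8, comma-separated, one header row, long format.
# Flow tables carry one row per country-year-commodity-element with a
# data-quality flag; supply and composition tables are plain long tables.

FLOW_ELEMENTS <- c(
  "production", "imports", "exports", "feed", "seed", "processing",
  "waste", "other_uses", "stock_change", "food"
)

FLAG_LEVELS <- c("official", "unofficial", "estimated", "imputed")

#' Default data-quality flag mapping
#'
#' Maps raw flag characters as found in bulk commodity-balance exports to
#' the four internal provenance categories: blank for official figures,
#' `*` for unofficial figures, `E` for estimates, and `I` for values
#' imputed from earlier estimates. Flag characters vary across data eras,
#' so every reader accepts a custom mapping.
#'
#' @return Named character vector mapping raw codes to
#'   `official`/`unofficial`/`estimated`/`imputed`.
#' @export
default_flag_map <- function() {
  setNames(c("official", "unofficial", "estimated", "imputed"),
           c("", "*", "E", "I"))
}

map_flags <- function(raw, flag_map, context) {
  raw <- ifelse(is.na(raw), "", as.character(raw))
  unknown <- setdiff(unique(raw), names(flag_map))
  if (length(unknown) > 0) {
    stop_input(sprintf(
      "%s contains unmapped flag code(s): %s.",
      context, paste(sprintf('"%s"', unknown), collapse = ", ")
    ))
  }
  factor(unname(flag_map[raw]), levels = FLAG_LEVELS)
}

#' Read a commodity flow table
#'
#' Reads a long-format flow CSV (`country,year,commodity,element,value,flag`)
#' and returns one row per country-year-commodity with one quantity column
#' and one flag column per balance element (production, imports, exports,
#' feed, seed, processing, waste, other_uses, stock_change, food).
#' Quantities are tonnes/year. All quantities must be finite and
#' non-negative except `stock_change`, which may be negative. Missing
#' elements for a record default to 0 with an `official` flag.
#'
#' @param path Path to the CSV file.
#' @param flag_map Named character vector mapping raw flag codes to the
#'   internal categories; see [default_flag_map()].
#' @return A tibble with columns `country`, `year`, `commodity`, one
#'   numeric column per element and one `<element>_flag` factor column.
#' @export
read_flow_table <- function(path, flag_map = default_flag_map()) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      year = readr::col_integer(),
      commodity = readr::col_character(),
      element = readr::col_character(),
      value = readr::col_double(),
      flag = readr::col_character()
    )
  )
  assert_columns(raw, c("country", "year", "commodity", "element", "value", "flag"),
                 sprintf("Flow table %s", path))
  validate_flow_long(raw, flag_map, path)
}

# Shared by read_flow_table and the synthetic generator (which builds the
# long table in memory): validates and widens a long flow table.
validate_flow_long <- function(raw, flag_map, context = "flow table") {
  if (nrow(raw) == 0) {
    out <- tibble(country = character(), year = integer(), commodity = character())
    for (el in FLOW_ELEMENTS) {
      out[[el]] <- numeric()
      out[[paste0(el, "_flag")]] <- factor(character(), levels = FLAG_LEVELS)
    }
    return(out)
  }
  bad_el <- setdiff(unique(raw$element), FLOW_ELEMENTS)
  if (length(bad_el) > 0) {
    stop_input(sprintf(
      "%s contains unknown element(s): %s.", context,
      paste(bad_el, collapse = ", ")
    ))
  }
  if (any(!is.finite(raw$value))) {
    stop_input(sprintf("%s contains non-finite quantities.", context))
  }
  neg <- raw$value < 0 & raw$element != "stock_change"
  if (any(neg)) {
    i <- which(neg)[1]
    stop_input(sprintf(
      "%s row %d: negative %s (%g) for %s/%s/%d.",
      context, i, raw$element[i], raw$value[i],
      raw$country[i], raw$commodity[i], raw$year[i]
    ))
  }
  raw$flag <- map_flags(raw$flag, flag_map, context)

  dup <- duplicated(raw[, c("country", "year", "commodity", "element")])
  if (any(dup)) {
    stop_input(sprintf(
      "%s has duplicate country/year/commodity/element rows (first: row %d).",
      context, which(dup)[1]
    ))
  }

  values <- tidyr::pivot_wider(
    raw[, c("country", "year", "commodity", "element", "value")],
    names_from = "element", values_from = "value"
  )
  flags <- tidyr::pivot_wider(
    raw[, c("country", "year", "commodity", "element", "flag")],
    names_from = "element", values_from = "flag",
    names_glue = "{element}_flag"
  )
  out <- dplyr::left_join(values, flags,
                          by = c("country", "year", "commodity"))
  for (el in FLOW_ELEMENTS) {
    if (!el %in% names(out)) out[[el]] <- 0
    fl <- paste0(el, "_flag")
    if (!fl %in% names(out)) {
      out[[fl]] <- factor("official", levels = FLAG_LEVELS)
    }
    out[[el]][is.na(out[[el]])] <- 0
    out[[fl]][is.na(out[[fl]])] <- "official"
  }
  out[, c("country", "year", "commodity", FLOW_ELEMENTS,
          paste0(FLOW_ELEMENTS, "_flag"))]
}

SUPPLY_BASES <- c("primary", "retail", "edible")

#' Construct a food supply table
#'
#' @param country,year,food,amount_g_day Parallel vectors describing
#'   per-capita supplies (g/person/day).
#' @param basis Supply basis: `primary` (primary-equivalent commodity
#'   weight), `retail`, or `edible`.
#' @return A validated supply tibble.
#' @export
food_supply <- function(country, year, food, amount_g_day,
                        basis = "primary") {
  out <- tibble(
    country = as.character(country),
    year = as.integer(year),
    food = as.character(food),
    amount_g_day = as.numeric(amount_g_day),
    basis = as.character(basis)
  )
  validate_supply_table(out)
}

validate_supply_table <- function(df, context = "supply table") {
  assert_columns(df, c("country", "year", "food", "amount_g_day", "basis"),
                 context)
  if (any(!is.finite(df$amount_g_day)) || any(df$amount_g_day < 0)) {
    stop_input(sprintf("%s: `amount_g_day` must be finite and >= 0.", context))
  }
  bad <- setdiff(unique(df$basis), SUPPLY_BASES)
  if (length(bad) > 0) {
    stop_input(sprintf(
      "%s: unknown basis value(s): %s.", context, paste(bad, collapse = ", ")
    ))
  }
  as_tibble(df)
}

#' Write a food supply table to CSV
#'
#' Values are written at full double precision so that a read/write
#' round trip is the identity.
#'
#' @param records Supply tibble as produced by [food_supply()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_supply_table <- function(records, path) {
  records <- validate_supply_table(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a food supply table from CSV
#'
#' @param path CSV path with columns `country,year,food,amount_g_day,basis`.
#' @return A validated supply tibble.
#' @export
read_supply_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      year = readr::col_integer(),
      food = readr::col_character(),
      amount_g_day = readr::col_double(),
      basis = readr::col_character()
    )
  )
  validate_supply_table(df, sprintf("supply table %s", path))
}

#' Read a food composition table
#'
#' Long CSV with columns `table_id,food,entry,nutrient,density_per_100g,unit`:
#' one row per nutrient of one candidate entry of one food in one
#' composition table. Densities are per 100 g edible portion and must be
#' non-negative; entries are expected to describe uncooked,
#' least-processed, unfortified forms.
#'
#' @param path CSV path.
#' @return A validated long composition tibble.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      table_id = readr::col_character(),
      food = readr::col_character(),
      entry = readr::col_character(),
      nutrient = readr::col_character(),
      density_per_100g = readr::col_double(),
      unit = readr::col_character()
    )
  )
  validate_composition_table(df, sprintf("composition table %s", path))
}

validate_composition_table <- function(df, context = "composition table") {
  assert_columns(
    df, c("table_id", "food", "entry", "nutrient", "density_per_100g", "unit"),
    context
  )
  if (any(!is.finite(df$density_per_100g)) || any(df$density_per_100g < 0)) {
    stop_input(sprintf("%s: densities must be finite and >= 0.", context))
  }
  as_tibble(df)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) file of pipeline settings. Missing
#' fields take the documented defaults; referenced paths, if any, must
#' resolve relative to the config file's directory.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list; see [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  base <- dirname(normalizePath(path))
  for (f in grep("_path$", names(cfg), value = TRUE)) {
    if (!is.null(cfg[[f]])) {
      p <- cfg[[f]]
      if (!file.exists(p)) p <- file.path(base, cfg[[f]])
      if (!file.exists(p)) {
        stop_input(sprintf("Config path `%s` does not resolve: %s", f, cfg[[f]]))
      }
      cfg[[f]] <- normalizePath(p)
    }
  }
  cfg
}

#' Construct a pipeline configuration
#'
#' @param n_iter Monte Carlo iteration count (default 1000).
#' @param seed Base RNG seed.
#' @param exclusion_threshold Country-exclusion threshold: a country-group
#'   reporting this many or fewer non-residual categories is excluded
#'   (default 5).
#' @param reference_kcal Reference diet used for energy adjustment
#'   (kcal/day, default 2000).
#' @param redistribute_unofficial Treat `unofficial`-flagged residual
#'   amounts as redistributable (default `FALSE`: they are retained).
#' @param fortification_statuses Which fortification rule statuses to
#'   apply (default both `mandatory` and `voluntary`).
#' @param fortification_year Year the fortification overlay applies to
#'   (`NULL` = most recent year present in the data).
#' @param days_per_year Day-count convention for per-capita conversion.
#' @param ... Further fields (e.g. `*_path` table locations) stored as-is.
#' @return A classed list of settings.
#' @export
pipeline_config <- function(n_iter = 1000L,
                            seed = 1L,
                            exclusion_threshold = 5L,
                            reference_kcal = 2000,
                            redistribute_unofficial = FALSE,
                            fortification_statuses = c("mandatory", "voluntary"),
                            fortification_year = NULL,
                            days_per_year = DAYS_PER_YEAR,
                            ...) {
  n_iter <- as.integer(n_iter)
  exclusion_threshold <- as.integer(exclusion_threshold)
  if (is.na(n_iter) || n_iter < 1) stop_input("`n_iter` must be >= 1.")
  if (is.na(exclusion_threshold) || exclusion_threshold < 0) {
    stop_input("`exclusion_threshold` must be >= 0.")
  }
  assert_finite(reference_kcal, "reference_kcal")
  if (reference_kcal <= 0) stop_input("`reference_kcal` must be positive.")
  structure(
    list(
      n_iter = n_iter, seed = as.integer(seed),
      exclusion_threshold = exclusion_threshold,
      reference_kcal = reference_kcal,
      redistribute_unofficial = isTRUE(redistribute_unofficial),
      fortification_statuses = fortification_statuses,
      fortification_year = fortification_year,
      days_per_year = days_per_year,
      ...
    ),
    class = "pipeline_config"
  )
}
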