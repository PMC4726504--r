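#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile median setNames
#' @importFrom utils head
NULL

# Internal assertion helpers. All user-facing errors are signalled with a
# class so callers (and tests) can distinguish validation failures from
# programming errors.

stop_input <- function(msg, ...) {
  rlang::abort(msg, class = "nutrisupply_input_error", ...)
}

assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_input(sprintf("`%s` must be finite and numeric.", what))
  }
  invisible(x)
}

assert_nonneg <- function(x, what) {
  assert_finite(x, what)
  if (any(x < 0)) {
    stop_input(sprintf("`%s` must be non-negative.", what))
  }
  invisible(x)
}

assert_fraction <- function(x, what, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  assert_finite(x, what)
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad)) {
    stop_input(sprintf(
      "`%s` must lie in %s%g, %g%s.", what,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Structured, suppressible log notes. Every silent data mutation the
# pipeline performs (clamping, fallbacks, ignored columns) goes through
# here, so a run can be audited from its message stream.
log_note <- function(stage, msg, ...) {
  rlang::inform(
    sprintf("[%s] %s", stage, sprintf(msg, ...)),
    class = "nutrisupply_note"
  )
}

log_warning <- function(stage, msg, ...) {
  rlang::warn(
    sprintf("[%s] %s", stage, sprintf(msg, ...)),
    class = "nutrisupply_warning"
  )
}

# Deterministic 31-bit hash of a character scalar (FNV-1a). Used to derive
# per-country RNG substreams so that the order in which countries are
# processed cannot change any result.
string_seed <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Combine a base seed with a string label into a 31-bit substream seed;
# arithmetic in double to avoid integer overflow.
substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + string_seed(label)) %%
               .Machine$integer.max)
}

# Days-per-year convention used when converting annual masses to
# per-person-per-day supplies. Explicit so it appears in exactly one place.
DAYS_PER_YEAR <- 365.25

#' Convert an annual commodity mass to a per-capita daily supply
#'
#' Converts tonnes/year into g/person/day given a population size, using a
#' 365.25 days/year convention.
#'
#' @param tonnes_per_year Numeric vector of annual masses (tonnes).
#' @param population Population of the country (persons), a positive number.
#' @return Numeric vector of supplies in g/person/day.
#' @export
#' @examples
#' per_capita_supply(41.6e3, 1e6) # ~113.9 g/person/day
per_capita_supply <- function(tonnes_per_year, population) {
  assert_nonneg(tonnes_per_year, "tonnes_per_year")
  assert_finite(population, "population")
  if (any(population <= 0)) stop_input("`population` must be positive.")
  tonnes_per_year * 1e6 / (population * DAYS_PER_YEAR)
}
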