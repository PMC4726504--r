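# Monte Carlo propagation of composition-table ambiguity into nutrient
# supply distributions.

MC_PROBS <- c(lower_95 = 0.025, median = 0.5, upper_95 = 0.975)

# All summary percentiles use the type-7 order-statistic definition with
# linear interpolation; centralised so the choice appears exactly once.
mc_quantiles <- function(x) {
  stats::quantile(x, probs = MC_PROBS, type = 7, names = FALSE)
}

#' Monte Carlo nutrient supply summaries for one country-year
#'
#' On each iteration one candidate composition entry is drawn uniformly
#' and independently for every food; the food's contribution is
#' `supply (g/day) x density / 100`, and contributions are summed across
#' foods into a national total per nutrient. Summaries over iterations
#' are the median and the 2.5th/97.5th percentiles (the 95% uncertainty
#' interval). With a single candidate per food every iteration is
#' identical and the interval has zero width.
#'
#' @param supplies Tibble `food,amount_g_day` of edible-basis supplies
#'   for one country-year.
#' @param candidates Named list (one element per food) of candidate
#'   density matrices: rows are candidate entries, columns are nutrients
#'   (see [candidate_matrix()]); all matrices must share the same
#'   nutrient columns.
#' @param n_iter Number of iterations, >= 1 (default 1000).
#' @param seed Integer seed; identical seed and inputs give identical
#'   summaries.
#' @param keep_draws Also return the full iterations-by-nutrients matrix
#'   of totals (for diagnostics and coupled group runs).
#' @return A tibble `nutrient,median,lower_95,upper_95,n_iterations`,
#'   with the draw matrix in attribute `"draws"` when `keep_draws = TRUE`.
#' @export
#' @examples
#' cand <- list(potato = matrix(70, 1, 1, dimnames = list("white", "calories")))
#' sup <- tibble::tibble(food = "potato", amount_g_day = 114)
#' mc_nutrient_supply(sup, cand, n_iter = 10, seed = 1) # 79.8 kcal/day
mc_nutrient_supply <- function(supplies, candidates, n_iter = 1000L,
                               seed = 1L, keep_draws = FALSE) {
  assert_columns(supplies, c("food", "amount_g_day"), "supplies")
  assert_nonneg(supplies$amount_g_day, "amount_g_day")
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1) stop_input("`n_iter` must be >= 1.")
  missing <- setdiff(supplies$food, names(candidates))
  if (length(missing) > 0) {
    stop_input(sprintf(
      "No candidate list for food(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  nutrients <- colnames(candidates[[supplies$food[1]]])
  if (is.null(nutrients)) stop_input("Candidate matrices must have nutrient column names.")

  totals <- matrix(0, nrow = n_iter, ncol = length(nutrients),
                   dimnames = list(NULL, nutrients))
  draws <- draw_candidate_indices(supplies$food, candidates, n_iter, seed)
  for (k in seq_len(nrow(supplies))) {
    f <- supplies$food[k]
    m <- candidates[[f]]
    if (!identical(colnames(m), nutrients)) {
      stop_input(sprintf("Candidate matrix for `%s` has mismatched nutrient columns.", f))
    }
    if (any(!is.finite(m))) {
      stop_input(sprintf("Non-finite density in candidate matrix for `%s`.", f))
    }
    totals <- totals + m[draws[[f]], , drop = FALSE] *
      (supplies$amount_g_day[k] / 100)
  }
  q <- apply(totals, 2, mc_quantiles)
  out <- tibble(
    nutrient = nutrients,
    median = unname(q[2, ]), lower_95 = unname(q[1, ]),
    upper_95 = unname(q[3, ]), n_iterations = n_iter
  )
  if (keep_draws) attr(out, "draws") <- totals
  out
}

# One uniform candidate draw per food per iteration, independent across
# foods and iterations. Seeded locally so the caller's RNG state is
# untouched and food order does not leak into other foods' draws.
draw_candidate_indices <- function(foods, candidates, n_iter, seed) {
  out <- list()
  for (f in unique(foods)) {
    ncand <- nrow(candidates[[f]])
    if (is.null(ncand) || ncand < 1) {
      stop_input(sprintf("Empty candidate list for food `%s`.", f))
    }
    fseed <- substream_seed(seed, f)
    out[[f]] <- withr::with_seed(fseed, sample.int(ncand, n_iter, replace = TRUE))
  }
  out
}

#' Monte Carlo nutrient supplies for a whole supply table
#'
#' Table-level driver: resolves candidates for every food of every
#' country via [resolve_candidates()] and runs [mc_nutrient_supply()]
#' per country-year. Each country uses an RNG substream derived
#' deterministically from the base seed and the country identifier, so
#' processing order cannot change results.
#'
#' @param supplies Edible-basis supply tibble.
#' @param composition Long composition tibble.
#' @param region_map Tibble `country,rank,table_id`.
#' @param n_iter,seed As in [mc_nutrient_supply()].
#' @param nutrients Character vector of nutrients (default the 23-
#'   nutrient set of [nutrient_set()]).
#' @return A tibble `country,year,nutrient,median,lower_95,upper_95,
#'   n_iterations`.
#' @export
nutrient_supplies <- function(supplies, composition, region_map,
                              n_iter = 1000L, seed = 1L,
                              nutrients = nutrient_set()$nutrient) {
  supplies <- validate_supply_table(supplies)
  keys <- dplyr::distinct(supplies, .data$country, .data$year)
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, ]
    sub <- supplies[supplies$country == key$country &
                      supplies$year == key$year, ]
    cands <- lapply(setNames(unique(sub$food), unique(sub$food)), function(f) {
      candidate_matrix(
        resolve_candidates(f, key$country, composition, region_map),
        nutrients
      )
    })
    cseed <- substream_seed(seed, key$country)
    summ <- mc_nutrient_supply(sub[, c("food", "amount_g_day")], cands,
                               n_iter = n_iter, seed = cseed)
    out[[i]] <- dplyr::bind_cols(
      tibble(country = key$country, year = key$year), summ
    )
  }
  dplyr::bind_rows(out)
}
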