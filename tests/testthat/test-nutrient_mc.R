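make_composition <- function() {
  tibble::tibble(
    table_id = c("regional", "regional", "regional", "usda", "india",
                 "fao_africa"),
    food = c("potatoes", "potatoes", "potatoes", "apples", "plums", "plums"),
    entry = c("russet", "red", "white", "apple_1", "plum_in", "plum_af"),
    nutrient = "calories",
    density_per_100g = c(79, 69, 70, 52, 46, 40),
    unit = "kcal"
  )
}

region_map <- tibble::tibble(
  country = c("A", "A"), rank = c(1L, 2L), table_id = c("regional", "usda")
)

test_that("candidate resolution walks the table chain", {
  comp <- make_composition()
  # present in the first chain table: all equally-matching entries kept
  hit <- resolve_candidates("potatoes", "A", comp, region_map)
  expect_setequal(hit$entry, c("russet", "red", "white"))

  # absent regionally, present downstream: downstream entries used
  hit2 <- resolve_candidates("apples", "A", comp, region_map)
  expect_equal(hit2$entry, "apple_1")

  # absent from the whole chain: global average over all tables
  expect_message(
    hit3 <- resolve_candidates("plums", "A", comp, region_map),
    "global average"
  )
  expect_equal(hit3$density_per_100g, mean(c(46, 40)))

  expect_error(resolve_candidates("durian", "A", comp, region_map),
               "durian", class = "nutrisupply_input_error")
})

test_that("candidate matrices fall back to the pool mean for missing nutrients", {
  cands <- tibble::tibble(
    table_id = "t", entry = c("e1", "e1", "e2"),
    nutrient = c("calories", "iron", "calories"),
    density_per_100g = c(100, 2, 80)
  )
  m <- nutrisupply:::candidate_matrix(cands, c("calories", "iron", "zinc"))
  expect_equal(m["e2", "iron"], 2)   # pool mean of the one observed value
  expect_equal(unname(m[, "zinc"]), c(0, 0)) # absent everywhere -> 0
})

test_that("a single-candidate food contributes supply x density / 100", {
  cand <- list(potatoes = matrix(70, 1, 1,
                                 dimnames = list("white", "calories")))
  sup <- tibble::tibble(food = "potatoes", amount_g_day = 114)
  out <- mc_nutrient_supply(sup, cand, n_iter = 100, seed = 1)
  expect_equal(out$median, 79.8)
  expect_equal(round(out$median), 80)
  # degenerate distribution: zero-width interval
  expect_equal(out$lower_95, out$upper_95)
})

test_that("Monte Carlo totals are linear, bounded, and reproducible", {
  toy <- mc_toy_instance()
  out <- mc_nutrient_supply(toy$supplies, toy$candidates, n_iter = 500,
                            seed = 7, keep_draws = TRUE)
  draws <- attr(out, "draws")

  # bounds: every iteration total lies between the all-min and all-max
  # candidate combinations
  expect_true(all(draws >= min(toy$enumerated) - 1e-12))
  expect_true(all(draws <= max(toy$enumerated) + 1e-12))
  expect_gte(out$lower_95, min(toy$enumerated))
  expect_lte(out$upper_95, max(toy$enumerated))

  # linearity: doubling supplies doubles every statistic exactly
  sup2 <- toy$supplies
  sup2$amount_g_day <- sup2$amount_g_day * 2
  out2 <- mc_nutrient_supply(sup2, toy$candidates, n_iter = 500, seed = 7)
  expect_equal(out2$median, 2 * out$median)
  expect_equal(out2$lower_95, 2 * out$lower_95)
  expect_equal(out2$upper_95, 2 * out$upper_95)

  # reproducibility: identical seed and inputs, identical summaries
  out3 <- mc_nutrient_supply(toy$supplies, toy$candidates, n_iter = 500,
                             seed = 7)
  expect_identical(out$median, out3$median)
  expect_identical(out$lower_95, out3$lower_95)

  expect_error(
    mc_nutrient_supply(toy$supplies, toy$candidates[1], n_iter = 10,
                       seed = 1),
    "candidate", class = "nutrisupply_input_error"
  )
})

test_that("summaries converge to the enumeration oracle on a tiny instance", {
  toy <- mc_toy_instance()
  out <- mc_nutrient_supply(toy$supplies, toy$candidates, n_iter = 4000,
                            seed = 11, keep_draws = TRUE)
  draws <- as.vector(attr(out, "draws"))
  v <- toy$enumerated
  # every total is one of the four enumerated combinations
  expect_true(all(vapply(draws, function(x) any(abs(x - v) < 1e-9), TRUE)))
  # each combination appears with frequency 1/4 within 3 binomial SEs
  se <- sqrt(0.25 * 0.75 / length(draws))
  for (val in v) {
    expect_lt(abs(mean(abs(draws - val) < 1e-9) - 0.25), 3 * se)
  }
  # outer percentiles sit at the extreme combinations; the median lies
  # in the oracle's median interval [v2, v3]
  expect_equal(out$lower_95, v[1], tolerance = 1e-6)
  expect_equal(out$upper_95, v[4], tolerance = 1e-6)
  expect_gte(out$median, v[2])
  expect_lte(out$median, v[3])
})

test_that("whole-table estimation is independent of country order", {
  b <- generate_world(fixture_spec(seed = 21, n_countries = 2,
                                   years = 2011L))
  sup <- food_supply(
    country = rep(c("C01", "C02"), each = 2), year = 2011L,
    food = rep(c("fruit_a", "veg_b"), 2),
    amount_g_day = c(120, 80, 60, 40), basis = "edible"
  )
  res1 <- suppressMessages(nutrient_supplies(
    sup, b$composition, b$comp_region_map, n_iter = 50, seed = 5
  ))
  res2 <- suppressMessages(nutrient_supplies(
    sup[rev(seq_len(nrow(sup))), ], b$composition, b$comp_region_map,
    n_iter = 50, seed = 5
  ))
  res2 <- res2[order(match(
    paste(res2$country, res2$nutrient),
    paste(res1$country, res1$nutrient)
  )), ]
  expect_equal(res1$median, res2$median)
  expect_equal(res1$lower_95, res2$lower_95)
})
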