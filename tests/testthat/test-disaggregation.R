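test_that("domestic supply is production + imports - exports, clamped at zero", {
  expect_equal(domestic_supply(100, 20, 30), 90)
  expect_equal(domestic_supply(0, 0, 0), 0)
  expect_warning(out <- domestic_supply(10, 0, 50), "clamped")
  expect_equal(out, max(0, 10 + 0 - 50))
  expect_error(domestic_supply(NaN, 0, 0), class = "nutrisupply_input_error")
})

test_that("primary-equivalent conversion multiplies by the factor", {
  expect_equal(to_primary_equivalent(10, 3.5), 35)
  expect_equal(to_primary_equivalent(0, 99), 0)
  expect_error(to_primary_equivalent(10, 0), class = "nutrisupply_input_error")

  # summing processed forms equals the hand-computed total
  amounts <- c(10, 4, 2.5)
  factors <- c(3.5, 1.2, 8)
  expect_equal(sum(to_primary_equivalent(amounts, factors)),
               10 * 3.5 + 4 * 1.2 + 2.5 * 8)
})

test_that("the parent food ratio is applied and preserved per child", {
  out <- apply_food_ratio(c(A = 60, B = 40), 100, 80)
  expect_equal(out, c(A = 48, B = 32))
  expect_equal(apply_food_ratio(c(A = 60, B = 40), 100, 100),
               c(A = 60, B = 40))
  expect_error(apply_food_ratio(c(A = 1), 0, 10),
               class = "nutrisupply_input_error")

  # ratio preservation on random fixtures
  withr::with_seed(1, {
    for (i in 1:20) {
      child <- stats::runif(5, 1, 100)
      pd <- sum(child) * stats::runif(1, 1, 2)
      pf <- pd * stats::runif(1, 0, 1)
      res <- apply_food_ratio(child, pd, pf)
      expect_equal(res / child, rep(pf / pd, 5))
      expect_equal(sum(res) / sum(child), pf / pd)
    }
  })
})

test_that("offal supply chains carcass-to-live and live-to-offal factors", {
  f <- tibble::tibble(
    animal_type = c("bovine", "pig", "poultry"),
    carcass_to_live = c(2.0, 1.7, 1.3),
    live_to_offal = c(0.05, 0.06, 0.04)
  )
  expect_equal(offal_supply(c(bovine = 100), f)$total, 100 * 2 * 0.05)
  expect_equal(offal_supply(c(bovine = 0, pig = 0), f)$total, 0)

  carc <- c(bovine = 100, pig = 50, poultry = 20)
  hand <- 100 * 2 * 0.05 + 50 * 1.7 * 0.06 + 20 * 1.3 * 0.04
  expect_equal(offal_supply(carc, f)$total, hand)
  expect_error(offal_supply(c(goat = 10), f), "goat",
               class = "nutrisupply_input_error")
})

test_that("the 1:1-line r-squared matches direct arithmetic and is unbounded below", {
  expect_equal(one_to_one_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(one_to_one_r2(c(1, 2, 3), c(1.1, 2.0, 2.9)), 1 - 0.02 / 1.62)
  expect_lt(one_to_one_r2(c(1, 2, 3) + 100, c(1.1, 2.0, 2.9)), 0)
  expect_error(one_to_one_r2(c(1, 2), c(5, 5)),
               class = "nutrisupply_input_error")
  expect_error(one_to_one_r2(1, 1), class = "nutrisupply_input_error")
})

test_that("disaggregation recovers constructed parents exactly and is monotone", {
  b <- generate_world(fixture_spec(seed = 11, nes_scenario = "none"))
  child <- nutrisupply:::validate_flow_long(b$flows_children,
                                            default_flag_map())
  parent <- nutrisupply:::validate_flow_long(b$flows_parents,
                                             default_flag_map())
  res <- suppressMessages(
    disaggregate_flows(child, parent, b$category_map, b$population)
  )
  expect_true(all(abs(res$validation$r2 - 1) < 1e-12))

  # increasing one child's production weakly increases its own food
  # supply and leaves the other children of other parents unchanged
  child2 <- child
  i <- which(child2$commodity == "fruit_a")[1]
  child2$production[i] <- child2$production[i] * 2
  res2 <- suppressMessages(
    disaggregate_flows(child2, parent, b$category_map, b$population)
  )
  key <- paste(res$supplies$country, res$supplies$year, res$supplies$food)
  key2 <- paste(res2$supplies$country, res2$supplies$year, res2$supplies$food)
  expect_identical(sort(key), sort(key2))
  m <- match(key, key2)
  bumped <- res$supplies$country == child$country[i] &
    res$supplies$year == child$year[i] & res$supplies$food == "fruit_a"
  expect_gte(res2$supplies$amount_g_day[m][bumped],
             res$supplies$amount_g_day[bumped])
  fruit_children <- b$category_map$child[
    b$category_map$parent_category == "fruit_other"
  ]
  untouched <- !res$supplies$food %in% fruit_children
  expect_equal(res2$supplies$amount_g_day[m][untouched],
               res$supplies$amount_g_day[untouched])
})
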