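test_that("energy adjustment normalises supplies to the reference diet", {
  expect_equal(energy_adjust(30, 3000), 20)
  expect_equal(energy_adjust(42, 2000), 42)
  expect_equal(energy_adjust(0, 2500), 0)
  expect_error(energy_adjust(10, 0), class = "nutrisupply_input_error")
})

test_that("group ratios apply by handling rule", {
  expect_equal(apply_group_ratio(20, "mapped", 1.10, TRUE), 22)
  expect_equal(apply_group_ratio(20, "uniform", NA, TRUE), 20)
  expect_equal(apply_group_ratio(20, "uniform", NA, FALSE), 20)
  expect_equal(apply_group_ratio(20, "adult_only", NA, FALSE), 0)
  expect_equal(apply_group_ratio(20, "adult_only", 1.3, TRUE), 26)
  # children and adolescents without an estimate take the average value
  expect_equal(apply_group_ratio(20, "mapped", NA, FALSE), 20)
  expect_error(apply_group_ratio(20, "bogus", 1, TRUE),
               class = "nutrisupply_input_error")
  expect_error(apply_group_ratio(20, "mapped", -1, TRUE),
               class = "nutrisupply_input_error")
})

test_that("group calories are allocated in proportion to requirements", {
  g <- tibble::tibble(population = c(1, 1),
                      energy_requirement = c(2200, 2800))
  out <- group_energy_supply(3000, g)
  expect_equal(out, c(2200, 2800) * 3000 / 2500)
  expect_equal(out[1], 2640)

  # equal requirements: every group receives the national supply
  eq <- tibble::tibble(population = c(2, 5), energy_requirement = c(2400, 2400))
  expect_equal(group_energy_supply(3100, eq), c(3100, 3100))

  # population-weighted mean equals the national supply
  withr::with_seed(8, {
    for (i in 1:10) {
      gg <- tibble::tibble(population = stats::runif(6, 1e4, 1e6),
                           energy_requirement = stats::runif(6, 1500, 3000))
      sup <- group_energy_supply(2700, gg)
      expect_equal(sum(gg$population * sup) / sum(gg$population), 2700)
    }
  })
  expect_error(group_energy_supply(3000, tibble::tibble(
    population = 0, energy_requirement = 2000
  )), class = "nutrisupply_input_error")
})

test_that("de-adjustment inverts energy adjustment", {
  expect_equal(deadjust(22, 2640), 29.04)
  expect_equal(round(deadjust(22, 2640)), 29)
  expect_equal(deadjust(15, 2000), 15)
  expect_equal(deadjust(energy_adjust(30, 3000), 3000), 30)
  expect_error(deadjust(10, 0), class = "nutrisupply_input_error")
})

test_that("population consistency enforcement rescales to the national mean", {
  gs <- tibble::tibble(
    food = "apples", group = c("g1", "g2"), amount_g_day = c(20, 40)
  )
  pops <- tibble::tibble(group = c("g1", "g2"), population = c(1, 1))
  nat <- tibble::tibble(food = "apples", amount_g_day = 30)
  out <- enforce_population_consistency(gs, pops, nat)
  expect_equal(out$amount_g_day, c(20, 40)) # already consistent

  nat$amount_g_day <- 30 / 1.1 # weighted mean 10% high
  out2 <- enforce_population_consistency(gs, pops, nat)
  expect_equal(out2$amount_g_day, c(20, 40) / 1.1)

  # random 34-group fixture: weighted mean matches to 1e-12 relative
  withr::with_seed(9, {
    groups <- sprintf("g%02d", 1:34)
    gs3 <- tidyr::expand_grid(food = c("a", "b", "c"), group = groups)
    gs3$amount_g_day <- stats::runif(nrow(gs3), 0, 100)
    pops3 <- tibble::tibble(group = groups,
                            population = stats::runif(34, 1e4, 1e6))
    nat3 <- tibble::tibble(food = c("a", "b", "c"),
                           amount_g_day = c(10, 55, 3))
    out3 <- enforce_population_consistency(gs3, pops3, nat3)
    check <- dplyr::summarise(
      dplyr::group_by(dplyr::left_join(out3, pops3, by = "group"), food),
      wmean = sum(population * amount_g_day) / sum(population)
    )
    expect_equal(check$wmean[match(nat3$food, check$food)],
                 nat3$amount_g_day, tolerance = 1e-12)
  })

  expect_error(enforce_population_consistency(
    tibble::tibble(food = "a", group = "g1", amount_g_day = 0),
    tibble::tibble(group = "g1", population = 1),
    tibble::tibble(food = "a", amount_g_day = 5)
  ), class = "nutrisupply_input_error")
})

test_that("the full demographic chain reduces to the national supplies in the symmetric limit", {
  groups <- tibble::tibble(
    group = c("f20", "m20"), sex = c("female", "male"),
    age_bracket = "20-24", is_adult = TRUE,
    population = c(3e5, 2e5), energy_requirement = c(2500, 2500)
  )
  supplies <- tibble::tibble(food = c("apples", "bread"),
                             amount_g_day = c(30, 150))
  gdd_map <- tibble::tibble(food = c("apples", "bread"),
                            gdd_category = c("fruit", "grains"),
                            handling = "mapped")
  ratios <- tidyr::expand_grid(gdd_category = c("fruit", "grains"),
                               group = c("f20", "m20"))
  ratios$ratio <- 1
  out <- agesex_supplies(supplies, 2800, groups, gdd_map, ratios)
  expect_equal(
    out$food_supplies$amount_g_day,
    rep(supplies$amount_g_day, each = 2),
    tolerance = 1e-12
  )
  # energy conservation holds exactly
  expect_equal(
    sum(groups$population * out$group_energy$energy_kcal_day) /
      sum(groups$population),
    2800
  )
})

test_that("group nutrient summaries degenerate correctly and stay coupled", {
  cands <- list(
    apples = matrix(52, 1, 1, dimnames = list("a", "calories")),
    bread = matrix(265, 1, 1, dimnames = list("b", "calories"))
  )
  gfs <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 2),
    food = rep(c("apples", "bread"), 2),
    amount_g_day = c(30, 100, 0, 0)
  )
  out <- group_nutrients(gfs, cands, n_iter = 20, seed = 1)
  g1 <- out[out$group == "g1", ]
  expect_equal(g1$median, 30 * 52 / 100 + 100 * 265 / 100)
  expect_equal(g1$lower_95, g1$upper_95)
  g2 <- out[out$group == "g2", ]
  expect_equal(g2$median, 0)

  # with shared draws, proportional groups give summaries proportional
  # to the national run (comonotone coupling)
  cands2 <- list(
    apples = matrix(c(40, 60), 2, 1,
                    dimnames = list(c("a1", "a2"), "calories"))
  )
  nat <- tibble::tibble(food = "apples", amount_g_day = 50)
  nat_out <- mc_nutrient_supply(nat, cands2, n_iter = 200, seed = 3)
  gfs2 <- tibble::tibble(group = c("g1", "g2"), food = "apples",
                         amount_g_day = c(25, 75))
  g_out <- group_nutrients(gfs2, cands2, n_iter = 200, seed = 3)
  # population weights (1,1): weighted mean of group medians equals the
  # national median because all groups share the same draws
  expect_equal(mean(g_out$median), nat_out$median)
  expect_equal(mean(g_out$lower_95), nat_out$lower_95)
})
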