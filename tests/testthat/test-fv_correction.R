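test_that("nes amounts are classified by data-quality flag", {
  all_official <- classify_nes(c(30, 20), c("official", "official"))
  expect_equal(all_official$redistributable, 0)
  expect_equal(all_official$retained, 50)

  all_estimated <- classify_nes(50, "estimated")
  expect_equal(all_estimated$redistributable, 50)
  expect_equal(all_estimated$retained, 0)

  mixed <- classify_nes(c(10, 40), c("official", "imputed"))
  expect_equal(mixed$redistributable, 40)
  expect_equal(mixed$retained, 10)
  expect_equal(mixed$dominant_flag, "imputed")

  expect_warning(u <- classify_nes(5, "unofficial"), "unofficial")
  expect_equal(u$retained, 5)
  u2 <- classify_nes(5, "unofficial", redistribute_unofficial = TRUE)
  expect_equal(u2$redistributable, 5)

  expect_error(classify_nes(1, "bogus"), class = "nutrisupply_input_error")
})

test_that("census redistribution splits the group total by census shares", {
  out <- redistribute_census(100, c(mango = 0.5, banana = 0.3, papaya = 0.2))
  expect_equal(out, c(mango = 50, banana = 30, papaya = 20))
  expect_equal(unname(redistribute_census(0, c(a = 0.6, b = 0.4))), c(0, 0))
  expect_error(redistribute_census(10, c(a = 0.6, b = 0.5)),
               class = "nutrisupply_input_error")

  # conservation is exact, the last food absorbing rounding residue
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- stats::runif(7)
      s <- s / sum(s)
      total <- stats::runif(1, 0, 1e6)
      expect_identical(sum(redistribute_census(total, s)), total)
    }
  })
})

test_that("proportional redistribution conserves mass and is idempotent at zero", {
  expect_equal(redistribute_proportional(50, c(A = 30, B = 20)),
               c(A = 60, B = 40))
  expect_equal(redistribute_proportional(0, c(A = 3, B = 2)),
               c(A = 3, B = 2))
  expect_error(redistribute_proportional(10, c(A = 0, B = 0)),
               class = "nutrisupply_input_error")

  withr::with_seed(4, {
    for (i in 1:20) {
      existing <- stats::runif(5, 0, 100)
      nes <- stats::runif(1, 0, 50)
      out <- redistribute_proportional(nes, existing)
      expect_equal(sum(out), sum(existing) + nes)
      # relative proportions among foods are unchanged
      expect_equal(out / sum(out), existing / sum(existing))
    }
  })
})

test_that("the exclusion rule fires at the threshold and is monotone", {
  expect_equal(exclusion_rule(5), "exclude")
  expect_equal(exclusion_rule(6), "retain")
  expect_equal(exclusion_rule(0), "exclude")
  expect_error(exclusion_rule(-1), class = "nutrisupply_input_error")

  # raising the threshold never converts excluded to retained
  for (n in 0:10) {
    decisions <- exclusion_rule(n, threshold = 0:10)
    excluded <- decisions == "exclude"
    expect_true(all(diff(excluded) >= 0))
  }
})

test_that("table-level correction redistributes estimated nes and retains official nes", {
  supplies <- food_supply(
    country = "A", year = 2011L,
    food = c(paste0("fruit_", 1:6), "fruit_nes"),
    amount_g_day = c(10, 20, 30, 40, 50, 60, 42)
  )
  group_map <- tibble::tibble(
    food = c(paste0("fruit_", 1:6), "fruit_nes"),
    food_group = "fruit", is_nes = c(rep(FALSE, 6), TRUE)
  )
  flags <- tibble::tibble(country = "A", year = 2011L, food = "fruit_nes",
                          flag = "estimated")
  res <- fv_correct(supplies, group_map, flags)
  expect_equal(sum(res$supplies$amount_g_day), sum(supplies$amount_g_day))
  expect_false("fruit_nes" %in% res$supplies$food)
  # proportional gains
  expect_equal(res$supplies$amount_g_day[res$supplies$food == "fruit_6"],
               60 + 42 * 60 / 210)

  flags$flag <- "official"
  res2 <- fv_correct(supplies, group_map, flags)
  expect_true("fruit_nes_retained" %in% res2$supplies$food)
  expect_equal(
    res2$supplies$amount_g_day[res2$supplies$food == "fruit_nes_retained"],
    42
  )
})

test_that("census shares replace the within-group split for the latest year", {
  supplies <- food_supply(
    country = "A", year = rep(c(2010L, 2011L), each = 3),
    food = rep(c("fruit_1", "fruit_2", "fruit_nes"), 2),
    amount_g_day = c(10, 20, 5, 12, 24, 6)
  )
  group_map <- tibble::tibble(
    food = c("fruit_1", "fruit_2", "fruit_nes", "fruit_3", "fruit_4",
             "fruit_5", "fruit_6"),
    food_group = "fruit",
    is_nes = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  # enough reported categories to avoid exclusion
  extra <- food_supply("A", rep(c(2010L, 2011L), each = 4),
                       rep(paste0("fruit_", 3:6), 2),
                       rep(1, 8))
  supplies <- dplyr::bind_rows(supplies, extra)
  flags <- tibble::tibble(country = "A", year = c(2010L, 2011L),
                          food = "fruit_nes", flag = "imputed")
  census <- tibble::tibble(country = "A", food_group = "fruit",
                           food = c("fruit_1", "fruit_2"),
                           share = c(0.7, 0.3))
  res <- fv_correct(supplies, group_map, flags, census_shares = census)
  latest <- res$supplies[res$supplies$year == 2011, ]
  total_2011 <- 12 + 24 + 6 + 4
  expect_equal(latest$amount_g_day[latest$food == "fruit_1"],
               0.7 * total_2011)
  # earlier years dropped for census countries
  expect_equal(nrow(res$supplies[res$supplies$year == 2010, ]), 0)
})
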