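# Shared helpers for building small in-code fixtures.

write_flow_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  readr::write_csv(rows, path, na = "")
  path
}

flow_rows <- function(country = "A", year = 2011L, commodity = "apples",
                      element = "production", value = 100, flag = "") {
  tibble::tibble(country = country, year = year, commodity = commodity,
                 element = element, value = value, flag = flag)
}

random_supplies <- function(n, seed = 42L) {
  withr::with_seed(seed, food_supply(
    country = sample(LETTERS[1:3], n, replace = TRUE),
    year = 2011L,
    food = paste0("food_", seq_len(n)),
    amount_g_day = stats::runif(n, 0, 500),
    basis = "edible"
  ))
}

# 2-food x 2-candidate Monte Carlo instance with its enumeration oracle:
# the four equiprobable totals of choosing one candidate per food.
mc_toy_instance <- function() {
  supplies <- tibble::tibble(food = c("f1", "f2"),
                             amount_g_day = c(100, 200))
  cand <- list(
    f1 = matrix(c(50, 80), 2, 1,
                dimnames = list(c("a", "b"), "calories")),
    f2 = matrix(c(10, 30), 2, 1,
                dimnames = list(c("c", "d"), "calories"))
  )
  totals <- as.vector(outer(c(50, 80) * 100 / 100, c(10, 30) * 200 / 100, "+"))
  list(supplies = supplies, candidates = cand,
       enumerated = sort(totals))
}
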