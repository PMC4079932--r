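# shared fixtures: small random-but-valid inputs built in code

# random abridged life table on the default grid with positive,
# age-increasing mortality
random_life_table <- function(grid = age_grid()) {
  k <- length(grid)
  m <- stats::runif(k, 0.01, 0.03) * exp(0.4 * (seq_len(k) - 1))
  P <- round(stats::runif(k, 2000, 20000))
  life_table(deaths = m * P, population = P, grid = grid)
}

random_prevalence <- function(k = 5) sort(stats::runif(k, 0.05, 0.9))

# small clustered survey scenario for fast simulation tests
small_scenario <- function(...) {
  hle_scenario(...)
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1)))
}
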