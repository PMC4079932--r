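test_that("degenerate prevalences reproduce the life table", {
  set.seed(10)
  lt <- random_life_table()
  h0 <- sullivan(lt, rep(0, 5))
  expect_equal(h0$hle, lt$ex)
  expect_equal(h0$uhle, rep(0, 5))
  h3 <- sullivan(lt, rep(0.3, 5))
  expect_equal(h3$hle, 0.7 * lt$ex, tolerance = 1e-12)
  expect_equal(h3$prop_uhle, rep(30, 5), tolerance = 1e-12)
})

test_that("healthy and unhealthy years sum to life expectancy", {
  set.seed(11)
  for (r in 1:50) {
    lt <- random_life_table()
    pi <- stats::runif(5)
    h <- sullivan(lt, pi)
    expect_rel_equal(h$hle + h$uhle, lt$ex, 1e-12)
    expect_true(all(h$hle >= 0 & h$uhle >= 0))
    expect_true(all(h$prop_uhle >= 0 & h$prop_uhle <= 100))
  }
})

test_that("the terminal proportion unhealthy equals the terminal prevalence", {
  set.seed(12)
  for (r in 1:20) {
    lt <- random_life_table()
    pi <- stats::runif(5)
    h <- sullivan(lt, pi)
    expect_equal(h$prop_uhle[5], 100 * pi[5], tolerance = 1e-9)
  }
})

test_that("swapping prevalence for its complement swaps HLE and UHLE", {
  set.seed(13)
  lt <- random_life_table()
  pi <- stats::runif(5)
  h1 <- sullivan(lt, pi)
  h2 <- sullivan(lt, 1 - pi)
  expect_equal(h1$hle, h2$uhle, tolerance = 1e-12)
  expect_equal(h1$uhle, h2$hle, tolerance = 1e-12)
})

test_that("raising any interval prevalence lowers HLE at earlier exact ages", {
  set.seed(14)
  lt <- random_life_table()
  pi <- rep(0.4, 5)
  base <- sullivan(lt, pi)
  for (i in 1:5) {
    pi2 <- pi; pi2[i] <- 0.6
    h <- sullivan(lt, pi2)
    expect_true(all(h$hle[1:i] < base$hle[1:i]))
    expect_true(all(h$uhle[1:i] > base$uhle[1:i]))
    if (i < 5) expect_equal(h$hle[(i + 1):5], base$hle[(i + 1):5])
  }
})

test_that("prevalence variances propagate through the Jagger formula", {
  set.seed(15)
  lt <- random_life_table()
  pi <- stats::runif(5, 0.2, 0.6)
  h0 <- sullivan(lt, pi, var_prev = rep(0, 5))
  expect_equal(h0$var_hle, rep(0, 5))
  expect_equal(h0$hle_hi - h0$hle_lo, rep(0, 5))

  vp <- stats::runif(5, 1e-4, 1e-3)
  h <- sullivan(lt, pi, var_prev = vp)
  # one-term tail at the open age: var = e80^2 var(pi_80) since L/l = e
  expect_equal(h$var_hle[5], lt$ex[5]^2 * vp[5], tolerance = 1e-12)
  # full cumulation, complement symmetry of the variance
  expect_equal(h$var_hle, rev(cumsum(rev(lt$Lx^2 * vp))) / lt$lx^2,
               tolerance = 1e-12)
  expect_equal(h$var_hle, h$var_uhle)
  expect_error(hle_variance(lt, pi, NULL), "required")
})

test_that("analytic HLE variance matches resampled clustered surveys", {
  set.seed(16)
  sc <- hle_scenario()
  lt <- registry_life_table(generate_mortality(sc), "women")
  B <- 300
  est <- vest <- numeric(B)
  for (b in seq_len(B)) {
    pt <- prevalence_table(generate_survey(sc), "global")
    h <- sullivan(lt, pt, sex = "women")  # fixed life table: prevalence-only
    est[b] <- h$hle[1]; vest[b] <- h$var_hle[1]
  }
  expect_gt(mean(vest) / stats::var(est), 0.75)
  expect_lt(mean(vest) / stats::var(est), 1.3)
})

test_that("group comparisons flag differences by their Wald intervals", {
  set.seed(17)
  lt <- random_life_table()
  pi <- stats::runif(5, 0.2, 0.6)
  h <- sullivan(lt, pi, var_prev = rep(4e-4, 5))
  same <- compare_health_expectancy(h, h)
  expect_equal(same$diff, rep(0, 5))
  expect_false(any(same$significant))
  expect_equal(same$hi - same$lo, 2 * 1.96 * sqrt(2 * h$var_hle),
               tolerance = 1e-12)

  lt2 <- random_life_table()
  h2 <- sullivan(lt2, pmin(pi + 0.2, 1), var_prev = rep(4e-4, 5))
  cmp <- compare_health_expectancy(h, h2, quantity = "uhle")
  expect_equal(cmp$diff, h2$uhle - h$uhle)
  expect_true(all(cmp$lo <= cmp$diff & cmp$diff <= cmp$hi))

  attr(h2, "indicator") <- "severe"
  attr(h, "indicator") <- "global"
  expect_error(compare_health_expectancy(h, h2), "indicator mismatch")
})

test_that("within-survey comparisons use the cross-sex covariance", {
  set.seed(18)
  sc <- hle_scenario()
  mort <- generate_mortality(sc)
  ltm <- registry_life_table(mort, "men")
  ltw <- registry_life_table(mort, "women")
  pt <- prevalence_table(generate_survey(sc), "global")
  cmp <- compare_sullivan(ltm, ltw, pt)
  hm <- sullivan(ltm, pt, sex = "men")
  hw <- sullivan(ltw, pt, sex = "women")
  naive <- compare_health_expectancy(hm, hw)
  expect_equal(cmp$diff, naive$diff, tolerance = 1e-12)
  # shared PSUs induce positive covariance on average, so the joint
  # variance is smaller where the accumulated cross-covariance dominates
  expect_lt(cmp$var[1], naive$var[1])
  expect_gt(min(cmp$var), 0)
})

test_that("mismatched grids and bad prevalences are rejected", {
  lt <- life_table(c(20, 50), c(1000, 500), grid = age_grid(c(60, 65)))
  expect_error(sullivan(lt, c(0.1, 0.2, 0.3)), "grid mismatch")
  expect_error(sullivan(lt, c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(sullivan(lt, c(0.1, 1.2)), "\\[0, 1\\]")
})
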