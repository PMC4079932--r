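test_that("age grids validate their structure and assign ages", {
  g <- age_grid()
  expect_equal(g$starts, c(60, 65, 70, 75, 80))
  expect_equal(g$widths, c(5, 5, 5, 5, Inf))
  expect_equal(g$labels[5], "80+")
  expect_error(age_grid(c(60, 60, 70)), "strictly increasing")
  expect_error(age_grid(65), "length")
  grp <- age_group(c(59, 60, 64.9, 65, 83, 102), g)
  expect_equal(as.character(grp),
               c(NA, "60-64", "60-64", "65-69", "80+", "80+"))
})

test_that("yearly death counts average arithmetically and keep the grid", {
  expect_equal(average_deaths(rbind(c(10, 20))), c(10, 20))
  expect_equal(average_deaths(list(c(9, 20), c(10, 22), c(11, 24))), c(10, 22))
  expect_equal(average_deaths(cbind(c(0, 0, 3))), 1.0)  # non-integer means kept
  expect_error(average_deaths(list(c(1, 2), c(1, 2, 3))), "mismatch")
  expect_error(average_deaths(rbind(c(-1, 2))), "non-negative")
})

test_that("the two-interval Chiang table matches its hand evaluation", {
  # frozen from evaluating q = nm/(1+(n-a)m), L = nl' + ad, L_w = l/m by hand
  lt <- life_table(deaths = c(0.02, 0.1) * c(1000, 500),
                   population = c(1000, 500),
                   grid = age_grid(c(60, 65)), radix = 1)
  expect_equal(lt$qx[1], 0.095238, tolerance = 1e-5)
  expect_equal(lt$lx[2], 0.904762, tolerance = 1e-5)
  expect_equal(lt$Lx, c(4.761905, 9.047619), tolerance = 1e-6)
  expect_equal(lt$ex, c(13.809524, 10.0), tolerance = 1e-6)
})

test_that("zero mortality before the open group leaves survival intact", {
  expect_warning(
    lt <- life_table(deaths = c(0, 0, 0, 0, 625), population = rep(5000, 5)),
    "zero death"
  )
  expect_equal(lt$lx, rep(1e5, 5))
  expect_equal(lt$ex[1], 28)   # 20 years closed + 1/0.125 in the open group
  expect_equal(lt$var_qx[1:4], rep(0, 4))
})

test_that("a constant central death rate gives e = 1/m at every exact age", {
  P <- c(8000, 6000, 5000, 3000, 2000)
  lt <- life_table(deaths = 0.2 * P, population = P)
  expect_equal(lt$ex, rep(5, 5), tolerance = 1e-9)
})

test_that("life-table identities hold for random mortality schedules", {
  set.seed(1)
  for (r in 1:50) {
    lt <- random_life_table()
    k <- nrow(lt)
    expect_true(all(lt$qx >= 0 & lt$qx <= 1))
    expect_equal(lt$qx[k], 1)
    expect_true(all(diff(lt$lx) <= 0))
    expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
    expect_rel_equal(lt$ex * lt$lx, lt$Tx, 1e-12)
    expect_rel_equal(lt$dx, lt$lx * lt$qx, 1e-12)
    # e can rise with age only within the width of the interval skipped
    expect_true(all(lt$ex[-k] <= lt$ex[-1] + lt$n[-k] + 1e-9))
    expect_true(all(lt$var_qx >= 0) && all(lt$var_ex >= 0))
  }
})

test_that("q stays in [0,1] across the admissible (m, a) range", {
  set.seed(2)
  g <- age_grid(c(60, 65))
  for (r in 1:100) {
    m <- stats::rexp(1, 2)
    a <- stats::runif(1, 1e-6, 5)
    lt <- suppressWarnings(
      life_table(deaths = c(m, 0.1) * 1000, population = c(1000, 1000),
                 grid = g, a = a))
    expect_true(lt$qx[1] >= 0 && lt$qx[1] <= 1)
  }
})

test_that("invalid mortality inputs are rejected", {
  P <- rep(1000, 5)
  expect_error(life_table(c(-1, 0, 0, 0, 10), P), "non-negative")
  expect_error(life_table(rep(10, 5), c(0, P[-1])), "positive")
  expect_error(life_table(rep(10, 4), P), "per grid interval")
  # survivors reach 80+ but no deaths are ever registered there
  expect_error(suppressWarnings(life_table(c(10, 10, 10, 10, 0), P)),
               "degenerate")
  expect_error(life_table(rep(10, 5), P, a = 7), "\\(0, n\\]")
})

test_that("triennium death totals shrink the expectancy variance threefold", {
  reg <- data.frame(sex = "men",
                    age_start = rep(c(60, 65, 70, 75, 80), 3),
                    year = rep(1:3, each = 5),
                    deaths = rep(c(150, 180, 220, 250, 480), 3),
                    population = rep(c(1e4, 8e3, 6e3, 45e2, 45e2), 3))
  lt3 <- registry_life_table(reg, "men")
  lt1 <- registry_life_table(reg[reg$year == 1, ], "men")
  expect_equal(lt3$ex, lt1$ex, tolerance = 1e-12)
  expect_equal(lt3$var_ex * 3, lt1$var_ex, tolerance = 1e-9)
})

test_that("life-expectancy differences carry Wald intervals", {
  set.seed(3)
  lt <- random_life_table()
  same <- le_difference(lt, lt)
  expect_equal(same$diff, rep(0, 5))
  expect_false(any(same$significant))

  a <- data.frame(age = 60, ex = 19.2, var_ex = 0.26)
  b <- data.frame(age = 60, ex = 23.7, var_ex = 0.21)
  d <- le_difference(a, b)
  expect_equal(d$diff, 4.5)
  expect_equal(d$hi - d$lo, 2 * 1.96 * sqrt(0.26 + 0.21), tolerance = 1e-12)
  expect_true(d$significant)

  expect_error(le_difference(a, data.frame(age = 65, ex = 1, var_ex = 0)),
               "grid mismatch")
})
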