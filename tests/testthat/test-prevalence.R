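test_that("indicator classification follows the dichotomization rules", {
  # walking-distance limitation only -> mild/moderate, not severe
  f <- classify_health("good", lim_mile = "limited", lim_yards = "not_limited",
                       lim_100yards = "not_limited", lim_bathing = "not_limited")
  expect_true(f$mild_moderate && f$global)
  expect_false(f$severe || f$poor_srh)

  # bathing/dressing limitation alone is severe and global, never mild
  f <- classify_health("excellent", FALSE, FALSE, FALSE, TRUE)
  expect_true(f$severe && f$global)
  expect_false(f$mild_moderate)

  # nothing limited, good health -> all flags off
  f <- classify_health("good", FALSE, FALSE, FALSE, FALSE)
  expect_false(any(unlist(f)))

  # all 16 item combinations: severe = i|j, exclusivity, global identity
  combos <- expand.grid(g = c(TRUE, FALSE), h = c(TRUE, FALSE),
                        i = c(TRUE, FALSE), j = c(TRUE, FALSE))
  f <- classify_health(rep("fair", 16), combos$g, combos$h, combos$i, combos$j)
  expect_equal(f$severe, combos$i | combos$j)
  expect_false(any(f$severe & f$mild_moderate))
  expect_equal(f$global, f$severe | f$mild_moderate)
  expect_true(all(f$poor_srh))

  # srh dichotomy over all five response levels
  f <- classify_health(c("excellent", "very good", "good", "fair", "poor"),
                       FALSE, FALSE, FALSE, FALSE)
  expect_equal(f$poor_srh, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("three-level and yes/no item codings collapse to limited", {
  f <- classify_health("good",
                       lim_mile = c("limited a lot", "limited a little", "not limited"),
                       lim_yards = c("no", "no", "yes"),
                       lim_100yards = "no", lim_bathing = "no")
  expect_equal(f$mild_moderate, c(TRUE, TRUE, TRUE))
  expect_error(classify_health("good", "sometimes", "no", "no", "no"),
               "invalid")
  expect_error(classify_health("meh", FALSE, FALSE, FALSE, FALSE), "invalid")
})

test_that("missing responses propagate to NA flags only when indeterminate", {
  f <- classify_health(NA, NA, "no", "no", "no")
  expect_true(is.na(f$poor_srh))
  expect_true(is.na(f$mild_moderate))  # hinges on the missing mile item
  expect_true(is.na(f$global))
  expect_false(f$severe)               # both severe items answered no
  # a determinate flag stays determinate despite another missing item
  f2 <- classify_health("good", "limited", NA, "no", "no")
  expect_true(f2$mild_moderate && f2$global)
})

test_that("weighted prevalence reduces to the weighted mean", {
  expect_equal(weighted_prevalence(c(1, 0, 0, 0, 0, 0, 0, 0))$prev, 0.125)
  expect_equal(weighted_prevalence(c(1, 0), w = c(2, 1))$prev, 2 / 3)
  set.seed(4)
  y <- stats::rbinom(40, 1, 0.3)
  expect_equal(weighted_prevalence(y)$prev, mean(y))
})

test_that("self-PSU equal-weight Taylor variance is binomial up to n/(n-1)", {
  set.seed(5)
  y <- stats::rbinom(200, 1, 0.35)
  est <- weighted_prevalence(y)
  n <- length(y); p <- mean(y)
  expect_equal(est$var, p * (1 - p) / n * n / (n - 1), tolerance = 1e-9)
})

test_that("single-PSU cells fall back to the deff-inflated binomial", {
  y <- c(1, 1, 0, 0)
  expect_warning(est <- weighted_prevalence(y, psu = rep(1, 4)), "single PSU")
  expect_equal(est$var, 2 * 0.5 * 0.5 / 4)
  est2 <- weighted_prevalence(y, method = "deff", deff0 = 3)
  expect_equal(est2$var, 3 * 0.25 / 4)
})

test_that("Taylor variance tracks the empirical variance of clustered samples", {
  # beta-binomial-style clusters with a known PSU effect
  set.seed(6)
  B <- 400; n_psu <- 40; m <- 12
  phat <- vhat <- numeric(B)
  for (b in seq_len(B)) {
    pc <- stats::plogis(stats::qlogis(0.3) + stats::rnorm(n_psu, 0, 0.6))
    y <- stats::rbinom(n_psu * m, 1, rep(pc, each = m))
    est <- weighted_prevalence(y, psu = rep(seq_len(n_psu), each = m))
    phat[b] <- est$prev; vhat[b] <- est$var
  }
  expect_gt(mean(vhat) / stats::var(phat), 0.8)
  expect_lt(mean(vhat) / stats::var(phat), 1.2)
  # clustering inflates variance well beyond binomial
  expect_gt(mean(vhat) / (0.3 * 0.7 / (n_psu * m)), 1.5)
})

test_that("prevalence tables are additive across exclusive indicators", {
  set.seed(7)
  srv <- generate_survey(hle_scenario(weight_cv = 0.4))
  pg <- prevalence_table(srv, "global")
  pm <- prevalence_table(srv, "mild_moderate")
  ps <- prevalence_table(srv, "severe")
  expect_equal(pg$prev, pm$prev + ps$prev, tolerance = 1e-12)
  expect_true(all(pg$lo >= 0 & pg$hi <= 1))
  expect_true(all(pg$n > 0))
})

test_that("chi-square tests are null at identical distributions", {
  y <- rep(c(1, 0), c(6, 14))
  g <- rep(c("a", "b"), 10)  # same y split in both groups
  pe <- suppressWarnings(prevalence_chisq(y, g, method = "pearson"))
  expect_equal(pe$statistic, 0)
  expect_equal(pe$p.value, 1)
  rs <- prevalence_chisq(y, g)
  expect_equal(rs$statistic, 0, tolerance = 1e-9)
  expect_equal(rs$p.value, 1, tolerance = 1e-6)
  expect_error(prevalence_chisq(rep(1, 20), g), "constant")
})

test_that("Rao-Scott equals Pearson under self-PSU equal weights", {
  set.seed(8)
  y <- stats::rbinom(300, 1, 0.4)
  g <- sample(c("a", "b"), 300, replace = TRUE)
  rs <- prevalence_chisq(y, g)
  pe <- prevalence_chisq(y, g, method = "pearson")
  expect_equal(rs$statistic, pe$statistic, tolerance = 1e-9)
  # single generalized design effect ~ n/(n-1)
  expect_equal(rs$design_effects, 300 / 299, tolerance = 0.02)
})
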