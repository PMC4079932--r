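#' Synthetic study scenario
#'
#' Bundles the parameters of the synthetic mortality registry and the
#' synthetic two-stage cluster survey, with known ground truth (see
#' [true_values()]). The defaults emulate the study conditions the
#' package is designed for: an urban population aged 60+ with
#' Gompertz-like adult mortality and a female survival advantage
#' (remaining life expectancy at 60 of about 19.2 years for men and
#' 23.7 for women), a household survey of about 1,500 respondents in 50
#' PSUs with a design effect near 2, and age-increasing,
#' sex-differentiated limitation prevalence (global limitations rising
#' from roughly a quarter/third at 60-64 to over a half/three quarters
#' at 80+ for men/women) with age-flat poor self-rated health.
#'
#' The limitation model is a latent ordered-logistic severity (none <
#' mild/moderate < severe) with a shared PSU random intercept: on the
#' cluster-specific logit scale, \eqn{P(\ge mild) = logis(\eta + u)} and
#' \eqn{P(severe) = logis(\eta + u - \delta)} with
#' \eqn{\eta = b_0 + b_1 (age - 62.5)} per sex and
#' \eqn{u \sim N(0, \sigma^2)} per PSU. Generating the two binary
#' severity levels from one latent scale makes mild/moderate and severe
#' mutually exclusive by construction, as the classification rules
#' require. `sigma` defaults to the value solving
#' \eqn{deff = 1 + (\bar m - 1)\rho_y} for the target design effect at
#' the PSU size `n_per_psu` (see [sigma_for_deff()]).
#'
#' @param alpha Gompertz baseline hazard at age 60, per sex (per year).
#' @param beta Gompertz log-slope per year of age, per sex.
#' @param population Mid-period population per age interval, per sex.
#' @param grid Age grid (default 60-64 ... 80+).
#' @param n_psu Number of survey PSUs (census tracts).
#' @param n_per_psu Respondents per PSU.
#' @param p_female Probability a respondent is a woman.
#' @param age_dist Per-sex probabilities of a respondent falling in each
#'   age group (rows `men`, `women`); ages are uniform within a group.
#' @param lim_b0,lim_slope Sex-named intercept (at age 62.5) and age
#'   slope of the latent limitation logit.
#' @param lim_delta Threshold gap between the global and severe levels.
#' @param srh_b0 Sex-named logit of poor self-rated health (age-flat).
#' @param deff_target Design effect the PSU effect is calibrated to.
#' @param sigma,sigma_srh PSU random-effect SDs; `NULL` solves for
#'   `deff_target`.
#' @param weight_cv Coefficient of variation of the (mean-1, lognormal)
#'   sampling weights; 0 gives constant weights.
#' @param max_age Upper bound for ages drawn in the open 80+ group.
#' @return A list of class `hle_scenario`.
#' @export
hle_scenario <- function(alpha = c(men = 0.01212, women = 0.00711),
                         beta = c(men = 0.095, women = 0.095),
                         population = list(men = c(17000, 13000, 9500, 6000, 5000),
                                           women = c(20000, 16500, 12500, 9000, 9000)),
                         grid = age_grid(),
                         n_psu = 50, n_per_psu = 30,
                         p_female = 0.595,
                         age_dist = rbind(men = c(218, 132, 117, 82, 66) / 615,
                                          women = c(256, 214, 164, 136, 134) / 904),
                         lim_b0 = c(men = -1.03, women = -0.72),
                         lim_slope = c(men = 0.055, women = 0.080),
                         lim_delta = 1.9,
                         srh_b0 = c(men = -1.95, women = -1.95),
                         deff_target = 2, sigma = NULL, sigma_srh = NULL,
                         weight_cv = 0, max_age = 90) {
  stopifnot(inherits(grid, "age_grid"))
  k <- length(grid)
  if (any(alpha <= 0)) stop("'alpha' must be positive")
  if (any(beta < 0)) stop("'beta' must be non-negative")
  for (s in c("men", "women")) {
    if (length(population[[s]]) != k)
      stop("'population$", s, "' must have one value per grid interval")
    if (any(population[[s]] <= 0)) stop("population counts must be positive")
  }
  if (n_psu < 2 || n_per_psu < 1) stop("need at least 2 PSUs with >= 1 respondent")
  if (p_female <= 0 || p_female >= 1) stop("'p_female' must be in (0, 1)")
  if (any(abs(rowSums(age_dist) - 1) > 1e-8))
    stop("'age_dist' rows must sum to 1")
  if (lim_delta <= 0) stop("'lim_delta' must be positive")
  if (max_age <= grid$starts[k]) stop("'max_age' must exceed the terminal exact age")
  if (is.null(sigma))
    sigma <- sigma_for_deff(deff_target, m_bar = n_per_psu)
  if (is.null(sigma_srh)) sigma_srh <- sigma
  if (sigma < 0 || sigma_srh < 0 || weight_cv < 0)
    stop("'sigma', 'sigma_srh' and 'weight_cv' must be non-negative")
  structure(list(alpha = alpha, beta = beta, population = population,
                 grid = grid, n_psu = n_psu, n_per_psu = n_per_psu,
                 p_female = p_female, age_dist = age_dist,
                 lim_b0 = lim_b0, lim_slope = lim_slope,
                 lim_delta = lim_delta, lim_ref_age = 62.5,
                 srh_b0 = srh_b0, sigma = sigma, sigma_srh = sigma_srh,
                 weight_cv = weight_cv, max_age = max_age),
            class = "hle_scenario")
}

#' @export
print.hle_scenario <- function(x, ...) {
  cat("Synthetic HLE scenario:", x$n_psu, "PSUs x", x$n_per_psu,
      "respondents; sigma =", round(x$sigma, 3), "\n")
  invisible(x)
}

#' PSU random-effect SD matching a target design effect
#'
#' Solves \eqn{deff = 1 + (\bar m - 1)\rho_y} for the latent normal PSU
#' SD \eqn{\sigma}, where the outcome intraclass correlation
#' \eqn{\rho_y} of the binary indicator is computed exactly by
#' integrating the logistic-normal model at a reference prevalence.
#'
#' @param deff Target design effect (> 1).
#' @param m_bar Average number of respondents per PSU.
#' @param p_ref Reference marginal prevalence (default 0.4).
#' @return The PSU SD \eqn{\sigma}.
#' @export
sigma_for_deff <- function(deff = 2, m_bar = 30, p_ref = 0.4) {
  if (deff <= 1) return(0)
  rho <- (deff - 1) / (m_bar - 1)
  icc <- function(s) {
    eta <- stats::qlogis(p_ref)
    # standardized substitution keeps the integrand well-scaled for tiny s
    m1 <- stats::integrate(function(t) stats::plogis(eta + s * t) * stats::dnorm(t),
                           -Inf, Inf, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(t) stats::plogis(eta + s * t)^2 * stats::dnorm(t),
                           -Inf, Inf, rel.tol = 1e-10)$value
    (m2 - m1^2) / (m1 * (1 - m1))
  }
  stats::uniroot(function(s) icc(s) - rho, c(1e-6, 5), tol = 1e-9)$root
}

# Gompertz survival from exact age 60: S(t) = exp(-alpha/beta (e^{beta t} - 1))
gompertz_survival <- function(t, alpha, beta) {
  if (beta == 0) exp(-alpha * t) else exp(-alpha / beta * (exp(beta * t) - 1))
}

# remaining life expectancy at age 60 + x0 under the Gompertz schedule
gompertz_ex <- function(x0, alpha, beta) {
  Sx <- gompertz_survival(x0, alpha, beta)
  stats::integrate(function(t) gompertz_survival(x0 + t, alpha, beta) / Sx,
                   0, Inf, rel.tol = 1e-10, subdivisions = 2000L)$value
}

# interval rates used by the registry generator: Gompertz rate at the
# closed-interval midpoint; occupancy-weighted average rate 1/e(80) for
# the open interval
scenario_rates <- function(scenario, sex) {
  grid <- scenario$grid
  k <- length(grid)
  al <- scenario$alpha[[sex]]
  be <- scenario$beta[[sex]]
  mid <- grid$starts[-k] + grid$widths[-k] / 2 - grid$starts[1]
  m <- al * exp(be * mid)
  m_term <- 1 / gompertz_ex(grid$starts[k] - grid$starts[1], al, be)
  c(m, m_term)
}

#' Generate a synthetic mortality registry
#'
#' Draws registered deaths per sex, age interval and calendar year as
#' independent Poisson counts with mean \eqn{m_i P_i}, where \eqn{m_i}
#' is the scenario's Gompertz rate at the interval midpoint (the
#' occupancy-weighted rate \eqn{1/e_{80}} in the open interval) and
#' \eqn{P_i} the scenario population. Deterministic given the RNG seed.
#'
#' @param scenario An [hle_scenario()].
#' @param years Number of calendar years (default 3, a triennium).
#' @return Data frame with columns `sex`, `age_start`, `year`, `deaths`,
#'   `population`.
#' @examples
#' set.seed(1)
#' head(generate_mortality(hle_scenario()))
#' @export
generate_mortality <- function(scenario, years = 3) {
  stopifnot(inherits(scenario, "hle_scenario"))
  grid <- scenario$grid
  out <- list()
  for (sex in c("men", "women")) {
    P <- scenario$population[[sex]]
    m <- scenario_rates(scenario, sex)
    lambda <- m * P
    if (any(lambda > 1e9))
      stop("overflow-scale populations: expected deaths exceed 1e9 in a cell")
    for (yr in seq_len(years)) {
      out[[length(out) + 1]] <- data.frame(
        sex = sex, age_start = grid$starts, year = yr,
        deaths = stats::rpois(length(P), lambda), population = P)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate synthetic clustered survey microdata
#'
#' Draws a two-stage cluster sample of respondents aged 60+ with sex,
#' age, sampling weight, PSU id, a five-category self-rated-health
#' response and the four limitation items, from the scenario's
#' logistic-normal models (see [hle_scenario()]). Item answers are
#' generated consistently with the latent severity category, so
#' [classify_health()] recovers it exactly: severe respondents are
#' limited in walking one hundred yards and/or bathing or dressing;
#' mild/moderate respondents are limited in one or both of the walking
#' distance items but in neither severe item.
#'
#' @param scenario An [hle_scenario()].
#' @return Data frame with columns `id`, `sex`, `age`, `weight`, `psu`,
#'   `srh`, `lim_mile`, `lim_yards`, `lim_100yards`, `lim_bathing`.
#' @examples
#' set.seed(1)
#' head(generate_survey(hle_scenario()))
#' @export
generate_survey <- function(scenario) {
  stopifnot(inherits(scenario, "hle_scenario"))
  grid <- scenario$grid
  k <- length(grid)
  n <- scenario$n_psu * scenario$n_per_psu
  psu <- rep(seq_len(scenario$n_psu), each = scenario$n_per_psu)
  u_lim <- stats::rnorm(scenario$n_psu, 0, scenario$sigma)[psu]
  u_srh <- stats::rnorm(scenario$n_psu, 0, scenario$sigma_srh)[psu]

  sex <- ifelse(stats::runif(n) < scenario$p_female, "women", "men")
  grp <- integer(n)
  for (s in c("men", "women")) {
    idx <- sex == s
    grp[idx] <- sample.int(k, sum(idx), replace = TRUE,
                           prob = scenario$age_dist[s, ])
  }
  lo <- grid$starts[grp]
  hi <- ifelse(is.finite(grid$widths[grp]), lo + grid$widths[grp], scenario$max_age)
  age <- stats::runif(n, lo, hi)

  eta <- scenario$lim_b0[sex] + scenario$lim_slope[sex] *
    (age - scenario$lim_ref_age) + u_lim
  p_glob <- stats::plogis(eta)
  p_sev <- stats::plogis(eta - scenario$lim_delta)
  r <- stats::runif(n)
  category <- ifelse(r < p_sev, "severe", ifelse(r < p_glob, "mild", "none"))

  lim_i <- lim_j <- lim_g <- lim_h <- rep(FALSE, n)
  sev <- category == "severe"
  lim_i[sev] <- stats::runif(sum(sev)) < 0.85
  lim_j[sev] <- stats::runif(sum(sev)) < 0.60
  lim_i[sev & !lim_i & !lim_j] <- TRUE       # severe => i and/or j
  lim_g[sev] <- stats::runif(sum(sev)) < 0.90
  lim_h[sev] <- stats::runif(sum(sev)) < 0.85
  mld <- category == "mild"
  lim_g[mld] <- stats::runif(sum(mld)) < 0.85
  lim_h[mld] <- stats::runif(sum(mld)) < 0.70
  lim_g[mld & !lim_g & !lim_h] <- TRUE       # mild => g and/or h

  p_poor <- stats::plogis(scenario$srh_b0[sex] + u_srh)
  poor <- stats::runif(n) < p_poor
  srh <- character(n)
  srh[poor] <- sample(c("fair", "poor"), sum(poor), replace = TRUE,
                      prob = c(0.9, 0.1))
  srh[!poor] <- sample(c("excellent", "very good", "good"), sum(!poor),
                       replace = TRUE, prob = c(0.111, 0.167, 0.722))

  weight <- if (scenario$weight_cv > 0) {
    sdl <- sqrt(log(1 + scenario$weight_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)

  data.frame(id = seq_len(n), sex = sex, age = age, weight = weight,
             psu = psu, srh = srh,
             lim_mile = ifelse(lim_g, "limited", "not_limited"),
             lim_yards = ifelse(lim_h, "limited", "not_limited"),
             lim_100yards = ifelse(lim_i, "limited", "not_limited"),
             lim_bathing = ifelse(lim_j, "limited", "not_limited"))
}

#' Ground truth of a synthetic scenario
#'
#' Computes, without sampling noise, the quantities the pipeline
#' estimates: remaining life expectancy at every exact grid age
#' (numerical integration of the Gompertz survival), the true prevalence
#' of each indicator per sex and age group (logistic-normal model
#' integrated over the PSU effect and the within-group uniform age
#' distribution), and the true healthy/unhealthy life expectancy
#' (integral of the survival weighted by the step-constant group
#' prevalences).
#'
#' @param scenario An [hle_scenario()].
#' @return List with elements `ex` (matrix sex x exact age), `prev`
#'   (list per indicator of matrices sex x age group), `hle` and `uhle`
#'   (lists per indicator of matrices sex x exact age).
#' @export
true_values <- function(scenario) {
  stopifnot(inherits(scenario, "hle_scenario"))
  grid <- scenario$grid
  k <- length(grid)
  sexes <- c("men", "women")
  inds <- c("poor_srh", "global", "mild_moderate", "severe")

  ex <- matrix(NA_real_, 2, k, dimnames = list(sexes, grid$labels))
  prev <- lapply(inds, function(i)
    matrix(NA_real_, 2, k, dimnames = list(sexes, grid$labels)))
  names(prev) <- inds
  hle <- uhle <- prev

  for (s in sexes) {
    al <- scenario$alpha[[s]]; be <- scenario$beta[[s]]
    x0 <- grid$starts - grid$starts[1]
    ex[s, ] <- vapply(x0, gompertz_ex, numeric(1), alpha = al, beta = be)

    # true cell prevalences: average the cluster-specific logistic over
    # the uniform age distribution (analytic in age) and the normal PSU
    # effect (numerical)
    for (gi in seq_len(k)) {
      a0 <- grid$starts[gi]
      a1 <- if (is.finite(grid$widths[gi])) a0 + grid$widths[gi] else scenario$max_age
      for (ind in inds) {
        if (ind == "poor_srh") {
          f <- function(u) stats::plogis(scenario$srh_b0[[s]] + u)
          sg <- scenario$sigma_srh
        } else {
          shift <- if (ind == "severe") scenario$lim_delta else 0
          b0 <- scenario$lim_b0[[s]] - shift
          b1 <- scenario$lim_slope[[s]]
          f <- function(u) mean_logis_over_age(b0 + u, b1, a0 - scenario$lim_ref_age,
                                               a1 - scenario$lim_ref_age)
          sg <- scenario$sigma
        }
        val <- if (sg == 0) f(0) else
          stats::integrate(function(t) vapply(sg * t, f, numeric(1)) * stats::dnorm(t),
                           -Inf, Inf, rel.tol = 1e-9)$value
        prev[[ind]][s, gi] <- val
      }
    }
    prev$mild_moderate[s, ] <- prev$global[s, ] - prev$severe[s, ]

    # person-years lived in each interval per unit survivor at 60
    Ival <- vapply(seq_len(k), function(gi) {
      a0 <- x0[gi]
      a1 <- if (is.finite(grid$widths[gi])) a0 + grid$widths[gi] else Inf
      stats::integrate(function(t) gompertz_survival(t, al, be), a0, a1,
                       rel.tol = 1e-10, subdivisions = 2000L)$value
    }, numeric(1))
    Sx <- gompertz_survival(x0, al, be)
    for (ind in inds) {
      unhealthy <- rev(cumsum(rev(prev[[ind]][s, ] * Ival))) / Sx
      uhle[[ind]][s, ] <- unhealthy
      hle[[ind]][s, ] <- ex[s, ] - unhealthy
    }
  }
  list(ex = ex, prev = prev, hle = hle, uhle = uhle)
}

# mean of plogis(b0 + b1 * x) for x uniform on [x0, x1]; analytic via
# the log-one-plus-exp antiderivative, with the b1 = 0 special case
mean_logis_over_age <- function(b0, b1, x0, x1) {
  if (b1 == 0) return(stats::plogis(b0))
  (log1pexp(b0 + b1 * x1) - log1pexp(b0 + b1 * x0)) / (b1 * (x1 - x0))
}

# numerically stable log(1 + exp(z))
log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
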