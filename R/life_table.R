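#' Average yearly death counts over a reference period
#'
#' Mortality rates for a single index year are commonly stabilised by
#' averaging registered deaths over a surrounding period (e.g. a
#' triennium) while keeping the mid-period population. This computes the
#' arithmetic mean of per-year death counts on a common age grid.
#'
#' @param yearly_deaths A numeric matrix or data frame (one row per year,
#'   one column per age interval), or a list of equal-length numeric
#'   vectors (one per year).
#' @return Numeric vector of averaged deaths, one per age interval.
#'   Non-integer values are expected and kept.
#' @examples
#' average_deaths(rbind(c(9, 20), c(10, 22), c(11, 24)))  # -> 10 22
#' @export
average_deaths <- function(yearly_deaths) {
  if (is.list(yearly_deaths) && !is.data.frame(yearly_deaths)) {
    len <- vapply(yearly_deaths, length, integer(1))
    if (length(unique(len)) != 1)
      stop("age grid mismatch: yearly death vectors have different lengths")
    yearly_deaths <- do.call(rbind, yearly_deaths)
  }
  m <- as.matrix(yearly_deaths)
  if (nrow(m) < 1) stop("at least one year of deaths is required")
  if (!is.numeric(m) || anyNA(m)) stop("death counts must be numeric and non-missing")
  if (any(m < 0)) stop("death counts must be non-negative")
  colMeans(m)
}

#' Abridged life table by the Chiang method
#'
#' Converts interval death counts and mid-period populations into the
#' standard abridged life-table columns, together with sampling variances
#' for the death probabilities and for life expectancy at each exact age.
#'
#' For a closed interval of width \eqn{n_i} with central death rate
#' \eqn{m_i = D_i/P_i} and average years lived by those dying \eqn{a_i},
#' the probability of death is
#' \deqn{q_i = n_i m_i / (1 + (n_i - a_i) m_i).}
#' The open terminal interval has \eqn{q = 1} and person-years
#' \eqn{L = l/m}. The variance of \eqn{q_i} is Chiang's
#' \eqn{q_i^2 (1-q_i) / D_i}, and the variance of \eqn{e_x} is the
#' weighted backward cumulation
#' \deqn{\mathrm{var}(e_x) = \frac{1}{l_x^2} \sum_{j \ge x}
#'   l_j^2 \left[(n_j - a_j) + e_{j+1}\right]^2 \mathrm{var}(q_j),}
#' over closed intervals, plus (by default) a delta-method term
#' \eqn{l_w^2 e_w^2 / D_w} for the open interval, where the terminal
#' expectancy \eqn{e_w = 1/m_w} is treated as a Poisson-count ratio.
#'
#' @param deaths Numeric vector of deaths per interval (possibly averaged
#'   over several years, so non-integer values are allowed).
#' @param population Numeric vector of mid-period population per interval.
#' @param grid An [age_grid()]; defaults to 60-64 ... 80+.
#' @param a Average years lived within the interval by those dying in it,
#'   for the closed intervals: a single number or a vector of length
#'   `length(grid) - 1`. Default `NULL` uses the midpoint rule
#'   \eqn{a_i = n_i/2}, the standard assumption at adult ages.
#' @param radix Starting cohort size \eqn{l} at the first exact age.
#' @param var_deaths Death counts entering the variance denominators.
#'   Defaults to `deaths`; when the rates are built from deaths averaged
#'   over several calendar years, pass the *total* registered deaths
#'   over the period so the variances reflect all counts that inform
#'   the rates.
#' @param terminal_variance Include the open-interval contribution to
#'   `var_ex`? Default `TRUE`.
#' @param z Normal quantile for the confidence limits (1.96 for 95%).
#' @return A data frame of class `life_table` with one row per interval:
#'   `age`, `n`, `deaths`, `population`, `mx`, `ax`, `qx`, `lx`, `dx`,
#'   `Lx`, `Tx`, `ex`, `var_qx`, `var_ex`, `se_ex`, `ex_lo`, `ex_hi`.
#'   The grid is attached as attribute `grid`.
#' @examples
#' lt <- life_table(deaths = c(171, 181, 223, 248, 475),
#'                  population = c(10200, 8050, 6300, 4450, 4550))
#' lt$ex[1]  # life expectancy at 60
#' @export
life_table <- function(deaths, population, grid = age_grid(), a = NULL,
                       radix = 1e5, var_deaths = deaths,
                       terminal_variance = TRUE, z = 1.96) {
  stopifnot(inherits(grid, "age_grid"))
  k <- length(grid)
  if (length(deaths) != k || length(population) != k)
    stop("'deaths' and 'population' must have one value per grid interval")
  if (anyNA(deaths) || anyNA(population))
    stop("'deaths' and 'population' must not contain NA")
  if (any(deaths < 0)) stop("death counts must be non-negative")
  if (any(population <= 0)) stop("population counts must be positive")
  if (length(var_deaths) != k || anyNA(var_deaths) || any(var_deaths < 0))
    stop("'var_deaths' must be one non-negative count per interval")

  n <- grid$widths
  if (is.null(a)) a <- n[-k] / 2
  if (length(a) == 1) a <- rep(a, k - 1)
  if (length(a) == k) a <- a[-k]  # terminal a is unused
  if (length(a) != k - 1) stop("'a' must have one value per closed interval")
  if (any(a <= 0) || any(a > n[-k]))
    stop("'a' must lie in (0, n] for every closed interval")

  m <- deaths / population
  q <- numeric(k)
  # capped at 1: the Chiang ratio exceeds 1 once a_i * m_i > 1
  q[-k] <- pmin(1, n[-k] * m[-k] / (1 + (n[-k] - a) * m[-k]))
  q[k] <- 1
  if (any(deaths[-k] == 0))
    warning("zero death counts in closed interval(s): q and var_q set to 0 there")

  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- numeric(k)
  L[-k] <- n[-k] * l[-1] + a * d[-k]
  if (l[k] > 0) {
    if (m[k] <= 0)
      stop("degenerate life table: survivors reach the open interval but its death rate is zero")
    L[k] <- l[k] / m[k]
  }
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  var_q <- numeric(k)
  pos <- var_deaths[-k] > 0
  var_q[-k][pos] <- (q[-k][pos]^2 * (1 - q[-k][pos])) / var_deaths[-k][pos]

  # var(e_x): backward cumulation of the closed-interval contributions,
  # optionally plus the delta-method term for the Poisson open interval
  contrib <- l[-k]^2 * ((n[-k] - a) + e[-1])^2 * var_q[-k]
  term <- 0
  if (terminal_variance && var_deaths[k] > 0 && l[k] > 0)
    term <- l[k]^2 * e[k]^2 / var_deaths[k]
  cum <- rev(cumsum(rev(c(contrib, term))))
  var_e <- ifelse(l > 0, cum / l^2, 0)
  se_e <- sqrt(var_e)

  out <- data.frame(
    age = grid$starts, n = n, deaths = deaths, var_deaths = var_deaths,
    population = population,
    mx = m, ax = c(a, NA), qx = q, lx = l, dx = d, Lx = L, Tx = Tx, ex = e,
    var_qx = var_q, var_ex = var_e, se_ex = se_e,
    ex_lo = e - z * se_e, ex_hi = e + z * se_e,
    row.names = grid$labels
  )
  attr(out, "grid") <- grid
  attr(out, "radix") <- radix
  class(out) <- c("life_table", "data.frame")
  out
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  radix <- attr(x, "radix")
  cat("Abridged life table (Chiang):", nrow(x), "age groups",
      if (!is.null(radix)) paste0("(radix ", format(radix, big.mark = ","), ")"),
      "\n")
  print.data.frame(round_df(as.data.frame(x), digits), ...)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  df
}

#' Difference in life expectancy between two groups
#'
#' Age-by-age Wald comparison (group B minus group A, e.g. women minus
#' men) with the variances of the two independent estimates summed.
#'
#' @param lt_a,lt_b Two [life_table()] objects (or data frames with
#'   columns `age`, `ex`, `var_ex`) on the same age grid.
#' @param z Normal quantile for the confidence limits.
#' @return Data frame with `age`, `ex_a`, `ex_b`, `diff`, `var`, `lo`,
#'   `hi` and logical `significant` (confidence interval excludes zero).
#' @export
le_difference <- function(lt_a, lt_b, z = 1.96) {
  need <- c("age", "ex", "var_ex")
  if (!all(need %in% names(lt_a)) || !all(need %in% names(lt_b)))
    stop("inputs must have columns age, ex, var_ex")
  if (nrow(lt_a) != nrow(lt_b) || any(lt_a$age != lt_b$age))
    stop("age grid mismatch between life tables")
  diff <- lt_b$ex - lt_a$ex
  v <- lt_a$var_ex + lt_b$var_ex
  lo <- diff - z * sqrt(v)
  hi <- diff + z * sqrt(v)
  data.frame(age = lt_a$age, ex_a = lt_a$ex, ex_b = lt_b$ex,
             diff = diff, var = v, lo = lo, hi = hi,
             significant = lo > 0 | hi < 0)
}
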