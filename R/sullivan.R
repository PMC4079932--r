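#' Sullivan decomposition of life expectancy into healthy and unhealthy years
#'
#' Partitions the person-years of an abridged life table by the
#' cross-sectional prevalence of an unhealthy state, giving healthy and
#' unhealthy life expectancy at every exact age of the grid:
#' \deqn{HLE_x = \frac{1}{l_x} \sum_{i \ge x} (1 - \pi_i) L_i, \qquad
#'       UHLE_x = \frac{1}{l_x} \sum_{i \ge x} \pi_i L_i,}
#' so that \eqn{HLE_x + UHLE_x = e_x} identically. The proportion of
#' unhealthy life expectancy is \eqn{100\,UHLE_x / e_x}; at the open
#' terminal age it equals \eqn{100\,\pi} of the terminal group for any
#' life table.
#'
#' Variances follow the delta-method approach of Jagger and colleagues.
#' The default mode `"prevalence_only"` keeps the survey sampling
#' component
#' \deqn{\mathrm{var}(HLE_x) = \frac{1}{l_x^2} \sum_{i \ge x} L_i^2
#'   \mathrm{var}(\pi_i),}
#' which is shared by `UHLE` (complement symmetry). Mode
#' `"plus_mortality"` adds the life-table component: the Chiang
#' expectancy-variance cumulation applied with health-weighted interval
#' survivorship, \eqn{l_j^2 [(n_j - a_j)(1-\pi_j) + HLE_{j+1}]^2
#' \mathrm{var}(q_j)} (and the analogous \eqn{\pi}-weighted form for
#' `UHLE`), plus the terminal Poisson term scaled by the healthy share.
#'
#' @param lt A [life_table()].
#' @param prev Either a numeric vector of prevalences (one per grid
#'   interval, in `[0, 1]`) or a [prevalence_table()]; if the table
#'   covers several groups, say which one with `sex`.
#' @param var_prev Optional numeric vector of prevalence variances; taken
#'   from `prev` when it is a `prevalence_table`. When absent, variance
#'   and confidence columns are `NA`.
#' @param sex Group to extract when `prev` spans several sexes.
#' @param variance `"prevalence_only"` (default) or `"plus_mortality"`.
#' @param z Normal quantile for confidence limits.
#' @return Data frame of class `health_expectancy` with one row per exact
#'   age: `age`, `ex`, `prev`, `hle`, `uhle`, `prop_uhle` (percent),
#'   `var_hle`, `var_uhle`, `se_hle`, `hle_lo`, `hle_hi`, `uhle_lo`,
#'   `uhle_hi`. The indicator name (if known), the variance mode and the
#'   grid are attached as attributes.
#' @examples
#' lt <- life_table(c(171, 181, 223, 248, 475),
#'                  c(10200, 8050, 6300, 4450, 4550))
#' sullivan(lt, prev = c(0.26, 0.29, 0.43, 0.49, 0.55))
#' @export
sullivan <- function(lt, prev, var_prev = NULL, sex = NULL,
                     variance = c("prevalence_only", "plus_mortality"),
                     z = 1.96) {
  variance <- match.arg(variance)
  if (!inherits(lt, "life_table")) stop("'lt' must be a life_table")
  grid <- attr(lt, "grid")
  indicator <- NA_character_
  prev_vcov <- NULL
  if (inherits(prev, "prevalence_table")) {
    indicator <- attr(prev, "indicator")
    stop_if_grid_mismatch(grid, attr(prev, "grid"), "life table and prevalence")
    vc <- attr(prev, "vcov")
    tab <- as.data.frame(prev)
    if (!is.null(sex)) tab <- tab[tab$sex == sex, , drop = FALSE]
    if (length(unique(tab$sex)) > 1)
      stop("'prev' spans several groups; select one with 'sex'")
    if (nrow(tab) == 0) stop("no prevalence rows for the requested group")
    ord <- order(tab$age)
    if (is.null(var_prev)) var_prev <- tab$var[ord]
    if (!is.null(vc)) prev_vcov <- vc[[unique(tab$sex)]]
    prev <- tab$prev[ord]
  }
  k <- nrow(lt)
  if (length(prev) != k)
    stop("age grid mismatch: prevalence must have one value per interval")
  if (anyNA(prev) || any(prev < 0) || any(prev > 1))
    stop("prevalences must lie in [0, 1]")

  hle <- rev(cumsum(rev((1 - prev) * lt$Lx))) / lt$lx
  uhle <- rev(cumsum(rev(prev * lt$Lx))) / lt$lx
  prop <- 100 * uhle / lt$ex

  if (!is.null(var_prev)) {
    if (length(var_prev) != k || anyNA(var_prev) || any(var_prev < 0))
      stop("'var_prev' must be one non-negative variance per interval")
    if (is.null(prev_vcov)) prev_vcov <- diag(var_prev, nrow = k)
    if (nrow(prev_vcov) != k)
      stop("prevalence covariance does not match the age grid")
    # quadratic form L' V L over the tail of the grid at each exact age;
    # off-diagonal terms carry the correlation between age cells that
    # share survey PSUs
    v_prev_comp <- vapply(seq_len(k), function(i) {
      idx <- i:k
      drop(t(lt$Lx[idx]) %*% prev_vcov[idx, idx, drop = FALSE] %*% lt$Lx[idx])
    }, numeric(1)) / lt$lx^2
    var_hle <- var_uhle <- v_prev_comp
    if (variance == "plus_mortality") {
      var_hle <- var_hle + mortality_component(lt, 1 - prev, hle)
      var_uhle <- var_uhle + mortality_component(lt, prev, uhle)
    }
  } else {
    var_hle <- var_uhle <- rep(NA_real_, k)
  }
  se_hle <- sqrt(var_hle)
  se_uhle <- sqrt(var_uhle)

  out <- data.frame(
    age = lt$age, ex = lt$ex, prev = prev,
    hle = hle, uhle = uhle, prop_uhle = prop,
    var_hle = var_hle, var_uhle = var_uhle, se_hle = se_hle,
    hle_lo = hle - z * se_hle, hle_hi = hle + z * se_hle,
    uhle_lo = uhle - z * se_uhle, uhle_hi = uhle + z * se_uhle,
    row.names = rownames(lt)
  )
  attr(out, "grid") <- grid
  attr(out, "indicator") <- indicator
  attr(out, "variance") <- variance
  class(out) <- c("health_expectancy", "data.frame")
  out
}

# life-table sampling contribution to var(HLE_x) (or var(UHLE_x)):
# Chiang's expectancy-variance cumulation with the interval person-years
# weighted by the healthy (resp. unhealthy) share
mortality_component <- function(lt, share, hx) {
  k <- nrow(lt)
  n <- lt$n
  a <- lt$ax[-k]
  contrib <- lt$lx[-k]^2 *
    ((n[-k] - a) * share[-k] + hx[-1])^2 * lt$var_qx[-k]
  term <- 0
  if (lt$var_deaths[k] > 0 && lt$lx[k] > 0)
    term <- lt$lx[k]^2 * hx[k]^2 / lt$var_deaths[k]
  rev(cumsum(rev(c(contrib, term)))) / lt$lx^2
}

#' Variance of healthy life expectancy
#'
#' The variance machinery of [sullivan()] on its own, for callers that
#' already have the point decomposition.
#'
#' @inheritParams sullivan
#' @param var_prev Prevalence variances, one per interval (required).
#' @return Numeric vector `var_hle` per exact age.
#' @export
hle_variance <- function(lt, prev, var_prev,
                         variance = c("prevalence_only", "plus_mortality")) {
  if (missing(var_prev) || is.null(var_prev))
    stop("prevalence variances are required")
  sullivan(lt, prev, var_prev, variance = match.arg(variance))$var_hle
}

#' Within-survey sex comparison of healthy/unhealthy life expectancy
#'
#' Compares `HLE` or `UHLE` between two groups whose prevalences come
#' from the *same* survey. Unlike [compare_health_expectancy()], which
#' assumes independent groups, this uses the joint PSU-linearized
#' covariance of all sex-by-age prevalence cells carried by the
#' [prevalence_table()]: respondents of both sexes share PSUs, so their
#' prevalence estimates are positively correlated and the variance of
#' the difference is smaller than the sum of the two variances. The
#' mortality components (independent registries) are added when
#' `variance = "plus_mortality"`.
#'
#' @param lt_a,lt_b [life_table()]s of the two groups.
#' @param prev A [prevalence_table()] covering both groups.
#' @param sex_a,sex_b Group labels in `prev` (difference is b minus a).
#' @param quantity `"hle"` or `"uhle"`.
#' @param variance `"prevalence_only"` or `"plus_mortality"`.
#' @param z Normal quantile for the confidence limits.
#' @return Data frame as in [compare_health_expectancy()].
#' @export
compare_sullivan <- function(lt_a, lt_b, prev, sex_a = "men", sex_b = "women",
                             quantity = c("hle", "uhle"),
                             variance = c("prevalence_only", "plus_mortality"),
                             z = 1.96) {
  quantity <- match.arg(quantity)
  variance <- match.arg(variance)
  if (!inherits(prev, "prevalence_table"))
    stop("'prev' must be a prevalence_table covering both groups")
  het_a <- sullivan(lt_a, prev, sex = sex_a, variance = "prevalence_only")
  het_b <- sullivan(lt_b, prev, sex = sex_b, variance = "prevalence_only")
  diff <- het_b[[quantity]] - het_a[[quantity]]
  k <- nrow(het_a)

  V <- attr(prev, "vcov_all")
  lab_a <- paste(sex_a, het_a$age, sep = ".")
  lab_b <- paste(sex_b, het_b$age, sep = ".")
  if (!is.null(V) && all(c(lab_a, lab_b) %in% rownames(V))) {
    # gradient of the difference wrt the joint prevalence vector:
    # +/- L_j / l_x on each group's tail cells (sign flips between HLE
    # and UHLE cancel in the quadratic form)
    v <- vapply(seq_len(k), function(i) {
      idx <- i:k
      g_a <- -lt_a$Lx[idx] / lt_a$lx[i]
      g_b <- lt_b$Lx[idx] / lt_b$lx[i]
      drop(t(g_a) %*% V[lab_a[idx], lab_a[idx], drop = FALSE] %*% g_a +
           t(g_b) %*% V[lab_b[idx], lab_b[idx], drop = FALSE] %*% g_b +
           2 * t(g_b) %*% V[lab_b[idx], lab_a[idx], drop = FALSE] %*% g_a)
    }, numeric(1))
  } else {
    v <- het_a[[paste0("var_", quantity)]] + het_b[[paste0("var_", quantity)]]
  }
  if (variance == "plus_mortality") {
    share_a <- if (quantity == "hle") 1 - het_a$prev else het_a$prev
    share_b <- if (quantity == "hle") 1 - het_b$prev else het_b$prev
    v <- v + mortality_component(lt_a, share_a, het_a[[quantity]]) +
      mortality_component(lt_b, share_b, het_b[[quantity]])
  }
  lo <- diff - z * sqrt(v)
  hi <- diff + z * sqrt(v)
  data.frame(age = het_a$age, a = het_a[[quantity]], b = het_b[[quantity]],
             diff = diff, var = v, lo = lo, hi = hi,
             significant = !is.na(v) & (lo > 0 | hi < 0))
}

#' Compare healthy/unhealthy life expectancy between two groups
#'
#' Wald comparison (group B minus group A) of `HLE` or `UHLE` at every
#' exact age, with the independent variances summed. Appropriate when
#' the two groups' prevalences come from independent surveys; for two
#' sexes measured in the same survey prefer [compare_sullivan()].
#'
#' @param het_a,het_b Two `health_expectancy` tables from [sullivan()]
#'   on the same grid and indicator.
#' @param quantity `"hle"` or `"uhle"`.
#' @param z Normal quantile for confidence limits.
#' @return Data frame with `age`, `a`, `b`, `diff`, `var`, `lo`, `hi`,
#'   `significant`.
#' @export
compare_health_expectancy <- function(het_a, het_b,
                                      quantity = c("hle", "uhle"), z = 1.96) {
  quantity <- match.arg(quantity)
  if (nrow(het_a) != nrow(het_b) || any(het_a$age != het_b$age))
    stop("age grid mismatch between health-expectancy tables")
  ia <- attr(het_a, "indicator"); ib <- attr(het_b, "indicator")
  if (!is.na(ia) && !is.na(ib) && ia != ib)
    stop("indicator mismatch: ", ia, " vs ", ib)
  va <- het_a[[paste0("var_", quantity)]]
  vb <- het_b[[paste0("var_", quantity)]]
  diff <- het_b[[quantity]] - het_a[[quantity]]
  v <- va + vb
  lo <- diff - z * sqrt(v)
  hi <- diff + z * sqrt(v)
  data.frame(age = het_a$age, a = het_a[[quantity]], b = het_b[[quantity]],
             diff = diff, var = v, lo = lo, hi = hi,
             significant = !is.na(v) & (lo > 0 | hi < 0))
}
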