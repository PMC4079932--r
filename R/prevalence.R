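#' Classify survey responses into dichotomous health-state indicators
#'
#' Builds the four indicators used throughout the package from a
#' five-category self-rated-health item and four yes/no physical
#' functioning items (limitations in walking more than a mile, walking
#' several hundred yards, walking one hundred yards, and bathing or
#' dressing):
#' \itemize{
#'   \item `poor_srh`: self-rated health is "fair" or "poor".
#'   \item `severe`: limited in walking one hundred yards and/or in
#'     bathing or dressing (the two most demanding items).
#'   \item `mild_moderate`: limited in walking more than a mile and/or
#'     several hundred yards, while *not* limited in either of the two
#'     severe items. Mild/moderate and severe are therefore mutually
#'     exclusive.
#'   \item `global`: limited in any of the four activities; equals
#'     `mild_moderate | severe` by construction.
#' }
#'
#' @param srh Character vector in `{excellent, very good, good, fair, poor}`.
#' @param lim_mile,lim_yards,lim_100yards,lim_bathing Limitation items:
#'   logical, `"limited"`/`"not_limited"`, `"yes"`/`"no"`, or the
#'   three-level form `"limited a lot"`/`"limited a little"`/
#'   `"not limited"` (the two limited levels collapse to limited).
#' @return Data frame of logicals `poor_srh`, `mild_moderate`, `severe`,
#'   `global`. `NA` inputs propagate to `NA` flags (complete-case
#'   handling is applied downstream, per indicator).
#' @examples
#' classify_health("good", lim_mile = TRUE, lim_yards = FALSE,
#'                 lim_100yards = FALSE, lim_bathing = FALSE)
#' @export
classify_health <- function(srh, lim_mile, lim_yards, lim_100yards, lim_bathing) {
  srh_levels <- c("excellent", "very good", "good", "fair", "poor")
  srh <- as.character(srh)
  bad <- !is.na(srh) & !(srh %in% srh_levels)
  if (any(bad))
    stop("invalid self-rated health response(s): ",
         paste(unique(srh[bad]), collapse = ", "))
  g <- as_limited(lim_mile, "lim_mile")
  h <- as_limited(lim_yards, "lim_yards")
  i <- as_limited(lim_100yards, "lim_100yards")
  j <- as_limited(lim_bathing, "lim_bathing")
  severe <- i | j
  mild_moderate <- (g | h) & !severe
  data.frame(poor_srh = srh %in% c("fair", "poor") |
               ifelse(is.na(srh), NA, FALSE),
             mild_moderate = mild_moderate,
             severe = severe,
             global = g | h | i | j)
}

# coerce a limitation item to logical; accepts logical, 0/1, yes/no,
# limited/not_limited, or the 3-level SF-36-style responses
as_limited <- function(x, what = "limitation item") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% c(0, 1))))
      stop("invalid ", what, " response(s): numeric values must be 0/1")
    return(x == 1)
  }
  x <- tolower(trimws(as.character(x)))
  yes <- c("limited", "yes", "limited a lot", "limited a little")
  no <- c("not_limited", "not limited", "no")
  bad <- !is.na(x) & !(x %in% c(yes, no))
  if (any(bad))
    stop("invalid ", what, " response(s): ",
         paste(unique(x[bad]), collapse = ", "))
  x %in% yes | ifelse(is.na(x), NA, FALSE)
}

#' Design-based estimate of a weighted proportion
#'
#' Estimates a prevalence \eqn{\pi = \sum w y / \sum w} with a
#' design-based variance under a with-replacement approximation for the
#' first sampling stage: the Taylor-linearized between-PSU estimator
#' \deqn{\widehat{\mathrm{var}}(\hat\pi) = \frac{a}{a-1}
#'   \sum_{c=1}^{a} Z_c^2 / W^2, \quad
#'   Z_c = \sum_{k \in c} w_k (y_k - \hat\pi),}
#' where \eqn{a} is the number of PSUs and \eqn{W = \sum w}. The design
#' effect is the ratio of this variance to the binomial
#' \eqn{\hat\pi(1-\hat\pi)/n}. When fewer than two PSUs are present (or
#' `method = "deff"`), the variance falls back to a design-effect
#' inflated binomial \eqn{\mathrm{deff}_0\,\hat\pi(1-\hat\pi)/n}.
#'
#' @param y Logical or 0/1 outcome vector.
#' @param w Positive sampling weights (default equal).
#' @param psu PSU identifiers (default each record its own PSU).
#' @param method `"taylor"` (default) or `"deff"`.
#' @param deff0 Assumed design effect for the fallback mode (default 2).
#' @param z Normal quantile for confidence limits.
#' @param ci `"wald"` (truncated to \[0, 1\]) or `"logit"`.
#' @return List with `prev`, `var`, `se`, `lo`, `hi`, `n`, `n_psu`,
#'   `deff`, `method`.
#' @export
weighted_prevalence <- function(y, w = NULL, psu = NULL,
                                method = c("taylor", "deff"), deff0 = 2,
                                z = 1.96, ci = c("wald", "logit")) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  y <- as.numeric(y)
  if (is.null(w)) w <- rep(1, length(y))
  if (is.null(psu)) psu <- seq_along(y)
  keep <- !is.na(y) & !is.na(w) & !is.na(psu)
  y <- y[keep]; w <- w[keep]; psu <- psu[keep]
  n <- length(y)
  if (n < 1) stop("no complete records in cell")
  if (any(w <= 0)) stop("weights must be positive")
  W <- sum(w)
  p <- sum(w * y) / W

  a <- length(unique(psu))
  used <- method
  if (method == "taylor" && a < 2) {
    warning("single PSU in cell: falling back to deff-inflated binomial variance")
    used <- "deff"
  }
  if (used == "taylor") {
    Zc <- rowsum(w * (y - p), group = psu)
    v <- a / (a - 1) * sum(Zc^2) / W^2
  } else {
    v <- deff0 * p * (1 - p) / n
  }
  srs <- p * (1 - p) / n
  deff <- if (srs > 0) v / srs else NA_real_
  se <- sqrt(v)
  if (ci == "wald" || p == 0 || p == 1) {
    lo <- max(0, p - z * se)
    hi <- min(1, p + z * se)
  } else {
    lse <- se / (p * (1 - p))  # delta method on the logit scale
    lo <- stats::plogis(stats::qlogis(p) - z * lse)
    hi <- stats::plogis(stats::qlogis(p) + z * lse)
  }
  list(prev = p, var = v, se = se, lo = lo, hi = hi,
       n = n, n_psu = a, deff = deff, method = used)
}

#' Prevalence of a health indicator by sex and age group
#'
#' Applies [classify_health()] and [weighted_prevalence()] cell by cell
#' over sex and age group. Records with a missing response for the
#' requested indicator are dropped from that indicator only
#' (complete-case analysis).
#'
#' @param data Survey data frame with columns `sex`, `age`, `srh`,
#'   `lim_mile`, `lim_yards`, `lim_100yards`, `lim_bathing`, and
#'   optionally `weight` and `psu`.
#' @param indicator One of `"poor_srh"`, `"global"`, `"mild_moderate"`,
#'   `"severe"`.
#' @param grid Age grid defining the groups (default 60-64 ... 80+).
#'   Records younger than the first exact age are excluded.
#' @param method,deff0,z,ci Passed on to [weighted_prevalence()].
#' @return Data frame of class `prevalence_table` with one row per
#'   sex-by-age cell: `sex`, `age`, `n`, `prev`, `var`, `se`, `lo`,
#'   `hi`, `deff`. The indicator and grid are attached as attributes,
#'   together with `vcov`: a per-sex list of full covariance matrices
#'   of the cell prevalences (PSUs are shared across age groups, so the
#'   cells are correlated; [sullivan()] uses these matrices when
#'   propagating prevalence uncertainty).
#' @export
prevalence_table <- function(data, indicator = c("poor_srh", "global",
                                                 "mild_moderate", "severe"),
                             grid = age_grid(),
                             method = c("taylor", "deff"), deff0 = 2,
                             z = 1.96, ci = c("wald", "logit")) {
  indicator <- match.arg(indicator)
  method <- match.arg(method)
  flags <- classify_health(data$srh, data$lim_mile, data$lim_yards,
                           data$lim_100yards, data$lim_bathing)
  y <- flags[[indicator]]
  grp <- age_group(data$age, grid)
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  psu <- if ("psu" %in% names(data)) data$psu else seq_len(nrow(data))
  sexes <- sort(unique(as.character(data$sex)))
  rows <- list()
  cells <- list()
  psu_f <- factor(psu)
  a_all <- nlevels(psu_f)
  for (s in sexes) {
    for (gi in seq_along(grid$starts)) {
      idx <- which(as.character(data$sex) == s &
                     !is.na(grp) & as.integer(grp) == gi & !is.na(y))
      if (length(idx) == 0) next
      est <- weighted_prevalence(y[idx], w[idx], psu[idx], method = method,
                                 deff0 = deff0, z = z, ci = ci)
      rows[[length(rows) + 1]] <- data.frame(
        sex = s, age = grid$starts[gi], n = est$n, prev = est$prev,
        var = est$var, se = est$se, lo = est$lo, hi = est$hi,
        deff = est$deff)
      cells[[paste(s, grid$starts[gi], sep = ".")]] <-
        list(idx = idx, prev = est$prev, var = est$var, sex = s)
    }
  }
  # joint covariance of all sex-by-age cell prevalences: domain
  # (subpopulation) linearization over the full PSU frame. PSUs span
  # several age groups and both sexes, so the cells are correlated;
  # the off-diagonal blocks feed the Sullivan variance and the
  # within-survey sex comparison.
  nc <- length(cells)
  V <- matrix(0, nc, nc, dimnames = list(names(cells), names(cells)))
  if (method == "taylor" && a_all >= 2) {
    score <- matrix(0, length(y), nc)
    for (j in seq_len(nc)) {
      idx <- cells[[j]]$idx
      score[idx, j] <- w[idx] * (y[idx] - cells[[j]]$prev) / sum(w[idx])
    }
    Zc <- rowsum(score, psu_f)
    V <- a_all / (a_all - 1) * crossprod(Zc)
    dimnames(V) <- list(names(cells), names(cells))
  } else {
    diag(V) <- vapply(cells, `[[`, numeric(1), "var")
  }
  cell_sex <- vapply(cells, `[[`, character(1), "sex")
  vcovs <- lapply(stats::setNames(sexes, sexes), function(s) {
    keep <- cell_sex == s
    V[keep, keep, drop = FALSE]
  })

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "indicator") <- indicator
  attr(out, "grid") <- grid
  attr(out, "vcov") <- vcovs
  attr(out, "vcov_all") <- V
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Chi-square test for a prevalence contrast under a complex design
#'
#' Tests independence between a grouping factor (sex or age group) and a
#' dichotomous health indicator. The default is a design-adjusted
#' Rao-Scott chi-square: the Pearson statistic is computed from the
#' weighted cell proportions and referred to a Satterthwaite-corrected
#' chi-square using the eigenvalues of the generalized design-effects
#' matrix (second-order correction). `method = "pearson"` gives the
#' classical Pearson test on unweighted counts (no continuity
#' correction) via [stats::chisq.test()].
#'
#' @param y Logical or 0/1 indicator vector.
#' @param group Factor (or coercible) with the comparison groups.
#' @param w,psu Weights and PSU ids (used by the Rao-Scott method).
#' @param method `"rao-scott"` (default) or `"pearson"`.
#' @return List with `statistic` (Pearson X^2 from weighted proportions,
#'   or the classical X^2), `df`, `p.value`, and for the Rao-Scott
#'   method the adjusted statistic and degrees of freedom.
#' @export
prevalence_chisq <- function(y, group, w = NULL, psu = NULL,
                             method = c("rao-scott", "pearson")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  group <- factor(group)
  if (is.null(w)) w <- rep(1, length(y))
  if (is.null(psu)) psu <- seq_along(y)
  keep <- !is.na(y) & !is.na(group) & !is.na(w) & !is.na(psu)
  y <- y[keep]; group <- droplevels(group[keep])
  w <- w[keep]; psu <- psu[keep]
  if (nlevels(group) < 2) stop("grouping factor needs at least two levels")
  if (length(unique(y)) < 2) stop("indicator is constant: empty row or column")
  if (method == "pearson") {
    ct <- stats::chisq.test(table(group, y), correct = FALSE)
    return(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p.value = ct$p.value, method = "pearson"))
  }
  rao_scott_chisq(y, group, w, psu)
}

# Rao-Scott second-order corrected chi-square for an R x 2 table.
# Cell proportions p_rc are ratio estimators with common denominator W;
# their covariance comes from with-replacement PSU linearization. The
# Pearson statistic (from weighted proportions, scaled by the unweighted
# n) is asymptotically a weighted sum of chi-square(1) variables with
# weights the eigenvalues of M %*% (n V), M the curvature of the
# statistic in the cell proportions; Satterthwaite matching gives the
# adjusted statistic and fractional degrees of freedom.
rao_scott_chisq <- function(y, group, w, psu) {
  R <- nlevels(group)
  C <- 2
  n <- length(y)
  W <- sum(w)
  cell <- (as.integer(group) - 1L) * C + (y + 1L)  # row-major r x c index
  RC <- R * C
  p <- numeric(RC)
  tab <- rowsum(w, cell)
  p[as.integer(rownames(tab))] <- tab / W
  pr <- rowSums(matrix(p, nrow = R, ncol = C, byrow = TRUE))
  pc <- colSums(matrix(p, nrow = R, ncol = C, byrow = TRUE))
  if (any(pr <= 0) || any(pc <= 0)) stop("empty row or column in table")
  E <- as.vector(t(outer(pr, pc)))            # row-major expected proportions
  X2 <- n * sum((p - E)^2 / E)

  # design covariance of the RC cell proportions (with-replacement PSUs)
  a <- length(unique(psu))
  if (a < 2) stop("Rao-Scott test needs at least two PSUs")
  ind <- matrix(0, n, RC)
  ind[cbind(seq_len(n), cell)] <- 1
  Zc <- rowsum(w * (ind - rep(p, each = n)), psu)   # a x RC cluster totals
  V <- a / (a - 1) * crossprod(Zc) / W^2

  # curvature of the Pearson statistic: h_rc = p_rc - p_r. p_.c
  rindex <- rep(seq_len(R), each = C)
  cindex <- rep(seq_len(C), times = R)
  H <- matrix(0, RC, RC)
  for (u in seq_len(RC)) for (v in seq_len(RC)) {
    H[u, v] <- (u == v) -
      (rindex[u] == rindex[v]) * pc[cindex[u]] -
      (cindex[u] == cindex[v]) * pr[rindex[u]]
  }
  M <- t(H) %*% diag(1 / E) %*% H
  lambda <- Re(eigen(M %*% (n * V), only.values = TRUE)$values)
  d <- (R - 1) * (C - 1)
  lambda <- sort(lambda, decreasing = TRUE)[seq_len(d)]
  lbar <- mean(lambda)
  a2 <- sum((lambda - lbar)^2) / (d * lbar^2)  # squared CV of the eigenvalues
  stat_adj <- X2 / (lbar * (1 + a2))
  df_adj <- d / (1 + a2)
  list(statistic = X2, statistic_adj = stat_adj, df = df_adj,
       design_effects = lambda,
       p.value = stats::pchisq(stat_adj, df_adj, lower.tail = FALSE),
       method = "rao-scott")
}
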