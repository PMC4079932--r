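#' Read a mortality registry file
#'
#' Reads delimited text with columns `sex`, `age_start`, `deaths`,
#' `population` and optionally `year` (one row per sex, interval and
#' year). Every row is validated; offending rows are reported with
#' their line numbers (line 1 is the header).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_mortality <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_start", "deaths", "population")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mortality file is missing column(s): ", paste(miss, collapse = ", "))
  problems <- character(0)
  line <- seq_len(nrow(df)) + 1L
  bad <- function(cond, msg) {
    w <- which(cond)
    if (length(w)) problems <<- c(problems, paste0("line ", line[w], ": ", msg))
  }
  bad(!is.finite(df$deaths), "deaths is missing or non-numeric")
  bad(!is.finite(df$population), "population is missing or non-numeric")
  bad(is.finite(df$deaths) & df$deaths < 0, "negative deaths")
  bad(is.finite(df$population) & df$population <= 0, "non-positive population")
  bad(!is.finite(df$age_start), "age_start is missing or non-numeric")
  if (length(problems))
    stop("invalid mortality file:\n  ", paste(problems, collapse = "\n  "))
  df
}

#' Read a survey microdata file
#'
#' Reads delimited text with columns `id`, `sex`, `age`, `weight`,
#' `psu`, `srh`, `lim_mile`, `lim_yards`, `lim_100yards`,
#' `lim_bathing`. Structural problems are reported with line numbers;
#' missing responses are allowed (handled complete-case downstream).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "weight", "psu", "srh",
            "lim_mile", "lim_yards", "lim_100yards", "lim_bathing")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("survey file is missing column(s): ", paste(miss, collapse = ", "))
  problems <- character(0)
  line <- seq_len(nrow(df)) + 1L
  bad <- function(cond, msg) {
    w <- which(cond)
    if (length(w)) problems <<- c(problems, paste0("line ", line[w], ": ", msg))
  }
  bad(!is.finite(df$age) | df$age < 0, "invalid age")
  bad(!is.finite(df$weight) | df$weight <= 0, "non-positive or missing weight")
  srh_ok <- is.na(df$srh) |
    df$srh %in% c("excellent", "very good", "good", "fair", "poor")
  bad(!srh_ok, "self-rated health outside its response domain")
  for (item in c("lim_mile", "lim_yards", "lim_100yards", "lim_bathing")) {
    v <- tolower(trimws(as.character(df[[item]])))
    ok <- is.na(df[[item]]) | v %in% c("limited", "not_limited", "not limited",
                                       "yes", "no", "true", "false",
                                       "limited a lot", "limited a little")
    bad(!ok, paste0(item, " outside its response domain"))
  }
  if (length(problems))
    stop("invalid survey file:\n  ", paste(problems, collapse = "\n  "))
  df
}

#' Build a life table from a registry data frame
#'
#' Convenience wrapper: subsets one sex from a registry read with
#' [read_mortality()] (or generated with [generate_mortality()]),
#' averages the death counts over the calendar years present, pairs
#' them with the mid-period population, and calls [life_table()].
#'
#' @param registry Data frame with columns `sex`, `age_start`, `deaths`,
#'   `population` and optionally `year`.
#' @param sex Which sex to extract.
#' @param grid Age grid; must match the `age_start` values present.
#' @param ... Passed to [life_table()].
#' @return A [life_table()].
#' @export
registry_life_table <- function(registry, sex, grid = age_grid(), ...) {
  sub <- registry[registry$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0) stop("no registry rows for sex ", sex)
  if (!"year" %in% names(sub)) sub$year <- 1L
  starts <- sort(unique(sub$age_start))
  if (length(starts) != length(grid$starts) || any(starts != grid$starts))
    stop("age grid mismatch between registry and grid")
  yearly <- lapply(split(sub, sub$year), function(d)
    d$deaths[match(grid$starts, d$age_start)])
  deaths <- average_deaths(yearly)
  pop <- sub$population[match(grid$starts, sub$age_start)]
  # variances use the total deaths registered over the period
  life_table(deaths, pop, grid = grid,
             var_deaths = deaths * length(yearly), ...)
}

#' Printed prevalence estimates from the 2008 Campinas survey
#'
#' Published design-based prevalence estimates (percent, with 95%
#' confidence limits and unweighted cell sizes) of poor self-rated
#' health and the three limitation indicators among residents aged 60+
#' of Campinas, Brazil, by sex and five-year age group (ISACAMP 2008
#' household survey). Useful as a realistic prevalence input when no
#' microdata are at hand. Variances are reconstructed from the
#' confidence limits as `((hi - lo)/2/1.96)^2` on the proportion scale.
#'
#' @param indicator Optional: one of `"poor_srh"`, `"global"`,
#'   `"mild_moderate"`, `"severe"`.
#' @param sex Optional: `"men"` or `"women"`.
#' @return Data frame with `indicator`, `sex`, `age`, `n`, `prev`
#'   (proportion), `var`, `lo`, `hi`. When filtered to a single
#'   indicator it carries `prevalence_table` attributes and can be fed
#'   straight to [sullivan()].
#' @export
campinas_prevalence <- function(indicator = NULL, sex = NULL) {
  path <- system.file("extdata", "campinas2008_prevalence.csv",
                      package = "healthexp", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(indicator = df$indicator, sex = df$sex,
                    age = df$age_start, n = df$n,
                    prev = df$prev_pct / 100,
                    var = ((df$hi_pct - df$lo_pct) / 2 / 1.96 / 100)^2,
                    lo = df$lo_pct / 100, hi = df$hi_pct / 100)
  if (!is.null(sex)) {
    sx <- match.arg(sex, c("men", "women"))
    out <- out[out$sex == sx, , drop = FALSE]
  }
  if (!is.null(indicator)) {
    indicator <- match.arg(indicator,
                           c("poor_srh", "global", "mild_moderate", "severe"))
    out <- out[out$indicator == indicator, , drop = FALSE]
    attr(out, "indicator") <- indicator
    attr(out, "grid") <- age_grid()
    class(out) <- c("prevalence_table", "data.frame")
  }
  rownames(out) <- NULL
  out
}

#' Printed life expectancies from the 2008 Campinas life tables
#'
#' Published remaining life expectancy at exact ages 60 to 80 by sex
#' (Campinas, Brazil, 2008; triennium-averaged registered deaths), with
#' 95% confidence limits where published.
#'
#' @return Data frame with `sex`, `age`, `ex`, `lo`, `hi`.
#' @export
campinas_life_expectancy <- function() {
  path <- system.file("extdata", "campinas2008_life_expectancy.csv",
                      package = "healthexp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

fmt1 <- function(x) ifelse(is.na(x), "", formatC(round(x, 1), format = "f", digits = 1))
star <- function(sig) ifelse(!is.na(sig) & sig, "*", "")

#' Render the three report tables
#'
#' Writes CSV and Markdown versions of the standard outputs: the
#' prevalence table (indicator by sex and age, with confidence limits),
#' the life-expectancy table (by sex, with the between-sex difference),
#' and the health-expectancy table (healthy years, unhealthy years and
#' percent-unhealthy blocks per indicator, with difference columns and
#' significance stars where the Wald interval excludes zero). Numbers
#' are rounded to one decimal (round-half-even) at render time only.
#'
#' @param dir Output directory (created if needed).
#' @param prevalence Named list (by indicator) of [prevalence_table()]s
#'   covering both sexes, or `NULL`.
#' @param lifetables List with elements `men` and `women`
#'   ([life_table()]s), or `NULL`.
#' @param het Nested list `het[[indicator]][[sex]]` of [sullivan()]
#'   tables, or `NULL`.
#' @param comparisons Nested list `comparisons[[indicator]][[quantity]]`
#'   from [compare_health_expectancy()] (quantities `hle`, `uhle`), and
#'   optionally `comparisons$le` from [le_difference()]; or `NULL`.
#' @return Invisibly, the paths of the files written.
#' @export
render_tables <- function(dir, prevalence = NULL, lifetables = NULL,
                          het = NULL, comparisons = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if (!is.null(prevalence)) {
    rows <- list()
    for (ind in names(prevalence)) {
      pt <- prevalence[[ind]]
      for (s in unique(pt$sex)) {
        sub <- pt[pt$sex == s, ]
        rows[[length(rows) + 1]] <- data.frame(
          indicator = ind, sex = s, age = sub$age, n = sub$n,
          prevalence = fmt1(100 * sub$prev),
          ci = paste0("(", fmt1(100 * sub$lo), " - ", fmt1(100 * sub$hi), ")"))
      }
    }
    written <- c(written, write_report(do.call(rbind, rows), dir, "prevalence"))
  } else warning("prevalence block missing: partial report")

  if (!is.null(lifetables)) {
    cmp <- if (!is.null(comparisons$le)) comparisons$le else
      le_difference(lifetables$men, lifetables$women)
    tab <- data.frame(
      age = lifetables$men$age,
      le_men = fmt1(lifetables$men$ex),
      ci_men = paste0("(", fmt1(lifetables$men$ex_lo), " - ",
                      fmt1(lifetables$men$ex_hi), ")"),
      le_women = fmt1(lifetables$women$ex),
      ci_women = paste0("(", fmt1(lifetables$women$ex_lo), " - ",
                        fmt1(lifetables$women$ex_hi), ")"),
      difference = paste0(fmt1(cmp$diff), star(cmp$significant)))
    written <- c(written, write_report(tab, dir, "life_expectancy"))
  } else warning("life-table block missing: partial report")

  if (!is.null(het)) {
    rows <- list()
    for (ind in names(het)) {
      hm <- het[[ind]]$men; hw <- het[[ind]]$women
      # conservation re-assertion before rendering
      for (h in list(hm, hw))
        if (any(abs(h$hle + h$uhle - h$ex) > 1e-6 * pmax(h$ex, 1)))
          stop("healthy + unhealthy years do not sum to life expectancy")
      cmp <- comparisons[[ind]]
      blocks <- list(
        hle = list(m = hm$hle, w = hw$hle, d = cmp$hle),
        uhle = list(m = hm$uhle, w = hw$uhle, d = cmp$uhle),
        prop_uhle = list(m = hm$prop_uhle, w = hw$prop_uhle, d = NULL))
      for (b in names(blocks)) {
        bk <- blocks[[b]]
        diffs <- if (!is.null(bk$d)) paste0(fmt1(bk$d$diff), star(bk$d$significant))
                 else fmt1(bk$w - bk$m)
        rows[[length(rows) + 1]] <- data.frame(
          block = b, indicator = ind, age = hm$age,
          men = fmt1(bk$m), women = fmt1(bk$w), difference = diffs)
      }
    }
    written <- c(written, write_report(do.call(rbind, rows), dir, "health_expectancy"))
  } else warning("health-expectancy block missing: partial report")

  invisible(written)
}

# write a data frame as CSV and a simple pipe-delimited Markdown table
write_report <- function(df, dir, name) {
  csv <- file.path(dir, paste0(name, ".csv"))
  md <- file.path(dir, paste0(name, ".md"))
  utils::write.csv(df, csv, row.names = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  writeLines(c(header, sep, body), md)
  c(csv, md)
}
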