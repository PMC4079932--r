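#' Abridged age grid
#'
#' Defines the age intervals of an abridged life table: a set of exact
#' starting ages, interval widths, and an open-ended (terminal) final
#' interval. The default grid is the five groups 60-64, 65-69, 70-74,
#' 75-79 and 80+ used throughout the package.
#'
#' @param starts Integer-valued vector of exact ages opening each interval,
#'   strictly increasing. The last interval is always open-ended.
#' @return An object of class `age_grid`: a list with `starts`, `widths`
#'   (the terminal width is `Inf`) and human-readable `labels`.
#' @examples
#' age_grid()
#' age_grid(c(0, 1, seq(5, 85, by = 5)))
#' @export
age_grid <- function(starts = c(60, 65, 70, 75, 80)) {
  if (!is.numeric(starts) || length(starts) < 2 || anyNA(starts))
    stop("'starts' must be a numeric vector of length >= 2 with no NAs")
  starts <- as.numeric(starts)
  if (any(diff(starts) <= 0))
    stop("age grid starts must be strictly increasing")
  k <- length(starts)
  widths <- c(diff(starts), Inf)
  labels <- c(paste0(starts[-k], "-", starts[-1] - 1),
              paste0(starts[k], "+"))
  structure(list(starts = starts, widths = widths, labels = labels),
            class = "age_grid")
}

#' @export
length.age_grid <- function(x) length(x$starts)

#' @export
print.age_grid <- function(x, ...) {
  cat("Abridged age grid:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Assign ages to age-grid intervals
#'
#' Intervals are left-closed: `[60, 65), ..., [80, Inf)`. Ages below the
#' first exact age map to `NA`.
#'
#' @param age Numeric vector of ages in years.
#' @param grid An [age_grid()].
#' @return A factor with one level per grid interval, in grid order.
#' @export
age_group <- function(age, grid = age_grid()) {
  stopifnot(inherits(grid, "age_grid"))
  cut(age, breaks = c(grid$starts, Inf), right = FALSE, labels = grid$labels)
}

# identical grids (same starts); used by every grid-aligned operation
same_grid <- function(a, b) {
  inherits(a, "age_grid") && inherits(b, "age_grid") &&
    length(a$starts) == length(b$starts) && all(a$starts == b$starts)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop("age grid mismatch between ", what)
  invisible(TRUE)
}
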