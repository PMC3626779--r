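# The theoretical inhibitory cascade: predicted morphospace line, cascade
# size trajectories, region/trend classification, and the m2-share test.

REGION_LEVELS <- c("m2_intermediate", "m2_largest", "m2_smallest")
TREND_LEVELS <- c("decreasing", "increasing", "all_equal")

#' Theoretical inhibitory cascade parameters
#'
#' The cascade predicts relative lower molar sizes (1, a, 2a - 1) along the
#' row, hence the morphospace line m3/m1 = 2 (m2/m1) - 1 and an m2 share of
#' exactly one third of total molar occlusal area. The slope/intercept CIs
#' are zero-width so the theory can be passed to [compare_lines()].
#'
#' @return An object of class `ic_theory`: a list with `slope` (2),
#'   `intercept` (-1), `m2_share` (1/3) and degenerate `slope_ci`,
#'   `intercept_ci`.
#' @export
ic_theory <- function() {
  structure(list(slope = 2, intercept = -1, m2_share = 1 / 3,
                 slope_ci = c(2, 2), intercept_ci = c(-1, -1),
                 source = "IC model"),
            class = "ic_theory")
}

#' @export
print.ic_theory <- function(x, ...) {
  cat("Inhibitory cascade theory: m3/m1 = 2 (m2/m1) - 1;",
      "m2 share = 1/3 (33.33%)\n")
  invisible(x)
}

#' The predicted morphospace line
#'
#' @param x m2/m1 area ratio(s), `x >= 0`.
#' @return The predicted m3/m1 ratio, `2 * x - 1`.
#' @examples
#' ic_line(c(0.5, 1, 1.5))  # 0, 1, 2
#' @export
ic_line <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0")
  2 * x - 1
}

#' Relative molar sizes under the cascade
#'
#' For an activator/inhibitor balance `a >= 0`, the cascade gives relative
#' areas (1, a, 2a - 1), cumulative along the row. A computed size at or
#' below zero means the tooth does not develop; it is floored at 0 and
#' flagged absent (m3 is lost for `a <= 0.5`).
#'
#' @param a Activator/inhibitor balance(s), `a >= 0`. `a = 1` gives three
#'   equal molars.
#' @return A `data.frame` with columns `a`, `s1`, `s2`, `s3`,
#'   `m3_absent`.
#' @examples
#' cascade_sizes(c(0.4, 1, 1.5))
#' @export
cascade_sizes <- function(a) {
  if (any(!is.finite(a)) || any(a < 0)) stop("a must be finite and >= 0")
  s3 <- pmax(0, 2 * a - 1)
  data.frame(a = a, s1 = rep(1, length(a)), s2 = a, s3 = s3,
             m3_absent = 2 * a - 1 <= 0)
}

.check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("ratios must be finite and non-negative")
  }
}

#' Classify a morphospace point against the predicted regions
#'
#' The cascade predicts that m2 is intermediate in size (or all molars are
#' equal). With `x` = m2/m1 and `y` = m3/m1, the two violation regions are
#' defined by strict inequalities: m2 largest iff `x > 1 + tol` and
#' `y < x - tol`; m2 smallest iff `x < 1 - tol` and `y > x + tol`. Boundary
#' and equality cases fall inside the predicted region, since equal sizes
#' are a permitted cascade outcome.
#'
#' @param x,y m2/m1 and m3/m1 area ratios (non-negative).
#' @param tol Non-negative classification tolerance (default 0, i.e.
#'   strict inequalities delimit the violation regions).
#' @return A factor with levels `m2_intermediate`, `m2_largest`,
#'   `m2_smallest`.
#' @examples
#' classify_region(c(1.2, 1.2, 0.8), c(1.5, 0.9, 0.9))
#' @export
classify_region <- function(x, y, tol = 0) {
  .check_xy(x, y)
  if (tol < 0) stop("tol must be >= 0")
  out <- rep("m2_intermediate", length(x))
  out[x > 1 + tol & y < x - tol] <- "m2_largest"
  out[x < 1 - tol & y > x + tol] <- "m2_smallest"
  factor(out, levels = REGION_LEVELS)
}

#' Classify the along-row size trend of a predicted-region point
#'
#' Defined only for points in the predicted (m2 intermediate) region:
#' sizes decrease posteriorly iff `x < 1 - tol` and `y < x - tol`, increase
#' iff `x > 1 + tol` and `y > x + tol`, and are taken as all-equal
#' otherwise. On real-valued data the all-equal bin is expected to be
#' empty at `tol = 0`.
#'
#' @inheritParams classify_region
#' @return A factor with levels `decreasing`, `increasing`, `all_equal`.
#' @export
classify_trend <- function(x, y, tol = 0) {
  .check_xy(x, y)
  if (tol < 0) stop("tol must be >= 0")
  region <- classify_region(x, y, tol)
  if (any(region != "m2_intermediate")) {
    stop("classify_trend is defined only for points in the predicted region")
  }
  out <- rep("all_equal", length(x))
  out[x < 1 - tol & y < x - tol] <- "decreasing"
  out[x > 1 + tol & y > x + tol] <- "increasing"
  factor(out, levels = TREND_LEVELS)
}

#' Region and trend counts for a set of genus records
#'
#' @param records A genus-record `data.frame` with columns `x` and `y`
#'   (rows with either missing are dropped and counted as such).
#' @param tol Classification tolerance, see [classify_region()].
#' @return An object of class `region_summary`: list with `n`, `region`
#'   (named counts), `trend` (named counts among predicted-region points),
#'   `pct_predicted` (percentage of points in the predicted region) and
#'   `n_dropped`.
#' @export
region_summary <- function(records, tol = 0) {
  ok <- stats::complete.cases(records[c("x", "y")])
  if (!any(ok)) stop("no records with both x and y")
  x <- records$x[ok]
  y <- records$y[ok]
  region <- classify_region(x, y, tol)
  inter <- region == "m2_intermediate"
  trend <- classify_trend(x[inter], y[inter], tol)
  structure(list(
    n = length(x),
    region = table(region),
    trend = table(trend),
    pct_predicted = 100 * sum(inter) / length(x),
    n_dropped = sum(!ok),
    tol = tol), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Morphospace region membership (n = %d, tol = %g):\n",
              x$n, x$tol))
  print(x$region)
  cat(sprintf("%.1f%% of genera fall in the predicted region\n",
              x$pct_predicted))
  cat("Trend among predicted-region genera:\n")
  print(x$trend)
  if (x$n_dropped > 0) {
    cat(sprintf("(%d genera lacked x and/or y and were not classified)\n",
                x$n_dropped))
  }
  invisible(x)
}

#' Test whether mean m2 share differs from one third
#'
#' Two-tailed one-sample t test of the genus mean m2 shares (as
#' percentages) against the cascade's exact prediction of 100/3 %.
#'
#' @param records Genus records with an `m2_share_mean` column
#'   (proportions in (0, 1); rows with missing share are dropped).
#' @return A `t_test` object (see [one_sample_t()]); its `mean` is the
#'   mean m2 share in percent.
#' @export
m2_share_test <- function(records) {
  shares <- records$m2_share_mean
  shares <- shares[!is.na(shares)]
  if (length(shares) < 2L) {
    stop("need at least 2 genera with complete m2 shares")
  }
  one_sample_t(100 * shares, mu = 100 / 3)
}
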