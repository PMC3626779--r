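# From-scratch statistics used by the pipeline: tie-aware Spearman rank
# correlation reporting the S statistic, and a one-sample two-tailed t test.
# (The one-way PERMANOVA lives in permanova.R.)

#' Spearman rank correlation with the S statistic
#'
#' Midranks are assigned to ties; rho is the Pearson correlation of the
#' rank vectors; the S statistic is derived from rho as
#' `S = (1 - rho) (n^3 - n) / 6`, which reduces to the classical sum of
#' squared rank differences when there are no ties and matches standard
#' statistical output under ties. The p value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 df, two-tailed.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   are dropped. At least 3 complete pairs are required.
#' @return An object of class `spearman`: list with `n`, `rho`, `S`, `p`.
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant input: rank correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  S <- (1 - rho) * (n^3 - n) / 6
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(list(n = n, rho = rho, S = S, p = p), class = "spearman")
}

#' @export
print.spearman <- function(x, digits = 4, ...) {
  cat(sprintf("Spearman rank correlation: n = %d, S = %s, rho = %s, p = %s\n",
              x$n, format(x$S, digits = digits),
              format(x$rho, digits = digits),
              format.pval(x$p, digits = digits)))
  invisible(x)
}

#' One-sample two-tailed t test
#'
#' `t = (mean - mu) / (s / sqrt(n))` with a two-tailed p value on n - 1 df
#' and a 95% confidence interval `mean +/- t(0.975, n - 1) s / sqrt(n)`.
#' A zero-variance sample gives `t = 0, p = 1` when the mean equals `mu`,
#' and an infinite flagged t otherwise.
#'
#' @param values Numeric sample (missing values dropped; n >= 2).
#' @param mu Null-hypothesis mean.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `t_test`: list with `t`, `df`, `mean`, `ci`,
#'   `p`, `mu`, `n`, and `zero_variance`.
#' @examples
#' one_sample_t(c(1, 2, 3), mu = 2)
#' @export
one_sample_t <- function(values, mu, conf_level = 0.95) {
  v <- as.numeric(values[!is.na(values)])
  n <- length(v)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(v)
  s <- stats::sd(v)
  df <- n - 1L
  zero_var <- s == 0
  if (zero_var) {
    # constant sample: equality with mu judged at floating tolerance
    if (abs(m - mu) <= 1e-12 * max(1, abs(mu))) {
      tstat <- 0
      p <- 1
    } else {
      tstat <- sign(m - mu) * Inf
      p <- 0
    }
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    tstat <- (m - mu) / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = df)
    ci <- m + c(-1, 1) * tq * se
  }
  structure(list(t = tstat, df = df, mean = m, ci = ci, p = p, mu = mu,
                 n = n, zero_variance = zero_var), class = "t_test")
}

#' @export
print.t_test <- function(x, digits = 4, ...) {
  cat(sprintf(
    "One-sample t test vs mu = %s: mean = %s, t = %s, df = %d, p = %s\n",
    format(x$mu, digits = digits), format(x$mean, digits = digits),
    format(x$t, digits = digits), x$df, format.pval(x$p, digits = digits)))
  cat(sprintf("  CI [%s, %s]%s\n",
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits),
              if (x$zero_variance) "  (zero-variance sample)" else ""))
  invisible(x)
}
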