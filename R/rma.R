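# Reduced major axis (standardised major axis) regression with analytic or
# bootstrap confidence intervals, and CI-overlap comparison of fitted lines.

#' Fit a reduced major axis regression
#'
#' Symmetric line fitting appropriate when both variables carry error:
#' slope = sign(r) * s_y / s_x (sample standard deviations, n - 1
#' denominator, which cancels in the ratio), intercept = ybar - slope *
#' xbar. The analytic slope interval is the standard SMA interval
#' `b * (sqrt(B + 1) -/+ sqrt(B))` with
#' `B = F(1 - alpha; 1, n - 2) (1 - r^2) / (n - 2)`; the intercept interval
#' uses the SMA elevation standard error
#' `sqrt(s_res^2 / n + xbar^2 SE(b)^2)` on a t distribution with n - 2 df.
#' The bootstrap alternative case-resamples and takes percentile
#' intervals.
#'
#' @param x Either a numeric vector of predictor values or a two-sided
#'   formula `y ~ x` evaluated in `data`.
#' @param y Numeric response (ignored when `x` is a formula).
#' @param data Optional data frame for the formula interface.
#' @param alpha Confidence level complement; intervals are at
#'   `1 - alpha` (default 0.05).
#' @param ci `"analytic"` (default) or `"bootstrap"`.
#' @param reps Bootstrap replicates (>= 999) when `ci = "bootstrap"`.
#' @param seed Integer seed, required for the bootstrap (the fit is then
#'   deterministic).
#' @return An object of class `rma_fit`: list with `n`, `slope`,
#'   `intercept`, `r`, `slope_ci`, `intercept_ci`, `alpha`, `method`,
#'   `perfect` (TRUE when r^2 = 1, in which case the intervals are
#'   zero-width), plus the data for the methods.
#' @examples
#' fit <- fit_rma(x = c(0, 1, 2), y = c(0, 1, 4))
#' coef(fit)
#' confint(fit)
#' d <- data.frame(u = 1:10, v = 2 * (1:10) - 1 + rnorm(10, sd = 0.1))
#' fit_rma(v ~ u, data = d)
#' @export
fit_rma <- function(x, y = NULL, data = NULL, alpha = 0.05,
                    ci = c("analytic", "bootstrap"), reps = 1999,
                    seed = NULL) {
  ci <- match.arg(ci)
  cl <- match.call()
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data, na.action = stats::na.omit)
    if (ncol(mf) != 2L) stop("formula must be of the form y ~ x")
    y <- mf[[1L]]
    x <- mf[[2L]]
  }
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete (x, y) pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: x and y must each have nonzero variance")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")

  est <- .rma_point(x, y)
  fit <- structure(c(est, list(n = n, x = x, y = y, alpha = alpha,
                               method = ci, call = cl)),
                   class = "rma_fit")
  if (ci == "analytic") {
    fit <- .rma_ci_analytic(fit, alpha)
  } else {
    if (is.null(seed)) stop("bootstrap CIs require a seed")
    if (reps < 999) stop("bootstrap requires reps >= 999")
    fit <- .rma_ci_bootstrap(fit, alpha, reps, seed)
  }
  fit
}

# Point estimates. sign convention: sign(slope) = sign(r); r = 0 keeps a
# positive slope.
.rma_point <- function(x, y) {
  r <- stats::cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

.rma_ci_analytic <- function(fit, alpha) {
  n <- fit$n
  r2 <- fit$r^2
  perfect <- (1 - r2) < .Machine$double.eps * 100
  if (perfect) {
    fit$slope_ci <- c(fit$slope, fit$slope)
    fit$intercept_ci <- c(fit$intercept, fit$intercept)
  } else {
    B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r2) / (n - 2)
    ends <- fit$slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
    fit$slope_ci <- sort(ends)
    se_b <- abs(fit$slope) * sqrt((1 - r2) / (n - 2))
    s_res2 <- stats::var(fit$y) * (1 - r2) * (n - 1) / (n - 2)
    se_int <- sqrt(s_res2 / n + mean(fit$x)^2 * se_b^2)
    tq <- stats::qt(1 - alpha / 2, n - 2)
    fit$intercept_ci <- fit$intercept + c(-1, 1) * tq * se_int
  }
  fit$perfect <- perfect
  fit$method <- "analytic"
  fit
}

.rma_ci_bootstrap <- function(fit, alpha, reps, seed) {
  set.seed(seed)
  n <- fit$n
  slopes <- numeric(reps)
  ints <- numeric(reps)
  for (b in seq_len(reps)) {
    for (try in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- fit$x[idx]
      yb <- fit$y[idx]
      if (stats::sd(xb) > 0 && stats::sd(yb) > 0) break
      if (try == 100L) stop("bootstrap resampling kept degenerating")
    }
    est <- .rma_point(xb, yb)
    slopes[b] <- est$slope
    ints[b] <- est$intercept
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  fit$slope_ci <- unname(stats::quantile(slopes, probs))
  fit$intercept_ci <- unname(stats::quantile(ints, probs))
  fit$perfect <- (1 - fit$r^2) < .Machine$double.eps * 100
  fit$method <- "bootstrap"
  fit$reps <- reps
  fit$seed <- seed
  fit
}

#' @export
print.rma_fit <- function(x, digits = 4, ...) {
  cat("Reduced major axis regression (", x$method, " CIs, ",
      format(100 * (1 - x$alpha)), "%)\n", sep = "")
  cat(sprintf("  n = %d, r = %s\n", x$n, format(x$r, digits = digits)))
  cat(sprintf("  slope     %s  [%s, %s]\n",
              format(x$slope, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits)))
  cat(sprintf("  intercept %s  [%s, %s]\n",
              format(x$intercept, digits = digits),
              format(x$intercept_ci[1], digits = digits),
              format(x$intercept_ci[2], digits = digits)))
  if (isTRUE(x$perfect)) cat("  (perfect fit: r^2 = 1, zero-width CIs)\n")
  invisible(x)
}

#' @export
coef.rma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.rma_fit <- function(object, parm, level, ...) {
  out <- rbind(object$intercept_ci, object$slope_ci)
  dimnames(out) <- list(c("intercept", "slope"),
                        c(format(object$alpha / 2),
                          format(1 - object$alpha / 2)))
  out
}

#' @export
predict.rma_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
fitted.rma_fit <- function(object, ...) predict(object)

#' @export
residuals.rma_fit <- function(object, ...) object$y - fitted(object)

#' @export
summary.rma_fit <- function(object, ...) {
  cmp <- compare_lines(object, ic_theory())
  structure(list(fit = object, r2 = object$r^2, vs_theory = cmp),
            class = "summary.rma_fit")
}

#' @export
print.summary.rma_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  r^2 = %s\n", format(x$r2, digits = digits)))
  cat(sprintf("  vs cascade line (slope 2, intercept -1): %s\n",
              if (x$vs_theory$different) "significantly different"
              else "not distinguishable at this level"))
  invisible(x)
}

#' @export
plot.rma_fit <- function(x, show_theory = TRUE, ...) {
  graphics::plot(x$x, x$y, xlab = "m2/m1 area", ylab = "m3/m1 area", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  if (show_theory) graphics::abline(-1, 2, col = "grey40", lty = 2)
  invisible(x)
}

.line_params <- function(obj) {
  if (inherits(obj, c("rma_fit", "ic_theory"))) {
    list(slope = obj$slope, slope_ci = obj$slope_ci,
         intercept = obj$intercept, intercept_ci = obj$intercept_ci)
  } else if (is.list(obj) && all(c("slope", "intercept") %in% names(obj))) {
    slope_ci <- if (!is.null(obj$slope_ci)) obj$slope_ci
    else if (!is.null(obj$slope_lo)) c(obj$slope_lo, obj$slope_hi)
    else c(obj$slope, obj$slope)
    int_ci <- if (!is.null(obj$intercept_ci)) obj$intercept_ci
    else if (!is.null(obj$intercept_lo)) c(obj$intercept_lo, obj$intercept_hi)
    else c(obj$intercept, obj$intercept)
    list(slope = obj$slope, slope_ci = as.numeric(slope_ci),
         intercept = obj$intercept, intercept_ci = as.numeric(int_ci))
  } else {
    stop("cannot extract line parameters from object of class ",
         paste(class(obj), collapse = "/"))
  }
}

.overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])

#' Compare two regression lines by confidence-interval overlap
#'
#' Two fits are declared different when either parameter's confidence
#' intervals are disjoint. Theoretical parameters (e.g. [ic_theory()]) have
#' zero-width intervals, so the comparison reduces to containment in the
#' fitted intervals.
#'
#' @param a,b `rma_fit` objects, an [ic_theory()] object, or any list with
#'   `slope`, `intercept` and (optionally) `slope_ci`, `intercept_ci`.
#' @return An object of class `line_comparison`: list with
#'   `slope_overlap`, `intercept_overlap`, `different`.
#' @examples
#' compare_lines(published_comparisons()$fits["mammalia", ], ic_theory())
#' @export
compare_lines <- function(a, b) {
  pa <- .line_params(a)
  pb <- .line_params(b)
  if (anyNA(c(pa$slope_ci, pb$slope_ci, pa$intercept_ci, pb$intercept_ci))) {
    stop("both lines need confidence intervals (or theoretical values)")
  }
  so <- .overlap(pa$slope_ci, pb$slope_ci)
  io <- .overlap(pa$intercept_ci, pb$intercept_ci)
  structure(list(slope_overlap = so, intercept_overlap = io,
                 different = !(so && io)),
            class = "line_comparison")
}

#' @export
print.line_comparison <- function(x, ...) {
  cat(sprintf("slope CIs %s; intercept CIs %s; lines %s\n",
              if (x$slope_overlap) "overlap" else "disjoint",
              if (x$intercept_overlap) "overlap" else "disjoint",
              if (x$different) "differ" else "do not differ"))
  invisible(x)
}

#' Published regression and m2-share comparison values
#'
#' Reported parameters from earlier molar-proportion studies, shipped as
#' constants for side-by-side tables: the theoretical cascade line, the
#' murine rodent fit, the arvicoline rodent fit, the canid fit, and the
#' broad mammalian fit, together with the murine and mammalian m2-share
#' test summaries. These are published numbers, not recomputed (their raw
#' data are external).
#'
#' @return A list with two data frames: `fits` (slope, slope CI,
#'   intercept, intercept CI per source) and `m2_share` (t, df, mean m2
#'   area percentage, 95% CI per source).
#' @export
published_comparisons <- function() {
  fits <- data.frame(
    source = c("IC model", "murine rodents", "arvicoline rodents",
               "Canidae", "Mammalia (broad sample)"),
    slope = c(2.000, 2.150, 1.390, 0.450, 2.303),
    slope_lo = c(2.000, 1.772, 1.208, 0.376, 2.007),
    slope_hi = c(2.000, 2.688, 1.555, 0.515, 2.655),
    intercept = c(-1.000, -1.219, -0.313, -0.080, -1.455),
    intercept_lo = c(-1.000, -1.651, -0.407, -0.104, -1.863),
    intercept_hi = c(-1.000, -0.925, -0.213, -0.037, -1.113),
    stringsAsFactors = FALSE)
  rownames(fits) <- c("theory", "murine", "arvicoline", "canid", "mammalia")
  m2 <- data.frame(
    source = c("IC model", "murine rodents", "Mammalia (broad sample)"),
    t = c(NA, 5.702, 3.898),
    df = c(NA, 28L, 129L),
    mean_pct = c(100 / 3, 34.84, 34.58),
    lo = c(NA, 34.30, 33.94),
    hi = c(NA, 35.38, 35.22),
    stringsAsFactors = FALSE)
  rownames(m2) <- c("theory", "murine", "mammalia")
  list(fits = fits, m2_share = m2)
}
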