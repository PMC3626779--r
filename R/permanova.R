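# One-way permutational MANOVA on Euclidean distances, implemented from the
# sum-of-squared-distances partition. For points in Euclidean space the
# distance form (1/n) sum_{i<j} d^2_ij equals the centroid form
# sum_i |x_i - xbar|^2, which is what the fast permutation loop uses.

# Within-group sum of squares about group centroids, from centred
# coordinates. `sizes` must align with the integer group codes 1..a.
.pmv_within <- function(Xc, codes, sizes, total_sq) {
  gs <- rowsum(Xc, codes)
  total_sq - sum(gs^2 / sizes)
}

# All permutations of 1:n (n <= 9), one per row: each permutation of
# 1:(n-1) with the value n inserted at every possible position.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' One-way PERMANOVA (permutational MANOVA)
#'
#' Partitions the total sum of squared Euclidean inter-point distances into
#' between- and within-group components:
#' `ss_total = (1/n) sum_{i<j} d^2_ij`,
#' `ss_within = sum_g (1/n_g) sum_{i<j in g} d^2_ij`,
#' `ss_between = ss_total - ss_within`, with `df_between = a - 1`,
#' `df_within = n - a`, pseudo-F the ratio of mean squares and
#' `R^2 = ss_between / ss_total`. The p value is
#' `(#{F_perm >= F_obs} + 1) / (n_perm + 1)` over uniform random
#' relabellings, deterministic given `seed`; with `exact = TRUE` (n <= 9)
#' every permutation of the labels is enumerated instead and the p value
#' is the exact tail proportion.
#'
#' @param coords Numeric matrix or data frame of point coordinates (here,
#'   the (m2/m1, m3/m1) morphospace plane).
#' @param labels Group labels, one per point; at least two groups, and no
#'   group may contain every point.
#' @param n_perm Number of random permutations (>= 99; default 999).
#' @param seed Optional integer seed for the permutations.
#' @param exact If `TRUE`, enumerate all permutations (requires n <= 9).
#' @return An object of class `permanova`: list with `tab` (anova-style
#'   table), `df_between`, `df_within`, `ss_between`, `ss_within`,
#'   `ss_total`, `ms_between`, `ms_within`, `F`, `R2`, `p`, `n_perm`,
#'   `seed`, `n`, `n_groups`.
#' @examples
#' set.seed(1)
#' xy <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 2), 10))
#' permanova_one_way(xy, rep(c("a", "b"), each = 10), n_perm = 199, seed = 1)
#' @export
permanova_one_way <- function(coords, labels, n_perm = 999, seed = NULL,
                              exact = FALSE) {
  X <- as.matrix(coords)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("coords must be complete")
  n <- nrow(X)
  f <- factor(labels)
  if (length(f) != n) stop("labels must match the number of points")
  if (anyNA(f)) stop("labels must be complete")
  a <- nlevels(f)
  if (a < 2L) stop("need at least two groups")
  sizes <- tabulate(f)
  if (max(sizes) == n) stop("one group contains every point")
  if (!exact && n_perm < 99) stop("n_perm < 99 gives unstable p values")
  if (exact && n > 9L) stop("exact enumeration supported only for n <= 9")

  codes <- as.integer(f)
  Xc <- sweep(X, 2L, colMeans(X))
  total_sq <- sum(Xc^2)
  ss_within <- .pmv_within(Xc, codes, sizes, total_sq)
  ss_total <- total_sq
  ss_between <- ss_total - ss_within
  df_b <- a - 1L
  df_w <- n - a
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  Fobs <- ms_b / ms_w
  R2 <- ss_between / ss_total

  Fperm_stat <- function(codes_perm) {
    ssw <- .pmv_within(Xc, codes_perm, sizes, total_sq)
    ((ss_total - ssw) / df_b) / (ssw / df_w)
  }

  if (exact) {
    perms <- .all_perms(n)
    Fs <- apply(perms, 1L, function(ix) Fperm_stat(codes[ix]))
    p <- mean(Fs >= Fobs - 1e-12)
    n_perm_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      if (Fperm_stat(codes[sample.int(n)]) >= Fobs) ge <- ge + 1L
    }
    p <- (ge + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  tab <- data.frame(
    Df = c(df_b, df_w, n - 1L),
    SumSqs = c(ss_between, ss_within, ss_total),
    MeanSqs = c(ms_b, ms_w, NA),
    F = c(Fobs, NA, NA),
    R2 = c(R2, ss_within / ss_total, 1),
    p = c(p, NA, NA),
    row.names = c("groups", "residual", "total"))

  structure(list(tab = tab, df_between = df_b, df_within = df_w,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_total, ms_between = ms_b, ms_within = ms_w,
                 F = Fobs, R2 = R2, p = p, n_perm = n_perm_used,
                 seed = seed, n = n, n_groups = a, exact = exact),
            class = "permanova")
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat(sprintf(
    "One-way PERMANOVA (Euclidean distance, %s permutations%s)\n",
    format(x$n_perm), if (x$exact) ", exhaustive" else ""))
  print(round(x$tab, digits))
  invisible(x)
}
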