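# Independent oracles and small data builders used across the test files.
# Every oracle is written from the defining formulas, not by calling the
# implementation it checks.

# One specimen's three teeth in long format.
tooth_rows <- function(specimen, genus, lengths, widths,
                       teeth = c("m1", "m2", "m3"), source = "literature") {
  data.frame(specimen_id = specimen, genus = genus, tooth = teeth,
             length = lengths, width = widths, source = source,
             stringsAsFactors = FALSE)
}

meta_row <- function(genus, group = "GroupA", diet = "omnivorous",
                     isolated_only = FALSE, molar_count = 3L) {
  data.frame(genus = genus, group = group, diet = diet,
             isolated_only = isolated_only, molar_count = molar_count,
             stringsAsFactors = FALSE)
}

# PERMANOVA from the pairwise squared-distance definition:
# ss_total = (1/n) sum_{i<j} d2_ij, ss_within = sum_g (1/n_g) sum_{i<j in g}.
oracle_permanova_F <- function(coords, labels) {
  X <- as.matrix(coords)
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(labels))
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total,
       ss_total = ss_total, ss_within = ss_within)
}

# Exhaustive permutation p value for the oracle F (tiny n only).
oracle_permanova_exact_p <- function(coords, labels) {
  n <- nrow(as.matrix(coords))
  Fobs <- oracle_permanova_F(coords, labels)$F
  perms <- perm_matrix(n)
  Fs <- apply(perms, 1, function(ix) oracle_permanova_F(coords, labels[ix])$F)
  mean(Fs >= Fobs - 1e-12)
}

# Lexicographic enumeration: fix each first element, recurse on the rest.
perm_matrix <- function(n) {
  vals <- seq_len(n)
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(k) {
      cbind(v[k], rec(v[-k]))
    }))
  }
  rec(vals)
}

# RMA slope through an independent route: the ratio of the two ordinary
# least squares slopes (y on x over x on y), square-rooted, sign from the
# correlation.
oracle_rma <- function(x, y) {
  b_yx <- stats::coef(stats::lm(y ~ x))[2]
  b_xy <- stats::coef(stats::lm(x ~ y))[2]
  slope <- unname(sign(stats::cor(x, y)) * sqrt(abs(b_yx / b_xy)))
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# A noiseless cascade genus table without using the simulator.
cascade_points <- function(a) {
  s <- cbind(1, a, pmax(0, 2 * a - 1))
  data.frame(genus = sprintf("g%02d", seq_along(a)),
             x = s[, 2] / s[, 1], y = s[, 3] / s[, 1])
}
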