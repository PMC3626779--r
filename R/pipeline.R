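# End-to-end analysis: raw measurement table -> genus morphospace records ->
# region classification, RMA regression, m2-share test, size-proxy
# correlations and PERMANOVAs, with full N bookkeeping and a writable
# report mirroring the standard result tables.

DIET_OUTLIERS_DEFAULT <- c("Uintatherium", "Merychyus", "Merycoidodon",
                           "Elomeryx", "Palaeostylops")
POOL_GROUPS_DEFAULT <- c(Carnivora = "Carnivora-Creodonta",
                         Creodonta = "Carnivora-Creodonta",
                         Primates = "Primates-Plesiadapiformes",
                         Plesiadapiformes = "Primates-Plesiadapiformes")

# Genus-level means of per-specimen dimension ratios (length and width of
# m2 and m3 scaled against m1), for the size-proxy correlation table.
.dimension_ratios <- function(measurements, specimen_ids) {
  m <- measurements[measurements$specimen_id %in% specimen_ids, , drop = FALSE]
  sp <- unique(m[c("specimen_id", "genus")])
  dims <- list()
  for (k in 1:3) {
    sub <- m[m$tooth == TOOTH_LEVELS[k], ]
    i <- match(sp$specimen_id, sub$specimen_id)
    dims[[paste0("l", k)]] <- sub$length[i]
    dims[[paste0("w", k)]] <- sub$width[i]
  }
  sp$lr21 <- dims$l2 / dims$l1
  sp$lr31 <- dims$l3 / dims$l1
  sp$wr21 <- dims$w2 / dims$w1
  sp$wr31 <- dims$w3 / dims$w1
  g <- factor(sp$genus, levels = sort(unique(sp$genus)))
  agg <- function(v) as.numeric(tapply(v, g, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  }))
  data.frame(genus = levels(g), lr21 = agg(sp$lr21), lr31 = agg(sp$lr31),
             wr21 = agg(sp$wr21), wr31 = agg(sp$wr31),
             stringsAsFactors = FALSE)
}

.spearman_row <- function(comparison, ratio, x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) {
    return(data.frame(comparison = comparison, ratio = ratio,
                      n = sum(ok), S = NA, p = NA, rho = NA,
                      stringsAsFactors = FALSE))
  }
  ct <- spearman_rank(x[ok], y[ok])
  data.frame(comparison = comparison, ratio = ratio, n = ct$n, S = ct$S,
             p = ct$p, rho = ct$rho, stringsAsFactors = FALSE)
}

# A grouping that degenerates (fewer than two usable groups, or one group
# holding every point) yields a skipped placeholder rather than an error:
# small datasets legitimately cannot support every clustering analysis.
.run_permanova <- function(records, labels, n_perm, seed, term) {
  keep <- stats::complete.cases(records[c("x", "y")]) & !is.na(labels)
  lab <- factor(labels[keep])
  if (nlevels(lab) < 2L || max(tabulate(lab)) == sum(keep)) {
    return(structure(list(term = term, skipped = TRUE, n = sum(keep),
                          n_groups = nlevels(lab),
                          reason = "fewer than two usable groups"),
                     class = "permanova_skipped"))
  }
  res <- permanova_one_way(as.matrix(records[keep, c("x", "y")]),
                           lab, n_perm = n_perm, seed = seed)
  res$term <- term
  res
}

#' Run the full inhibitory cascade analysis
#'
#' Executes the whole pipeline on a measurement table and genus metadata:
#' area computation, inclusion filtering, per-specimen ratios, genus
#' aggregation, morphospace region/trend classification, size-proxy
#' Spearman correlations, reduced major axis regression with comparison
#' against the theoretical cascade line and published fits, the m2-share
#' t test, four one-way PERMANOVAs (all taxonomic groups; groups with at
#' least `min_group_size` genera after pooling; diet; diet with the listed
#' outlier genera removed), and convex hulls per group and diet.
#'
#' @param measurements Measurement table (data frame) or path to a CSV,
#'   see [read_measurements()].
#' @param metadata Genus metadata (data frame) or path, see
#'   [read_metadata()].
#' @param tol Region classification tolerance (default 0).
#' @param alpha Significance level for the regression CIs (default 0.05).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed Integer seed controlling all permutation randomness.
#' @param diet_outliers Genera excluded from the reduced diet analysis.
#' @param pool_groups Named character vector mapping group labels to
#'   pooled labels before the five-or-more analysis.
#' @param min_group_size Minimum pooled group size for that analysis.
#' @param strict Passed to [filter_specimens()]/[aggregate_genera()].
#' @return An object of class `ic_analysis`: list with `records`,
#'   `exclusions`, `region`, `table1` (correlations), `rma`, `table2`
#'   (line comparisons), `m2_test`, `table3`, `permanova` (list of four),
#'   `table4`, `hulls`, `ns` (N bookkeeping) and `provenance`.
#' @examples
#' sim <- simulate_dataset(sim_scenario("conforming", seed = 1))
#' an <- run_analysis(sim$measurements, sim$metadata, seed = 1,
#'                    n_perm = 199)
#' an
#' @export
run_analysis <- function(measurements, metadata, tol = 0, alpha = 0.05,
                         n_perm = 999, seed = 1L,
                         diet_outliers = DIET_OUTLIERS_DEFAULT,
                         pool_groups = POOL_GROUPS_DEFAULT,
                         min_group_size = 5L, strict = TRUE) {
  if (is.character(measurements)) {
    measurements <- .with_stage("molar_data", read_measurements(measurements))
  }
  if (is.character(metadata)) {
    metadata <- .with_stage("molar_data", read_metadata(metadata))
  }
  if (!.is_count(seed)) stop("seed must be a single integer")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  areas <- .with_stage("molar_data", specimen_areas(measurements))
  fl <- .with_stage("molar_data",
                    filter_specimens(areas, metadata, strict = strict))
  ratios <- .with_stage("molar_data", specimen_ratios(fl$kept))
  records <- .with_stage("molar_data",
                         aggregate_genera(ratios, metadata, strict = strict))

  okxy <- stats::complete.cases(records[c("x", "y")])
  records$region <- factor(NA_character_, levels = REGION_LEVELS)
  records$trend <- factor(NA_character_, levels = TREND_LEVELS)
  records$region[okxy] <- classify_region(records$x[okxy], records$y[okxy],
                                          tol)
  inter <- okxy & records$region == "m2_intermediate"
  records$trend[which(inter)] <- classify_trend(records$x[which(inter)],
                                                records$y[which(inter)], tol)
  region <- .with_stage("ic_model", region_summary(records, tol))

  dimr <- .with_stage("pipeline",
                      .dimension_ratios(measurements, fl$kept$specimen_id))
  i <- match(records$genus, dimr$genus)
  table1 <- .with_stage("resampling_stats", rbind(
    .spearman_row("length:width", "m2/m1", dimr$lr21[i], dimr$wr21[i]),
    .spearman_row("length:width", "m3/m1", dimr$lr31[i], dimr$wr31[i]),
    .spearman_row("length:area", "m2/m1", dimr$lr21[i], records$x),
    .spearman_row("length:area", "m3/m1", dimr$lr31[i], records$y),
    .spearman_row("width:area", "m2/m1", dimr$wr21[i], records$x),
    .spearman_row("width:area", "m3/m1", dimr$wr31[i], records$y)))

  rma <- .with_stage("rma_regression",
                     fit_rma(x = records$x[okxy], y = records$y[okxy],
                             alpha = alpha))
  pub <- published_comparisons()
  this_row <- data.frame(source = "this analysis", slope = rma$slope,
                         slope_lo = rma$slope_ci[1],
                         slope_hi = rma$slope_ci[2],
                         intercept = rma$intercept,
                         intercept_lo = rma$intercept_ci[1],
                         intercept_hi = rma$intercept_ci[2],
                         stringsAsFactors = FALSE)
  table2 <- rbind(pub$fits, this_row)
  table2$different_from_this <- vapply(seq_len(nrow(table2)), function(k) {
    compare_lines(table2[k, ], this_row)$different
  }, logical(1))

  m2_test <- .with_stage("ic_model", m2_share_test(records))
  table3 <- rbind(pub$m2_share,
                  data.frame(source = "this analysis", t = m2_test$t,
                             df = m2_test$df, mean_pct = m2_test$mean,
                             lo = m2_test$ci[1], hi = m2_test$ci[2],
                             stringsAsFactors = FALSE))

  pooled <- records$group
  hit <- pooled %in% names(pool_groups)
  pooled[hit] <- unname(pool_groups[pooled[hit]])
  tab <- table(pooled[okxy])
  big <- names(tab)[tab >= min_group_size]
  lab5 <- ifelse(pooled %in% big, pooled, NA)
  diet_red <- ifelse(records$genus %in% diet_outliers, NA, records$diet)

  permanovas <- list(
    phylogeny = .with_stage("resampling_stats",
      .run_permanova(records, records$group, n_perm, sub_seeds[1],
                     "phylogeny")),
    phylogeny_5plus = .with_stage("resampling_stats",
      .run_permanova(records, lab5, n_perm, sub_seeds[2],
                     "phylogeny (5+)")),
    diet = .with_stage("resampling_stats",
      .run_permanova(records, records$diet, n_perm, sub_seeds[3], "diet")),
    diet_reduced = .with_stage("resampling_stats",
      .run_permanova(records, diet_red, n_perm, sub_seeds[4],
                     "diet (reduced)")))
  table4 <- do.call(rbind, lapply(permanovas, function(p) {
    if (inherits(p, "permanova_skipped")) {
      return(data.frame(test = p$term, n = p$n, df = NA_integer_,
                        ss = NA_real_, ms = NA_real_, F = NA_real_,
                        R2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(test = p$term, n = p$n, df = p$df_between,
               ss = p$ss_between, ms = p$ms_between, F = p$F, R2 = p$R2,
               p = p$p, stringsAsFactors = FALSE)
  }))
  rownames(table4) <- NULL

  hulls <- .with_stage("pipeline", list(
    group = group_hulls(records, by = "group"),
    diet = group_hulls(records, by = "diet")))

  ns <- c(n_specimens_input = nrow(areas),
          n_specimens_kept = nrow(fl$kept),
          n_exclusion_records = nrow(fl$exclusions),
          n_genera = nrow(records),
          n_genera_xy = sum(okxy),
          n_genera_x = sum(!is.na(records$x)),
          n_genera_y = sum(!is.na(records$y)),
          n_genera_m2_share = sum(!is.na(records$m2_share_mean)),
          n_genera_5plus = sum(!is.na(lab5) & okxy))

  config <- list(tol = tol, alpha = alpha, n_perm = n_perm, seed = seed,
                 diet_outliers = diet_outliers, pool_groups = pool_groups,
                 min_group_size = min_group_size)
  provenance <- list(config = config, config_hash = .config_hash(config),
                     seed = seed,
                     version = as.character(utils::packageVersion("icascade")))

  structure(list(records = records, exclusions = fl$exclusions,
                 region = region, table1 = table1, rma = rma,
                 table2 = table2, m2_test = m2_test, table3 = table3,
                 permanova = permanovas, table4 = table4, hulls = hulls,
                 ns = ns, provenance = provenance),
            class = "ic_analysis")
}

#' @export
print.permanova_skipped <- function(x, ...) {
  cat(sprintf("PERMANOVA '%s' skipped: %s (n = %d)\n", x$term, x$reason,
              x$n))
  invisible(x)
}

#' @export
print.ic_analysis <- function(x, digits = 4, ...) {
  cat("Inhibitory cascade analysis\n")
  cat(sprintf("  %d genera (%d with both ratios) from %d kept specimens\n",
              x$ns["n_genera"], x$ns["n_genera_xy"],
              x$ns["n_specimens_kept"]))
  r <- x$region$region
  cat(sprintf(
    "  regions: %d intermediate / %d m2-largest / %d m2-smallest (%.1f%% predicted)\n",
    r["m2_intermediate"], r["m2_largest"], r["m2_smallest"],
    x$region$pct_predicted))
  cat(sprintf("  RMA: slope %s [%s, %s], intercept %s [%s, %s]\n",
              format(x$rma$slope, digits = digits),
              format(x$rma$slope_ci[1], digits = digits),
              format(x$rma$slope_ci[2], digits = digits),
              format(x$rma$intercept, digits = digits),
              format(x$rma$intercept_ci[1], digits = digits),
              format(x$rma$intercept_ci[2], digits = digits)))
  cat(sprintf("  mean m2 share %.2f%% (t = %s, df = %d, p = %s)\n",
              x$m2_test$mean, format(x$m2_test$t, digits = digits),
              x$m2_test$df, format.pval(x$m2_test$p, digits = 3)))
  cat("  PERMANOVA:\n")
  t4 <- x$table4
  for (k in seq_len(nrow(t4))) {
    if (is.na(t4$F[k])) {
      cat(sprintf("    %-16s skipped (fewer than two usable groups)\n",
                  t4$test[k]))
    } else {
      cat(sprintf(
        "    %-16s n = %3d, df = %2d, F = %7.3f, R2 = %.3f, p = %s\n",
        t4$test[k], t4$n[k], t4$df[k], t4$F[k], t4$R2[k],
        format.pval(t4$p[k], digits = 3)))
    }
  }
  invisible(x)
}

#' @export
summary.ic_analysis <- function(object, ...) {
  print(object, ...)
  cat("\nSize-proxy Spearman correlations (genus-level ratios):\n")
  print(transform(object$table1, S = signif(S, 6), rho = signif(rho, 4),
                  p = format.pval(p, digits = 3)), row.names = FALSE)
  invisible(object)
}

#' @export
plot.ic_analysis <- function(x, hull_by = NULL, ...) {
  rec <- x$records[stats::complete.cases(x$records[c("x", "y")]), ]
  cols <- c(m2_intermediate = "grey25", m2_largest = "firebrick",
            m2_smallest = "dodgerblue3")
  graphics::plot(rec$x, rec$y, col = cols[as.character(rec$region)],
                 pch = 16, xlab = "m2/m1 area", ylab = "m3/m1 area", ...)
  graphics::abline(-1, 2, col = "grey55", lty = 2)
  graphics::abline(x$rma$intercept, x$rma$slope, col = "red")
  graphics::abline(0, 1, col = "grey80", lty = 3)
  graphics::abline(v = 1, col = "grey80", lty = 3)
  if (!is.null(hull_by)) {
    h <- x$hulls[[hull_by]]
    for (lab in unique(h$label)) {
      hh <- h[h$label == lab, ]
      if (!hh$degenerate[1]) {
        graphics::polygon(hh$x, hh$y, border = "grey40")
      }
    }
  }
  invisible(x)
}

#' Convex hulls of genus records per label
#'
#' Computes the minimum-area convex polygon occupied by each group or
#' dietary guild in the morphospace. Vertices are returned
#' counter-clockwise starting from the lowest (then leftmost) point.
#' Labels with fewer than three distinct points, or with all points
#' collinear, are flagged degenerate (their points are returned as-is).
#'
#' @param records Genus records with `x`, `y` and the grouping column.
#' @param by Grouping column: `"group"` or `"diet"`.
#' @return A `data.frame` with columns `label`, `vertex`, `x`, `y`,
#'   `degenerate`, `area`.
#' @export
group_hulls <- function(records, by = c("group", "diet")) {
  by <- match.arg(by)
  ok <- stats::complete.cases(records[c("x", "y")]) & !is.na(records[[by]])
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no complete records to build hulls from")
  out <- list()
  for (lab in sort(unique(rec[[by]]))) {
    pts <- unique(rec[rec[[by]] == lab, c("x", "y")])
    hull <- .convex_hull(as.matrix(pts))
    out[[lab]] <- data.frame(label = lab,
                             vertex = seq_len(nrow(hull$vertices)),
                             x = hull$vertices[, 1], y = hull$vertices[, 2],
                             degenerate = hull$degenerate, area = hull$area,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Convex hull with CCW orientation, anchored at the lowest-then-leftmost
# vertex. Shoelace area; zero area (collinear) is degenerate.
.convex_hull <- function(pts) {
  if (nrow(pts) < 3L) {
    return(list(vertices = pts, degenerate = TRUE, area = 0))
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[idx, , drop = FALSE]
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
                 v[c(2:nrow(v), 1), 1] * v[, 2])
  if (area2 < 0) {  # clockwise -> reverse
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    area2 <- -area2
  }
  start <- order(v[, 2], v[, 1])[1]
  if (start > 1) v <- v[c(start:nrow(v), 1:(start - 1)), , drop = FALSE]
  degenerate <- nrow(v) < 3L || abs(area2) < 1e-12
  list(vertices = v, degenerate = degenerate, area = abs(area2) / 2)
}

#' Write an analysis report to a directory
#'
#' Emits the genus records (with region/trend labels), the exclusion log,
#' the four result tables, the region summary, the convex hulls and a flat
#' key-value summary (`summary.tsv`) carrying the headline numbers and the
#' provenance block (seed, configuration hash, package version). Numeric
#' columns are written at full precision so reports are reproducible
#' byte-for-byte under a fixed configuration.
#'
#' @param analysis An `ic_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ic_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    .write_tsv(df, p)
    paths <<- c(paths, p)
  }
  rec <- analysis$records
  rec$region <- as.character(rec$region)
  rec$trend <- as.character(rec$trend)
  put(rec, "genus_records.tsv")
  put(analysis$exclusions, "exclusions.tsv")
  put(analysis$table1, "table1.tsv")
  put(analysis$table2, "table2.tsv")
  put(analysis$table3, "table3.tsv")
  put(analysis$table4, "table4.tsv")
  rs <- analysis$region
  put(data.frame(key = c(names(rs$region), names(rs$trend),
                         "pct_predicted", "n_classified"),
                 value = c(as.numeric(rs$region), as.numeric(rs$trend),
                           rs$pct_predicted, rs$n)),
      "region_summary.tsv")
  put(rbind(cbind(by = "group", analysis$hulls$group),
            cbind(by = "diet", analysis$hulls$diet)), "hulls.tsv")

  s <- analysis
  kv <- c(
    rma_slope = s$rma$slope, rma_slope_lo = s$rma$slope_ci[1],
    rma_slope_hi = s$rma$slope_ci[2], rma_intercept = s$rma$intercept,
    rma_intercept_lo = s$rma$intercept_ci[1],
    rma_intercept_hi = s$rma$intercept_ci[2], rma_r = s$rma$r,
    pct_predicted = s$region$pct_predicted,
    mean_m2_share_pct = s$m2_test$mean, m2_share_t = s$m2_test$t,
    m2_share_df = s$m2_test$df,
    s$ns)
  kv_df <- data.frame(key = c(names(kv), "seed", "config_hash", "version"),
                      value = c(.fmt_num(unname(kv)),
                                as.character(s$provenance$seed),
                                s$provenance$config_hash,
                                s$provenance$version))
  p <- file.path(dir, "summary.tsv")
  utils::write.table(kv_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
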