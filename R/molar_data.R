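# Reading, validation, filtering and genus-level aggregation of lower molar
# measurements. The analysis unit is the genus; the raw unit is one tooth of
# one specimen (long format: one row per specimen x tooth position).

#' Read a long-format molar measurement table
#'
#' Reads a CSV with one row per measured tooth. Required columns are
#' `specimen_id`, `genus`, `tooth` (one of `"m1"`, `"m2"`, `"m3"`),
#' `length` and `width` (mm, blank for missing). An optional `source`
#' column records provenance (e.g. literature, photo, database) and
#' defaults to `"literature"`.
#'
#' Validation is strict: unknown tooth labels, non-positive lengths or
#' widths, and duplicated (specimen, tooth) pairs are errors that name the
#' offending rows. Missing `length` or `width` values are allowed and
#' propagate as `NA` (a tooth with either dimension missing contributes no
#' area; length is never used as a proxy for area).
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with columns `specimen_id`, `genus`, `tooth`,
#'   `length`, `width`, `source`.
#' @seealso [specimen_areas()], [read_metadata()]
#' @examples
#' path <- system.file("extdata", "demo_measurements.csv", package = "icascade")
#' head(read_measurements(path))
#' @export
read_measurements <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("measurement file not found: ", paste(path, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("specimen_id", "genus", "tooth", "length", "width")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("measurement table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$source)) df$source <- "literature"
  df$specimen_id <- as.character(df$specimen_id)
  df$genus <- as.character(df$genus)
  df$tooth <- as.character(df$tooth)
  df$length <- as.numeric(df$length)
  df$width <- as.numeric(df$width)

  bad_tooth <- which(!(df$tooth %in% TOOTH_LEVELS))
  if (length(bad_tooth)) {
    stop("unknown tooth label(s) ",
         paste(unique(df$tooth[bad_tooth]), collapse = ", "),
         " in row(s) ", paste(bad_tooth, collapse = ", "))
  }
  bad_dim <- which((!is.na(df$length) & df$length <= 0) |
                     (!is.na(df$width) & df$width <= 0))
  if (length(bad_dim)) {
    stop("non-positive length/width in row(s) ",
         paste(bad_dim, collapse = ", "))
  }
  key <- paste(df$specimen_id, df$tooth, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (specimen_id, tooth) pair(s) in row(s) ",
         paste(dup, collapse = ", "))
  }
  df[c("specimen_id", "genus", "tooth", "length", "width", "source")]
}

#' Read a genus metadata table
#'
#' Reads a CSV keyed by genus with the grouping information the pipeline
#' needs: `group` (higher taxonomic label), `diet` (one of the six broad
#' dietary guilds: folivorous, carnivorous, omnivorous, insectivorous,
#' frugivorous, durophagous), and the per-genus filter flags
#' `isolated_only` (logical: taxon known solely from isolated molars) and
#' `molar_count` (number of lower molar positions in the tooth row).
#' `isolated_only` defaults to `FALSE` and `molar_count` to 3 when absent.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with columns `genus`, `group`, `diet`,
#'   `isolated_only`, `molar_count`.
#' @export
read_metadata <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("metadata file not found: ", paste(path, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("genus", "group", "diet")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$isolated_only)) df$isolated_only <- FALSE
  if (is.null(df$molar_count)) df$molar_count <- 3L
  df$genus <- as.character(df$genus)
  df$group <- as.character(df$group)
  df$diet <- as.character(df$diet)
  df$isolated_only <- as.logical(df$isolated_only)
  df$molar_count <- as.integer(df$molar_count)
  bad_diet <- which(!is.na(df$diet) & !(df$diet %in% DIET_LEVELS))
  if (length(bad_diet)) {
    stop("unknown diet label(s): ",
         paste(unique(df$diet[bad_diet]), collapse = ", "))
  }
  dup <- which(duplicated(df$genus))
  if (length(dup)) {
    stop("duplicated genus row(s): ",
         paste(unique(df$genus[dup]), collapse = ", "))
  }
  df[c("genus", "group", "diet", "isolated_only", "molar_count")]
}

#' Per-specimen occlusal areas from length and width
#'
#' Estimates the occlusal area of each tooth as the product of its maximum
#' length and maximum width, and lays specimens out one per row with areas
#' `a1`, `a2`, `a3` (mm^2). A tooth with either dimension missing gets a
#' missing area; length alone is never used as an area proxy.
#'
#' @param measurements A measurement table as returned by
#'   [read_measurements()].
#' @return A `data.frame` with columns `specimen_id`, `genus`, `a1`, `a2`,
#'   `a3`, plus bookkeeping columns `n_teeth` (tooth rows recorded) and
#'   `n_partial` (teeth recorded with exactly one dimension missing), used
#'   downstream to attribute exclusions.
#' @examples
#' m <- data.frame(specimen_id = "s1", genus = "Genus",
#'                 tooth = c("m1", "m2", "m3"),
#'                 length = c(2, 2, 2), width = c(1.5, 1, NA),
#'                 source = "literature")
#' specimen_areas(m)  # a3 is NA: width unavailable
#' @export
specimen_areas <- function(measurements) {
  m <- measurements
  need <- c("specimen_id", "genus", "tooth", "length", "width")
  if (!all(need %in% names(m))) {
    stop("measurements must have columns ", paste(need, collapse = ", "))
  }
  sp <- unique(m[c("specimen_id", "genus")])
  if (anyDuplicated(sp$specimen_id)) {
    bad <- sp$specimen_id[duplicated(sp$specimen_id)]
    stop("specimen(s) assigned to more than one genus: ",
         paste(unique(bad), collapse = ", "))
  }
  m$area <- m$length * m$width
  partial <- xor(is.na(m$length), is.na(m$width))
  for (k in 1:3) {
    sub <- m[m$tooth == TOOTH_LEVELS[k], ]
    sp[[paste0("a", k)]] <- sub$area[match(sp$specimen_id, sub$specimen_id)]
  }
  sp$n_teeth <- as.integer(table(factor(m$specimen_id,
                                        levels = sp$specimen_id)))
  pt <- tapply(partial, factor(m$specimen_id, levels = sp$specimen_id), sum)
  sp$n_partial <- as.integer(pt)
  rownames(sp) <- NULL
  sp
}

#' Apply the specimen and genus inclusion rules
#'
#' Drops (1) whole genera known only from isolated molars, (2) whole genera
#' with fewer than three lower molar positions, and (3) specimens without at
#' least one adjacent pair of measured areas among (m1, m2) and (m2, m3).
#' Every dropped specimen or genus receives exactly one primary exclusion
#' record. When an adjacency failure is attributable to a tooth recorded
#' with one dimension missing, the rule is `missing_length_or_width`;
#' otherwise it is `fewer_than_two_adjacent`.
#'
#' @param areas Specimen areas from [specimen_areas()].
#' @param metadata Genus metadata from [read_metadata()] (or any data frame
#'   with `genus`, `isolated_only`, `molar_count`).
#' @param strict If `TRUE` (default), a genus absent from `metadata` is an
#'   error; if `FALSE` it is assumed non-isolated with three molars and a
#'   warning is issued.
#' @return A list with elements `kept` (the surviving rows of `areas`) and
#'   `exclusions` (a `data.frame` with columns `id`, `level`
#'   (`"genus"`/`"specimen"`), `rule`, `note`).
#' @export
filter_specimens <- function(areas, metadata, strict = TRUE) {
  idx <- match(areas$genus, metadata$genus)
  unknown <- unique(areas$genus[is.na(idx)])
  if (length(unknown)) {
    if (strict) {
      stop("genus missing from metadata: ", paste(unknown, collapse = ", "))
    }
    warning("genus missing from metadata, assuming not isolated with ",
            "3 molars: ", paste(unknown, collapse = ", "))
  }
  isolated <- ifelse(is.na(idx), FALSE, metadata$isolated_only[idx])
  molars <- ifelse(is.na(idx), 3L, metadata$molar_count[idx])
  isolated[is.na(isolated)] <- FALSE
  molars[is.na(molars)] <- 3L

  exclusions <- list()
  drop <- rep(FALSE, nrow(areas))

  iso_gen <- unique(areas$genus[isolated])
  if (length(iso_gen)) {
    exclusions[[length(exclusions) + 1L]] <- data.frame(
      id = iso_gen, level = "genus", rule = "isolated_molars_only",
      note = "taxon known solely from isolated molars",
      stringsAsFactors = FALSE)
    drop <- drop | isolated
  }
  few_gen <- unique(areas$genus[!isolated & molars < 3L])
  if (length(few_gen)) {
    exclusions[[length(exclusions) + 1L]] <- data.frame(
      id = few_gen, level = "genus", rule = "fewer_than_three_molar_positions",
      note = "tooth row has fewer than three lower molars",
      stringsAsFactors = FALSE)
    drop <- drop | (!isolated & molars < 3L)
  }

  adj <- (!is.na(areas$a1) & !is.na(areas$a2)) |
    (!is.na(areas$a2) & !is.na(areas$a3))
  no_adj <- !drop & !adj
  if (any(no_adj)) {
    partial <- if (!is.null(areas$n_partial)) areas$n_partial > 0 else
      rep(FALSE, nrow(areas))
    rule <- ifelse(partial[no_adj], "missing_length_or_width",
                   "fewer_than_two_adjacent")
    exclusions[[length(exclusions) + 1L]] <- data.frame(
      id = areas$specimen_id[no_adj], level = "specimen", rule = rule,
      note = "no adjacent molar pair with both areas measurable",
      stringsAsFactors = FALSE)
    drop <- drop | no_adj
  }

  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(id = character(), level = character(), rule = character(),
               note = character(), stringsAsFactors = FALSE)
  list(kept = areas[!drop, , drop = FALSE], exclusions = excl)
}

#' Per-specimen molar area ratios and m2 share
#'
#' Scales each tooth area against m1: `r21 = a2/a1`, `r31 = a3/a1`,
#' `r32 = a3/a2`. A ratio is present exactly when both constituent areas
#' are. `m2_share = a2/(a1+a2+a3)` is present only when all three areas
#' are. Values below 1 indicate a posterior decrease in molar size.
#'
#' @param areas Specimen areas (typically the `kept` element of
#'   [filter_specimens()]).
#' @return The input with columns `r21`, `r31`, `r32`, `m2_share` appended.
#' @examples
#' a <- data.frame(specimen_id = "s1", genus = "g", a1 = 2, a2 = 3, a3 = 4)
#' specimen_ratios(a)[c("r21", "r31", "r32", "m2_share")]
#' @export
specimen_ratios <- function(areas) {
  out <- areas
  out$r21 <- out$a2 / out$a1
  out$r31 <- out$a3 / out$a1
  out$r32 <- out$a3 / out$a2
  tot <- out$a1 + out$a2 + out$a3
  out$m2_share <- out$a2 / tot
  out
}

#' Aggregate specimen ratios into genus-level morphospace records
#'
#' Computes, per genus, the arithmetic mean of the available per-specimen
#' ratios (not the ratio of mean areas — the two differ under noise):
#' `x` = mean r21 (m2/m1 area), `y` = mean r31 (m3/m1 area), and the mean
#' m2 share of total molar area. Each statistic uses the specimens for
#' which it is defined, so a genus can contribute to the m2/m1 analyses but
#' not the morphospace; downstream statistics each report their own N.
#'
#' @param ratios Specimen ratios from [specimen_ratios()].
#' @param metadata Genus metadata (`genus`, `group`, `diet`).
#' @param strict If `TRUE`, a genus absent from `metadata` is an error.
#' @return A `data.frame` with one row per genus: `genus`, `n_specimens`,
#'   `x`, `y`, `m2_share_mean`, `group`, `diet`.
#' @export
aggregate_genera <- function(ratios, metadata, strict = TRUE) {
  if (!nrow(ratios)) stop("no specimens to aggregate")
  g <- factor(ratios$genus, levels = sort(unique(ratios$genus)))
  mean_na <- function(v, f) {
    out <- tapply(v, f, function(z) {
      z <- z[!is.na(z)]
      if (length(z)) mean(z) else NA_real_
    })
    as.numeric(out)
  }
  rec <- data.frame(
    genus = levels(g),
    n_specimens = as.integer(table(g)),
    x = mean_na(ratios$r21, g),
    y = mean_na(ratios$r31, g),
    m2_share_mean = mean_na(ratios$m2_share, g),
    stringsAsFactors = FALSE)
  idx <- match(rec$genus, metadata$genus)
  missing <- rec$genus[is.na(idx)]
  if (length(missing) && strict) {
    stop("genus absent from metadata: ", paste(missing, collapse = ", "))
  }
  rec$group <- metadata$group[idx]
  rec$diet <- metadata$diet[idx]
  rec
}

#' Write / read genus records at full precision
#'
#' Tab-separated output whose numeric columns are written with 17
#' significant digits, so that writing and re-reading reproduces identical
#' double-precision values.
#'
#' @param records A genus-record `data.frame`.
#' @param path Output (input) path.
#' @return `path`, invisibly (`read_genus_records` returns the records).
#' @export
write_genus_records <- function(records, path) {
  .write_tsv(records, path)
}

#' @rdname write_genus_records
#' @export
read_genus_records <- function(path) {
  df <- .read_tsv(path)
  for (col in c("x", "y", "m2_share_mean")) {
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  }
  df
}
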