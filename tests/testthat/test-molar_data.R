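test_that("measurement reader parses, fills defaults and enforces the schema", {
  path <- system.file("extdata", "demo_measurements.csv", package = "icascade")
  m <- read_measurements(path)
  expect_setequal(names(m),
                  c("specimen_id", "genus", "tooth", "length", "width",
                    "source"))
  expect_true(all(m$tooth %in% c("m1", "m2", "m3")))
  # one record per (specimen, tooth) row; blanks become NA
  expect_equal(sum(m$specimen_id == "Arctocyon_1"), 3L)
  expect_true(is.na(m$width[m$specimen_id == "Didelphodus_1" &
                              m$tooth == "m3"]))

  tmp <- withr::local_tempfile(fileext = ".csv")
  bad <- tooth_rows("s1", "g", c(2, 2, 2), c(1, 1, 1),
                    teeth = c("m1", "m2", "m4"))
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_measurements(tmp), "m4")

  bad2 <- tooth_rows("s1", "g", c(2, -1, 2), c(1, 1, 1))
  write.csv(bad2, tmp, row.names = FALSE)
  expect_error(read_measurements(tmp), "non-positive")

  dup <- rbind(tooth_rows("s1", "g", c(2, 2, 2), c(1, 1, 1)),
               tooth_rows("s1", "g", 2, 1, teeth = "m1"))
  write.csv(dup, tmp, row.names = FALSE)
  expect_error(read_measurements(tmp), "duplicated")
})

test_that("areas are length x width with missing dimensions propagating", {
  m <- rbind(tooth_rows("s1", "g1", c(2.0, 2, 2), c(1.5, 1, 1)),
             tooth_rows("s2", "g1", c(3, 2, 1), c(NA, 2, 1)))
  a <- specimen_areas(m)
  expect_equal(a$a1[a$specimen_id == "s1"], 3.0)
  expect_equal(a$a2[a$specimen_id == "s1"], 2.0)
  expect_true(is.na(a$a1[a$specimen_id == "s2"]))
  expect_equal(a$a3[a$specimen_id == "s2"], 1.0)
  expect_equal(a$n_partial, c(0L, 1L))
  # a specimen may not belong to two genera
  m2 <- m
  m2$genus[4] <- "g2"
  m2$specimen_id <- c("s1", "s1", "s1", "s1", "s2", "s2")
  expect_error(specimen_areas(m2), "more than one genus")
})

test_that("inclusion rules keep adjacent pairs and drop flagged genera", {
  a <- data.frame(
    specimen_id = c("s1", "s2", "s3", "s4", "s5"),
    genus = c("g1", "g1", "g2", "g3", "g4"),
    a1 = c(1, 1, 1, 1, 1), a2 = c(1, 1, NA, 1, 1),
    a3 = c(NA, 1, 1, 1, 1),
    n_teeth = c(2L, 3L, 2L, 3L, 3L), n_partial = c(1L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  meta <- rbind(meta_row("g1"), meta_row("g2"),
                meta_row("g3", isolated_only = TRUE),
                meta_row("g4", molar_count = 2L))
  fl <- filter_specimens(a, meta)
  # s1 kept: (m1, m2) adjacent pair suffices even with a3 missing
  expect_setequal(fl$kept$specimen_id, c("s1", "s2"))
  expect_setequal(fl$exclusions$id, c("s3", "g3", "g4"))
  rules <- setNames(fl$exclusions$rule, fl$exclusions$id)
  expect_equal(rules[["g3"]], "isolated_molars_only")
  expect_equal(rules[["g4"]], "fewer_than_three_molar_positions")
  expect_equal(rules[["s3"]], "fewer_than_two_adjacent")
  # exactly one primary record per dropped unit; kept + dropped partition
  expect_equal(anyDuplicated(fl$exclusions$id), 0L)
  n_dropped_specimens <- sum(!(a$specimen_id %in% fl$kept$specimen_id))
  expect_equal(nrow(fl$kept) + n_dropped_specimens, nrow(a))

  expect_error(filter_specimens(a, meta[-1, ]), "g1")
  expect_warning(fl2 <- filter_specimens(a, meta[-1, ], strict = FALSE),
                 "assuming")
  expect_true(all(c("s1", "s2") %in% fl2$kept$specimen_id))
})

test_that("ratios appear exactly where both areas exist and m2 share needs all three", {
  a <- data.frame(specimen_id = c("s1", "s2", "s3"), genus = "g",
                  a1 = c(3, 2, 2), a2 = c(3, 3, 3), a3 = c(3, 4, NA),
                  stringsAsFactors = FALSE)
  r <- specimen_ratios(a)
  expect_equal(r$r21, c(1, 1.5, 1.5))
  expect_equal(r$r31, c(1, 2, NA_real_))
  expect_equal(r$m2_share, c(1 / 3, 3 / 9, NA_real_))
  # product identity r31 = r21 * r32 whenever all three areas exist
  full <- !is.na(r$r32)
  expect_equal(r$r31[full], r$r21[full] * r$r32[full], tolerance = 1e-12)
})

test_that("genus aggregation means per-specimen ratios and reports own Ns", {
  r <- data.frame(specimen_id = c("s1", "s2", "s3"),
                  genus = c("gA", "gA", "gB"),
                  r21 = c(1.0, 1.2, 2.0), r31 = c(1.1, NA, 3.0),
                  r32 = c(1.1, NA, 1.5), m2_share = c(0.33, NA, 0.33),
                  stringsAsFactors = FALSE)
  meta <- rbind(meta_row("gA"), meta_row("gB", group = "GroupB"))
  rec <- aggregate_genera(r, meta)
  expect_equal(rec$x[rec$genus == "gA"], 1.1)
  expect_equal(rec$y[rec$genus == "gA"], 1.1)  # mean of available r31 only
  expect_equal(rec$n_specimens, c(2L, 1L))
  # single specimen: record equals its ratios
  expect_equal(rec$x[rec$genus == "gB"], 2.0)
  expect_equal(rec$y[rec$genus == "gB"], 3.0)
  expect_error(aggregate_genera(r, meta[1, ]), "gB")
})

test_that("genus records round-trip through disk bit-for-bit", {
  sim <- simulate_dataset(sim_scenario("conforming", seed = 11))
  fl <- filter_specimens(specimen_areas(sim$measurements), sim$metadata)
  rec <- aggregate_genera(specimen_ratios(fl$kept), sim$metadata)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genus_records(rec, tmp)
  back <- read_genus_records(tmp)
  expect_identical(back$x, rec$x)
  expect_identical(back$y, rec$y)
  expect_identical(back$m2_share_mean, rec$m2_share_mean)
  expect_identical(back$genus, rec$genus)
})
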