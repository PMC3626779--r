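quick_config <- function(seed, cv = 0, missing = 0, dev = list(),
                         a_mean = 1.2, a_sd = 0.3, n = 40) {
  sim_config(list(sim_group("G1", "omnivorous", n, a_mean, a_sd),
                  sim_group("G2", "folivorous", n, a_mean + 0.3, a_sd)),
             measurement_cv = cv, missing_rate = missing,
             deviation_modes = dev, seed = seed)
}

test_that("configuration validation rejects malformed inputs", {
  g <- sim_group("G", "omnivorous", 5, 1, 0.1)
  expect_error(sim_config(list(g)), "seed")
  expect_error(sim_config(list("x"), seed = 1), "sim_group")
  expect_error(sim_config(list(g), missing_rate = 1, seed = 1))
  expect_error(sim_config(list(g), deviation_modes = list(list(group = "G")),
                          seed = 1), "deviation")
  expect_error(sim_group("G", "herbivorous", 5, 1, 0.1))
  expect_error(sim_group("G", "omnivorous", 5, -1, 0.1))
})

test_that("same seed gives byte-identical tables, different seeds differ", {
  s1 <- simulate_dataset(sim_scenario("conforming", seed = 5))
  s2 <- simulate_dataset(sim_scenario("conforming", seed = 5))
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(sim_scenario("conforming", seed = 6))
  expect_false(identical(s1$measurements, s3$measurements))
})

test_that("noiseless conforming data lie exactly on the predicted line", {
  sim <- simulate_dataset(quick_config(seed = 8))
  r <- specimen_ratios(specimen_areas(sim$measurements))
  three <- complete.cases(r[c("a1", "a2", "a3")])
  expect_true(all(abs(r$r31[three] - (2 * r$r21[three] - 1)) < 1e-12))
  # per-specimen and per-genus ratios coincide without noise
  rec <- aggregate_genera(r, sim$metadata)
  i <- match(r$genus, rec$genus)
  expect_equal(r$r21, rec$x[i], tolerance = 1e-12)
  # truth table matches what the pipeline recovers
  j <- match(rec$genus, sim$truth$genus)
  expect_equal(rec$x, sim$truth$true_x[j], tolerance = 1e-12)
})

test_that("degenerate and deviation settings behave as specified", {
  # a_sd = 0, a_mean = 1: every genus at the morphospace centre (1, 1)
  cfg <- sim_config(list(sim_group("G", "omnivorous", 15, 1, 0)),
                    measurement_cv = 0, missing_rate = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  rec <- aggregate_genera(specimen_ratios(specimen_areas(sim$measurements)),
                          sim$metadata)
  expect_equal(rec$x, rep(1, 15), tolerance = 1e-12)
  expect_equal(rec$y, rep(1, 15), tolerance = 1e-12)

  # m2 bulge: region is m2-largest exactly when (1+delta) a > max(1, 2a-1)
  delta <- 0.3
  cfg2 <- quick_config(seed = 9, dev = list(list(group = "G1",
                                                 mode = "m2_bulge",
                                                 delta = delta)))
  sim2 <- simulate_dataset(cfg2)
  tr <- sim2$truth[sim2$truth$group == "G1" & !is.na(sim2$truth$true_y), ]
  a <- tr$a
  should_bulge <- (1 + delta) * a > pmax(1, 2 * a - 1)
  expect_equal(tr$true_region == "m2_largest", should_bulge)
  # and the analytic prediction agrees with classify_region on true ratios
  expect_equal(as.character(classify_region(tr$true_x, tr$true_y)),
               tr$true_region)
})

test_that("simulated m1 areas match the configured lognormal", {
  cfg <- sim_config(list(sim_group("G", "omnivorous", 400, 1, 0.2)),
                    m1_area_lognormal = c(log(15), 1), seed = 12)
  sim <- simulate_dataset(cfg)
  lm1 <- log(sim$truth$m1_area)
  expect_equal(mean(lm1), log(15), tolerance = 0.15)
  expect_equal(sd(lm1), 1, tolerance = 0.15)
})

test_that("genera losing m3 are flagged with two molar positions and filtered out", {
  cfg <- sim_config(list(sim_group("G", "carnivorous", 200, 0.5, 0.15)),
                    measurement_cv = 0, missing_rate = 0, seed = 4)
  sim <- simulate_dataset(cfg)
  lost <- sim$truth$a <= 0.5
  expect_true(any(lost))
  expect_equal(sim$metadata$molar_count == 2L, lost)
  fl <- filter_specimens(specimen_areas(sim$measurements), sim$metadata)
  kept_genera <- unique(fl$kept$genus)
  expect_true(all(!(sim$metadata$genus[lost] %in% kept_genera)))
})

test_that("recovery report flags perfect recovery on noiseless data and key mismatches", {
  sim <- simulate_dataset(quick_config(seed = 10))
  an_rec <- aggregate_genera(
    specimen_ratios(filter_specimens(specimen_areas(sim$measurements),
                                     sim$metadata)$kept),
    sim$metadata)
  rr <- recovery_report(sim$truth, an_rec)
  expect_equal(rr$slope_bias, 0, tolerance = 1e-10)
  expect_equal(rr$intercept_bias, 0, tolerance = 1e-10)
  expect_equal(rr$region_accuracy, 1)
  bad <- an_rec
  bad$genus[1] <- "not_in_truth"
  expect_error(recovery_report(sim$truth, bad), "missing from the truth")
})

test_that("null-diet scenario severs the diet/morphospace link", {
  sim <- simulate_dataset(sim_scenario("null_diet", seed = 13))
  conforming <- simulate_dataset(sim_scenario("conforming", seed = 13))
  # same geometry, permuted diet labels
  expect_identical(sim$measurements, conforming$measurements)
  expect_identical(sort(sim$metadata$diet), sort(conforming$metadata$diet))
  expect_false(identical(sim$metadata$diet, conforming$metadata$diet))
})
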