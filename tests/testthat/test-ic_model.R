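test_that("the predicted line and cascade sizes are mutually consistent", {
  expect_equal(ic_line(1), 1)
  expect_equal(ic_line(1.5), 2)
  expect_equal(ic_line(0.5), 0)  # third molar lost at the zero of the line
  expect_error(ic_line(-0.1))

  cs <- cascade_sizes(c(1, 1.5, 0.4))
  expect_equal(unlist(cs[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(1, 1, 1))
  expect_equal(cs$s3[2], 2.0)
  expect_equal(cs$s3[3], 0)
  expect_equal(cs$m3_absent, c(FALSE, FALSE, TRUE))

  # cascade points always lie exactly on the line (a >= 0.5)
  a <- seq(0.5, 3, by = 0.01)
  cs <- cascade_sizes(a)
  expect_equal(cs$s3 / cs$s1, ic_line(cs$s2 / cs$s1), tolerance = 1e-14)
})

test_that("region classification matches its defining inequalities and the theory never leaves its own region", {
  expect_equal(as.character(classify_region(1.2, 1.5)), "m2_intermediate")
  expect_equal(as.character(classify_region(1.2, 0.9)), "m2_largest")
  expect_equal(as.character(classify_region(0.8, 0.9)), "m2_smallest")
  # boundary/equality cases fall inside the predicted region
  expect_equal(as.character(classify_region(1, 1)), "m2_intermediate")
  expect_equal(as.character(classify_region(1.3, 1.3)), "m2_intermediate")

  a <- seq(0, 3, by = 0.02)
  cs <- cascade_sizes(a)
  expect_true(all(classify_region(cs$s2, cs$s3) == "m2_intermediate"))

  # labels invariant to uniform scaling of all three areas
  set.seed(4)
  areas <- matrix(runif(150, 0.5, 6), ncol = 3)
  base <- classify_region(areas[, 2] / areas[, 1], areas[, 3] / areas[, 1])
  for (c_scale in c(0.2, 5)) {
    sc <- areas * c_scale
    expect_identical(classify_region(sc[, 2] / sc[, 1], sc[, 3] / sc[, 1]),
                     base)
  }
  expect_error(classify_region(-1, 1), "non-negative")
})

test_that("trend labels split the predicted region and error elsewhere", {
  expect_equal(as.character(classify_trend(0.8, 0.6)), "decreasing")
  expect_equal(as.character(classify_trend(1.3, 1.8)), "increasing")
  expect_equal(as.character(classify_trend(1.0, 1.0)), "all_equal")
  expect_error(classify_trend(1.2, 0.9), "predicted region")
})

test_that("region summary counts sum to N, are permutation-invariant and handle conformant data", {
  rec <- data.frame(x = c(1.2, 1.2, 0.8), y = c(1.5, 0.9, 0.9))
  rs <- region_summary(rec)
  expect_equal(as.numeric(rs$region),
               c(1, 1, 1))
  expect_equal(rs$pct_predicted, 100 / 3)
  expect_equal(sum(rs$region), rs$n)

  rs2 <- region_summary(rec[c(3, 1, 2), ])
  expect_equal(rs2$region, rs$region)

  on_line <- cascade_points(seq(1.05, 2, length.out = 20))
  rs3 <- region_summary(on_line)
  expect_equal(rs3$pct_predicted, 100)
  expect_equal(unname(as.numeric(rs3$trend["increasing"])), 20)
  expect_error(region_summary(data.frame(x = NA_real_, y = NA_real_)))
})

test_that("m2 share test targets exactly one third and uses genus means", {
  rec <- data.frame(m2_share_mean = rep(1 / 3, 10))
  tt <- m2_share_test(rec)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$mu, 100 / 3)

  # algebraic oracle: share(a) = a / (1 + a + max(0, 2a - 1)), which is
  # exactly 1/3 on the line (a >= 1/2) and a/(1+a) below it
  a <- seq(0.1, 3, by = 0.05)
  share <- a / (1 + a + pmax(0, 2 * a - 1))
  expect_equal(share[a >= 0.5], rep(1 / 3, sum(a >= 0.5)), tolerance = 1e-12)
  expect_equal(share[a < 0.5], (a / (1 + a))[a < 0.5], tolerance = 1e-12)

  rec2 <- data.frame(m2_share_mean = share[a >= 0.5] + rnorm(sum(a >= 0.5),
                                                             sd = 1e-3))
  tt2 <- m2_share_test(rec2)
  expect_equal(tt2$df, sum(a >= 0.5) - 1L)
  expect_error(m2_share_test(data.frame(m2_share_mean = 0.5)), "at least 2")
})
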