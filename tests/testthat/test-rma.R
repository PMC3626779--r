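test_that("point estimates match the s_y/s_x definition and an independent OLS route", {
  # frozen hand computation: var x = 1, var y = 13/3
  fit <- fit_rma(x = c(0, 1, 2), y = c(0, 1, 4))
  expect_equal(fit$slope, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(fit$intercept, 5 / 3 - sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(fit$intercept, fit$slope))

  # perfect-fit recovery of the theoretical line
  a <- seq(0.6, 2.4, length.out = 40)
  fit2 <- fit_rma(x = a, y = 2 * a - 1)
  expect_equal(fit2$slope, 2, tolerance = 1e-13)
  expect_equal(fit2$intercept, -1, tolerance = 1e-13)
  expect_true(fit2$perfect)
  expect_equal(fit2$slope_ci, c(2, 2), tolerance = 1e-13)

  # independent oracle on random data, including negative correlation
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(30)
    y <- 0.5 - 1.3 * x + rnorm(30)
    fit3 <- fit_rma(x = x, y = y)
    orc <- oracle_rma(x, y)
    expect_equal(fit3$slope, orc["slope"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit3$intercept, orc["intercept"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sign(fit3$slope), sign(fit3$r))
  }
  expect_error(fit_rma(x = c(1, 2), y = c(1, 2)), "at least 3")
  expect_error(fit_rma(x = c(1, 1, 1), y = 1:3), "variance")
})

test_that("formula interface, methods and residuals behave like a model object", {
  d <- data.frame(u = seq(0.5, 2, length.out = 20))
  set.seed(21)
  d$v <- 2 * d$u - 1 + rnorm(20, sd = 0.05)
  fit <- fit_rma(v ~ u, data = d)
  expect_s3_class(fit, "rma_fit")
  expect_equal(fit$n, 20L)
  expect_equal(predict(fit, newdata = 1), fit$intercept + fit$slope)
  expect_equal(residuals(fit), d$v - fitted(fit))
  ci <- confint(fit)
  expect_equal(dim(ci), c(2L, 2L))
  expect_true(ci["slope", 1] <= fit$slope && fit$slope <= ci["slope", 2])
  expect_output(print(summary(fit)), "Reduced major axis")
})

test_that("RMA is symmetric in x and y and equivariant under rescaling", {
  set.seed(12)
  for (rep in 1:5) {
    x <- runif(25, 0.5, 3)
    y <- 2 * x - 1 + rnorm(25, sd = 0.3)
    bxy <- fit_rma(x = x, y = y)$slope
    byx <- fit_rma(x = y, y = x)$slope
    expect_equal(bxy, 1 / byx, tolerance = 1e-12)
    cc <- 3.7
    sc <- fit_rma(x = x, y = cc * y)
    base <- fit_rma(x = x, y = y)
    expect_equal(sc$slope, cc * base$slope, tolerance = 1e-12)
    expect_equal(sc$intercept, cc * base$intercept, tolerance = 1e-12)
  }
})

test_that("analytic CIs tighten as alpha grows and bootstrap agrees on well-behaved data", {
  set.seed(5)
  x <- runif(60, 0.5, 2.5)
  y <- 2 * x - 1 + rnorm(60, sd = 0.2)
  widths <- sapply(c(0.01, 0.05, 0.2, 0.5), function(al) {
    diff(fit_rma(x = x, y = y, alpha = al)$slope_ci)
  })
  expect_true(all(diff(widths) < 0))  # monotone shrink toward alpha -> 1

  fa <- fit_rma(x = x, y = y)
  fb <- fit_rma(x = x, y = y, ci = "bootstrap", reps = 1999, seed = 3)
  fb2 <- fit_rma(x = x, y = y, ci = "bootstrap", reps = 1999, seed = 3)
  expect_identical(fb$slope_ci, fb2$slope_ci)  # deterministic given seed
  w <- diff(fa$slope_ci)
  expect_lt(max(abs(fa$slope_ci - fb$slope_ci)), 0.25 * w)
  expect_error(fit_rma(x = x, y = y, ci = "bootstrap", reps = 99, seed = 1),
               "reps")
  expect_error(fit_rma(x = x, y = y, ci = "bootstrap"), "seed")
})

test_that("line comparison reproduces containment and overlap logic", {
  theory <- ic_theory()
  pub <- published_comparisons()$fits
  # broad mammalian fit: slope CI 2.007:2.655 excludes the theoretical 2.0
  cmp <- compare_lines(pub["mammalia", ], theory)
  expect_false(cmp$slope_overlap)
  expect_true(cmp$different)
  # murine CI 1.772:2.688 overlaps the mammalian CI on both parameters
  cmp2 <- compare_lines(pub["mammalia", ], pub["murine", ])
  expect_true(cmp2$slope_overlap)
  expect_false(cmp2$different)
  # a line compared with itself is never different
  set.seed(8)
  x <- runif(20, 0.5, 2)
  y <- 2 * x - 1 + rnorm(20, sd = 0.1)
  fit <- fit_rma(x = x, y = y)
  expect_false(compare_lines(fit, fit)$different)
  expect_error(compare_lines(fit, list(slope = 2)), "parameters")
})
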