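test_that("per-iteration deviation matches the direct formula", {
  # data lying exactly on the curve, draws equal to that curve: deviation 0
  dev0 <- per_iteration_deviation(fake_draws(3, 0),
                                  data.frame(x = 1, n = 10L, y = 5L))
  expect_equal(dev0, 0)  # p(1) = 0.5 = 5/10 exactly

  # single point, single draw: |0.50 - 0.40| in percentage points
  one <- per_iteration_deviation(fake_draws(3, 0),
                                 data.frame(x = 1, n = 10L, y = 4L))
  expect_equal(one, 10)

  # order invariance and bounds
  d <- data.frame(x = c(0.5, 1, 2, 0), n = 20L, y = c(2L, 9L, 17L, 1L))
  dr <- fake_draws(B = c(2, 3), C = c(0, 0.2), E = 1, Z = c(0.02, 0.05))
  expect_equal(per_iteration_deviation(dr, d),
               per_iteration_deviation(dr, d[c(4, 2, 1, 3), ]))
  dev <- per_iteration_deviation(dr, d)
  expect_true(all(dev >= 0 & dev <= 100))
})

test_that("empty-trial rows are dropped with a warning", {
  d <- data.frame(x = c(1, 2), n = c(10L, 0L), y = c(5L, 0L))
  expect_warning(dev <- per_iteration_deviation(fake_draws(3, 0), d),
                 "empty-trial")
  expect_equal(dev, 0)
})

test_that("variability summary is the median with a 95% iteration interval", {
  dr <- fake_draws(B = rep(3, 200), C = seq(-1, 1, length.out = 200))
  d <- data.frame(x = 1, n = 10L, y = 5L)
  v <- within_bioassay_variability(dr, d)
  dev <- per_iteration_deviation(dr, d)
  expect_equal(v$value, median(dev))
  expect_true(v$ci_low <= v$value && v$value <= v$ci_high)
  expect_lte(v$value, max(dev))
})

test_that("statistic approaches the exact mean absolute binomial deviation", {
  cp <- curve_params(3, 0, 1, 0)
  x <- c(0.5, 1, 2)
  p <- mortality_curve(cp, x)
  n <- 100L
  # independent oracle: E|Y/n - p| by exact enumeration of the binomial pmf
  expected_dev <- function(p, n) {
    k <- 0:n
    sum(dbinom(k, n, p) * abs(k / n - p)) * 100
  }
  oracle <- mean(vapply(p, expected_dev, numeric(1), n = n))
  # many replicate observations per concentration, scored against the true
  # curve held fixed (degenerate draws)
  d <- withr::with_seed(55, data.frame(
    x = rep(x, each = 400), n = n,
    y = rbinom(1200, n, rep(p, each = 400))))
  v <- within_bioassay_variability(fake_draws(3, 0), d)
  expect_lt(abs(v$value - oracle) / oracle, 0.1)
})

test_that("aggregation across institutions uses mean and min-max", {
  mk <- function(v, inst) data.frame(institution = inst,
                                     species = "Ae. aegypti",
                                     insecticide = "insecticide-A",
                                     value = v, ci_low = v - 1, ci_high = v + 1,
                                     endpoint_type = "mortality")
  est <- rbind(mk(4, "I1"), mk(6, "I2"), mk(8, "I3"))
  agg <- aggregate_variability(est)
  expect_equal(agg$value, 6)
  expect_equal(c(agg$ci_low, agg$ci_high), c(4, 8))
  expect_equal(aggregate_variability(est[c(2, 3, 1), ])$value, 6)
  # single institution passes through its own interval
  one <- aggregate_variability(est[1, ])
  expect_equal(c(one$value, one$ci_low, one$ci_high), c(4, 3, 5))
  est$insecticide[2] <- "other"
  expect_error(aggregate_variability(est), "mixed")
})
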