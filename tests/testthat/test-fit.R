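# Shared tiny dataset for sampler checks: 4 concentrations spanning the
# response range, generated once from B = 2, C = 0.5 (E = 1, Z = 0).
tiny_data <- data.frame(x = c(0.3, 1, 3, 10), n = 25L, y = c(4L, 12L, 20L, 25L))

test_that("prior-only fit recovers the truncated-normal priors", {
  fit <- fit_dose_response(data.frame(x = numeric(0), n = integer(0),
                                      y = integer(0)),
                           config = mcmc_config(seed = 31))
  s <- fit$samples
  # closed-form means of the truncated priors
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_lt(abs(mean(s$B) - trunc_mean(3, 1, 0, Inf)), 0.05)
  expect_lt(abs(mean(s$C) - 3), 0.2)
  expect_lt(abs(mean(s$E) - trunc_mean(3, 5, 0, Inf)), 0.2)
  expect_lt(abs(mean(s$Z) - trunc_mean(0, 5, 0, 1)), 0.02)
})

test_that("all retained draws respect the parameter constraints", {
  fit <- fit_dose_response(tiny_data, config = fast_config(5))
  s <- fit$samples
  expect_true(all(s$B > 0) && all(s$E > 0) && all(s$Z >= 0) && all(s$Z < 1))
  ran <- if (fit$escalated) fit$config$escalation_iterations else
    fit$config$iterations
  expect_equal(nrow(s),
               fit$config$chains * ran * (1 - fit$config$warmup_fraction))
})

test_that("sampling is deterministic given seed, config and data", {
  f1 <- fit_dose_response(tiny_data, config = fast_config(17))
  f2 <- fit_dose_response(tiny_data, config = fast_config(17))
  expect_identical(f1$samples, f2$samples)
  f3 <- fit_dose_response(tiny_data, config = fast_config(18))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("grid posterior normalises, honours degenerate grids, and is symmetric", {
  g1 <- grid_posterior(tiny_data, grid = list(B = 2, C = 0.5),
                       fixed = list(E = 1, Z = 0))
  expect_equal(sum(g1$cells$mass), 1)
  expect_equal(g1$cells$mass, 1)  # point-mass grid

  # data symmetric about x = e^0 = 1 with E = 1 fixed: the C marginal is
  # symmetric about 0, so its posterior mean sits at 0
  sym <- data.frame(x = c(0.25, 0.5, 2, 4), n = 40L, y = c(10L, 15L, 25L, 30L))
  gs <- grid_posterior(sym, priors = prior_spec(C = c(0, 5)),
                       grid = list(B = seq(0.1, 6, length.out = 150),
                                   C = seq(-4, 4, length.out = 401)),
                       fixed = list(E = 1, Z = 0))
  expect_lt(abs(gs$means["C"]), 0.02)
})

test_that("MCMC agrees with the grid oracle on the reduced model", {
  g <- grid_posterior(tiny_data,
                      grid = list(B = seq(0.05, 8, length.out = 300),
                                  C = seq(-4, 5, length.out = 300)),
                      fixed = list(E = 1, Z = 0))
  fit <- fit_dose_response(tiny_data, config = mcmc_config(seed = 11),
                           fixed = list(E = 1, Z = 0))
  for (nm in c("B", "C")) {
    mcse <- sd(fit$samples[[nm]]) / sqrt(fit$diagnostics$ess[[nm]])
    expect_lt(abs(mean(fit$samples[[nm]]) - g$means[[nm]]), 3 * mcse)
  }
})

test_that("with Z fixed at 0 and large n the posterior concentrates on truth", {
  cp <- curve_params(3, 0, 1, 0)
  des <- campaign_design(concentrations = c(0.25, 0.5, 1, 2, 4),
                         n_per_concentration = 10000L,
                         replicates_per_concentration = 4L,
                         n_control = 1L, n_bioassays = 1L)
  ds <- simulate_bioassay(cp, des, seed = 61)
  rec <- ds$records[ds$records$concentration_ug_per_bottle > 0, ]
  dat <- data.frame(x = rec$concentration_ug_per_bottle, n = rec$n_exposed,
                    y = rec$n_responded)
  fit <- fit_dose_response(dat, config = mcmc_config(seed = 8),
                           fixed = list(Z = 0))
  expect_lt(abs(median(fit$samples$B) - 3) / 3, 0.05)
  expect_lt(abs(median(fit$samples$C) - 0), 0.05)
})

test_that("per-replicate fitting yields one tagged fit per bioassay", {
  cp <- curve_params(3, 0, 1, 0.03)
  des <- campaign_design(n_bioassays = 3L)
  ds <- simulate_bioassay(cp, des, seed = 15)
  fits <- fit_per_replicate(ds, config = fast_config(4, iterations = 500L))
  expect_length(fits, 3L)
  expect_setequal(names(fits), unique(ds$records$bioassay_id))
  for (f in fits) expect_true("bioassay_id" %in% names(f$fit_scope))
  # determinism across repeated calls
  fits2 <- fit_per_replicate(ds, config = fast_config(4, iterations = 500L))
  expect_identical(fits[[1]]$samples, fits2[[1]]$samples)
})
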