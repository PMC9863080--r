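test_that("identical seeds reproduce byte-identical datasets", {
  cp <- curve_params(3, 0, 1, 0.03)
  des <- campaign_design()
  a <- simulate_bioassay(cp, des, seed = 42)
  b <- simulate_bioassay(cp, des, seed = 42)
  expect_identical(a$records, b$records)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_bioassay_csv(a, f1); write_bioassay_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a$records,
                         simulate_bioassay(cp, des, seed = 43)$records))
})

test_that("empirical proportions converge to the true curve at large n", {
  cp <- curve_params(3, 0, 1, 0)
  des <- campaign_design(concentrations = c(0.5, 1, 2),
                         n_per_concentration = 1000000L,
                         replicates_per_concentration = 1L,
                         n_control = 1L, n_bioassays = 1L)
  for (s in 1:3) {
    ds <- simulate_bioassay(cp, des, seed = 200 + s)
    rec <- ds$records[ds$records$concentration_ug_per_bottle > 0, ]
    p_obs <- rec$n_responded / rec$n_exposed
    p_true <- mortality_curve(cp, rec$concentration_ug_per_bottle)
    # 3 sigma of a binomial proportion at n = 1e6
    expect_true(all(abs(p_obs - p_true) <=
                      3 * sqrt(pmax(p_true * (1 - p_true), 0.25e-6) / 1e6)))
  }
  # the inflection point specifically: p = 0.5 at x = e^C
  mid <- ds$records[ds$records$concentration_ug_per_bottle == 1, ]
  expect_lt(abs(mid$n_responded / mid$n_exposed - 0.5), 3 * sqrt(0.25 / 1e6))
  # Z = 0 means controls never respond
  ctrl <- ds$records[ds$records$concentration_ug_per_bottle == 0, ]
  expect_true(all(ctrl$n_responded == 0))
})

test_that("campaign size follows the design arithmetic and labs are labelled", {
  cp <- curve_params(3, 0, 1, 0.03)
  des <- campaign_design()  # 6 concentrations, 4 reps, 2 control bottles, 3 bioassays
  curves <- perturb_curves(cp, c("L1", "L2", "L3"), scale = 0.1, seed = 5)
  camp <- simulate_campaign(curves, des, seed = 9)
  rows_per_bioassay <- length(des$concentrations) *
    des$replicates_per_concentration + 2L
  expect_equal(nrow(camp$records), 3L * des$n_bioassays * rows_per_bioassay)
  expect_setequal(unique(camp$records$institution), c("L1", "L2", "L3"))
  # mosquitoes per concentration per lab: 3 bioassays x 100
  one <- camp$records[camp$records$institution == "L1" &
                        camp$records$concentration_ug_per_bottle ==
                        des$concentrations[1], ]
  expect_equal(sum(one$n_exposed), 300L)
  expect_error(simulate_campaign(setNames(curves, c("L1", "L1", "L3")),
                                 des, seed = 1), "duplicate")
})

test_that("zero perturbation scale keeps every laboratory at the base truth", {
  base <- curve_params(3, 0.2, 1.2, 0.05)
  curves <- perturb_curves(base, paste0("L", 1:4), scale = 0, seed = 3)
  lc50 <- vapply(curves, invert_lc, numeric(1), q = 0.5)
  expect_true(all(lc50 == invert_lc(base, 0.5)))
  curves2 <- perturb_curves(base, paste0("L", 1:4), scale = 0.2, seed = 3)
  expect_gt(stats::sd(vapply(curves2, invert_lc, numeric(1), q = 0.5)), 0)
})

test_that("beta-binomial overdispersion inflates between-replicate variance", {
  cp <- curve_params(3, 0, 1, 0)
  mk <- function(rho) campaign_design(concentrations = 1,
                                      n_per_concentration = 100L,
                                      replicates_per_concentration = 4L,
                                      n_control = 1L, n_bioassays = 60L,
                                      overdispersion_rho = rho)
  # 240 replicate bottles at the inflection point
  v <- vapply(c(0, 0.1), function(rho) {
    ds <- simulate_bioassay(cp, mk(rho), seed = 77)
    rec <- ds$records[ds$records$concentration_ug_per_bottle > 0, ]
    stats::var(rec$n_responded / rec$n_exposed)
  }, numeric(1))
  expect_gt(v[2], v[1])
  # binomial-only variance should be near p(1-p)/25
  expect_lt(abs(v[1] - 0.25 / 25), 0.004)
})

test_that("simulated datasets are valid: round trip and clean QC", {
  cp <- curve_params(3, 0, 1, 0.03)
  for (s in 1:3) {
    ds <- simulate_bioassay(cp, campaign_design(), seed = 300 + s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_bioassay_csv(ds, path)
    back <- read_bioassay_csv(path)
    expect_equal(back$records$n_responded, ds$records$n_responded)
    qc <- apply_qc(ds)
    expect_false(any(qc$report$status == "unevaluable"))
  }
})

test_that("oviposition simulation has the right asymptotes and OI midpoint", {
  cp <- curve_params(3, 0, 1, 0)
  big <- campaign_design(concentrations = c(1e-6, 1, 1e6),
                         n_per_concentration = 500000L,
                         replicates_per_concentration = 1L,
                         n_control = 500000L, n_bioassays = 1L)
  ds <- simulate_oviposition(cp, control_laying_rate = 0.7, big, seed = 21,
                             chambering_rate = 1)
  rec <- ds$records
  rate <- function(x) {
    r <- rec[rec$concentration_ug_per_bottle == x, ]
    sum(r$n_responded) / sum(r$n_chambered)
  }
  expect_true(all(rec$endpoint_type == "oviposition"))
  expect_lt(abs(rate(1e-6) - 0.3), 0.01)   # x -> 0: non-laying -> Z
  expect_gt(rate(1e6), 0.999)              # upper asymptote
  # OI at x = e^C with E = 1: treated laying = 0.7 * 0.5, control 0.7 -> 50%
  oi <- compute_oi(1 - rate(1), 1 - rate(0))
  expect_lt(abs(oi - 50), 1)
})
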