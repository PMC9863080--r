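test_that("CSV round trip preserves records and row order", {
  rec <- make_records(concentration = c(0, 1, 10), n_exposed = 25,
                      n_responded = c(1, 5, 20))
  rec$concentration_ug_per_bottle[2] <- 1.234567890123  # 12 significant digits
  ds <- bioassay_dataset(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bioassay_csv(ds, path)
  back <- read_bioassay_csv(path)
  expect_equal(nrow(back$records), 3L)
  expect_equal(as.numeric(back$records$n_exposed), ds$records$n_exposed)
  expect_equal(as.numeric(back$records$n_responded), ds$records$n_responded)
  expect_equal(back$records$concentration_ug_per_bottle,
               ds$records$concentration_ug_per_bottle, tolerance = 1e-12)
  expect_identical(back$records$bioassay_id, ds$records$bioassay_id)
})

test_that("malformed input is rejected with informative errors", {
  rec <- make_records(concentration = c(0, 1), n_exposed = 25,
                      n_responded = c(30, 5))
  expect_error(bioassay_dataset(rec), "row\\(s\\) 1.*exceeds n_exposed")

  ok <- make_records(concentration = c(0, 1, 10), n_exposed = 25,
                     n_responded = c(1, 5, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ok[, setdiff(names(ok), "n_chambered")], path,
                   row.names = FALSE)
  expect_error(read_bioassay_csv(path), "n_chambered")

  empty <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ok[0, ], empty, row.names = FALSE)
  expect_error(read_bioassay_csv(empty), "empty")

  expect_error(read_bioassay_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("replicate pooling sums counts with the right denominator", {
  g <- make_records(concentration = 1, n_exposed = 25,
                    n_responded = c(5, 7, 6, 4))
  expect_equal(pool_replicates(g), list(n_total = 100, y_total = 22))
  expect_equal(pool_replicates(g[sample(4), ]),
               list(n_total = 100, y_total = 22))  # order-invariant

  one <- make_records(concentration = 1, n_exposed = 25, n_responded = 0)
  expect_equal(pool_replicates(one), list(n_total = 25, y_total = 0))

  ovi <- make_records(concentration = 5, n_exposed = c(12, 10),
                      n_responded = c(9, 8), endpoint_type = "oviposition",
                      n_chambered = c(10, 8))
  expect_equal(pool_replicates(ovi), list(n_total = 18, y_total = 17))

  mixed <- rbind(g[1, ], transform(ovi[1, ], concentration_ug_per_bottle = 1,
                                   bioassay_id = "b1"))
  expect_error(pool_replicates(mixed), "mixed endpoint")
})

test_that("Abbott correction follows the formula, clamps, and is monotone", {
  expect_equal(abbott_correct(0.6, 0.2), 0.5)
  expect_equal(abbott_correct(0.37, 0), 0.37)
  expect_equal(abbott_correct(0.1, 0.2), 0)       # clamped at zero
  expect_error(abbott_correct(0.5, 1), "undefined")
  for (pc in c(0, 0.05, 0.19, 0.6)) {
    p <- seq(0, 1, by = 0.05)
    corrected <- abbott_correct(p, pc)
    expect_true(all(diff(corrected) >= 0))
    expect_equal(abbott_correct(pc, pc), 0)
  }
})

test_that("oviposition inhibition compares laying rates against control", {
  expect_equal(compute_oi(0.2, 0.8), 75)
  expect_equal(compute_oi(0.8, 0.8), 0)
  expect_equal(compute_oi(0, 0.5), 100)
  expect_error(compute_oi(0.2, 0), "undefined")
})

test_that("QC statuses follow the control-mortality rules and partition bioassays", {
  mk <- function(id, ctrl_dead) {
    rbind(make_records(concentration = 0, n_exposed = 50,
                       n_responded = ctrl_dead, bioassay_id = id,
                       replicate_id = "c1"),
          make_records(concentration = c(1, 10), n_exposed = 50,
                       n_responded = c(20, 45), bioassay_id = id))
  }
  rec <- rbind(mk("b04", 2), mk("b10", 5), mk("b20", 10), mk("b25", 13))
  # one bioassay with no controls at all
  rec <- rbind(rec, make_records(concentration = c(1, 10), n_exposed = 50,
                                 n_responded = c(10, 40), bioassay_id = "b_nc"))
  qc <- apply_qc(bioassay_dataset(rec))
  status <- setNames(qc$report$status, qc$report$bioassay_id)
  expect_equal(status[["b04"]], "accepted")                  # 4%
  expect_equal(status[["b10"]], "accepted_with_correction")  # 10%
  expect_equal(status[["b20"]], "discarded")                 # exactly 20%
  expect_equal(status[["b25"]], "discarded")                 # 26%
  expect_equal(status[["b_nc"]], "unevaluable")
  # partition: every bioassay gets exactly one status, accepted set matches
  expect_equal(nrow(qc$report), 5L)
  kept <- unique(qc$accepted$records$bioassay_id)
  expect_setequal(kept, c("b04", "b10"))

  # oviposition: control laying rate 25% (< 30%) is discarded
  ovi <- rbind(
    make_records(concentration = 0, n_exposed = 40, n_responded = 30,
                 bioassay_id = "ov1", endpoint_type = "oviposition",
                 n_chambered = 40, replicate_id = "c1"),
    make_records(concentration = c(5, 50), n_exposed = 40,
                 n_responded = c(30, 38), endpoint_type = "oviposition",
                 n_chambered = 40, bioassay_id = "ov1"))
  qc2 <- apply_qc(bioassay_dataset(ovi))
  expect_equal(qc2$report$status, "discarded")
  expect_match(qc2$report$reason, "laying rate 25.0%")
})
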