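nullTruth <- function(angles = seq(-180, 180, by = 10)) {
  groundTruthMetrics(MachineModel(), angles)
}

test_that("range summary reports max - min with extrema angles", {
  truth <- nullTruth(c(0, 90, 180))
  truth$epid_sag_y <- c(-0.4, 0.0, 0.42)
  m <- metricsFromTruth(truth)
  rs <- rangeSummary(m)
  expect_equal(rs$range[rs$metric == "epid_sag_y"], 0.82)
  expect_equal(rs$angle_max_deg[rs$metric == "epid_sag_y"], 180)
  expect_true(all(rs$range[rs$metric != "epid_sag_y"] == 0))
  # reordering angles changes nothing
  m2 <- metricsFromTruth(truth[c(3, 1, 2), ])
  expect_equal(sort(rangeSummary(m2)$range), sort(rs$range))
})

test_that("reproducibility is the per-angle sample SD across replicates", {
  t0 <- nullTruth()
  reps <- lapply(c(0, 0.1, 0.2), function(o) {
    t <- t0; t$gantry_sag_y <- t$gantry_sag_y + o
    metricsFromTruth(t)
  })
  r <- reproducibility(reps)
  expect_equal(unname(r$maxSd["gantry_sag_y"]), 0.1)
  expect_equal(unname(r$maxSd["epid_sag_x"]), 0)
  expect_error(reproducibility(reps[1]), class = "inputError")
  # identical replicates: SD identically zero
  same <- reproducibility(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(max(same$maxSd), 0)
})

test_that("RMSD comparison is symmetric, zero on self, exact on constant offsets", {
  t0 <- nullTruth()
  m1 <- metricsFromTruth(t0)
  expect_equal(max(rmsdCompare(m1, m1)), 0)
  t2 <- t0; t2$mlc_sag_L <- t2$mlc_sag_L + 0.1
  m2 <- metricsFromTruth(t2)
  r12 <- rmsdCompare(m1, m2); r21 <- rmsdCompare(m2, m1)
  expect_equal(unname(r12["mlc_sag_L"]), 0.1)
  expect_equal(r12, r21)
  # CCW ordering (descending angles) pairs correctly with CW
  mRev <- metricsFromTruth(t0[rev(seq_len(nrow(t0))), ], direction = "CCW")
  expect_equal(max(rmsdCompare(m1, mRev)), 0)
  # insufficient overlap
  narrow <- metricsFromTruth(nullTruth(seq(0, 100, by = 10)))
  expect_error(rmsdCompare(m1, narrow), class = "coverageError")
})

test_that("tolerance verdicts follow TG-142 quantities and report margins", {
  truth <- nullTruth()
  truth$epid_sag_y[10] <- 2.68
  truth$delta_sdd[12] <- -8.65
  m <- metricsFromTruth(truth)
  v <- toleranceCheck(m, ToleranceConfig())
  sagRow <- v[v$metric == "epid_sag_y", ]
  expect_false(sagRow$pass)
  expect_equal(sagRow$margin, 2 - 2.68)
  expect_false(v[v$metric == "delta_sdd", "pass"])   # |−8.65| > 5 mm
  expect_true(v[v$metric == "mlc_sag_R", "pass"])
  # all-zero metrics pass everything that has a threshold
  v0 <- toleranceCheck(metricsFromTruth(nullTruth()))
  expect_true(all(v0$pass[!is.na(v0$pass)]))
})

test_that("SDD magnification impact follows the first-order inverse-square rule", {
  w <- magnificationImpact(8.65, 1500)
  expect_equal(round(unname(w["magnification_pct"]), 2), 0.58)
  expect_equal(round(unname(w["dose_change_pct"]), 2), 1.15)
  expect_equal(unname(magnificationImpact(0, 1500)), c(0, 0))
  expect_equal(round(unname(magnificationImpact(-7.5, 1500)), 2), c(-0.5, -1))
})

test_that("metrics and reports serialise to CSV and JSON", {
  m <- metricsFromTruth(nullTruth())
  f <- tempfile(fileext = ".csv")
  writeMetricsCsv(m, f)
  back <- readMetricsCsv(f)
  expect_equal(metricsTable(back), metricsTable(m))
  rep <- summaryReport(m)
  j <- tempfile(fileext = ".json")
  writeReportJson(rep, j)
  parsed <- jsonlite::read_json(j)
  expect_length(parsed$ranges, 12L)
})
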