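test_that("acquisition schedules cover full rotations inclusively", {
  expect_length(acquisitionSchedule(AcquisitionPlan("integrated")), 37L)
  expect_equal(acquisitionSchedule(AcquisitionPlan("integrated", stepDeg = 90)),
               c(0, 90, 180, 270, 360))
  expect_length(acquisitionSchedule(AcquisitionPlan("cine")), 91L)
  ccw <- acquisitionSchedule(AcquisitionPlan("integrated", direction = "CCW"))
  expect_equal(ccw[1], 360)
  expect_equal(rev(ccw), acquisitionSchedule(AcquisitionPlan("integrated")))
})

test_that("the zero-deformation model projects the ideal phantom at every angle", {
  geom <- fixGeometry()
  lay <- geom@markerLayout
  for (a in c(0, 37, 90, -120, 180)) {
    pr <- projectMarkers(MachineModel(), a, geom)
    expect_equal(unname(markerPositions(pr$markers)), unname(lay),
                 tolerance = 1e-12)
    expect_equal(unname(fieldEdges(pr$edges)), c(-90, 90, 90, -90),
                 tolerance = 1e-12)
  }
})

test_that("projected geometry encodes skew and SDD change as the equations read them", {
  geom <- fixGeometry()
  # skew 0.2 deg at gantry 90: pair (a,b) y-difference = tan(psi) * separation
  model <- MachineModel(skew = c(sin1 = 0.2))
  pr <- projectMarkers(model, 90, geom)
  p <- markerPositions(pr$markers)
  expect_equal(p["b", "y"] - p["a", "y"],
               tan(0.2 * pi / 180) * (p["b", "x"] - p["a", "x"]),
               tolerance = 1e-12)
  # SDD +8.65 mm: head-marker x separations scale by 1508.65/1500
  model2 <- MachineModel(sddVariation = c(cos1 = -8.65 / 2))
  pr2 <- projectMarkers(model2, 180, geom)   # cos1 term reaches -2x at 180
  p2 <- markerPositions(pr2$markers)
  expect_equal((p2["b", "x"] - p2["a", "x"]) / 100, 1508.65 / 1500,
               tolerance = 1e-12)
})

test_that("rendering is deterministic per seed and replicates differ only in noise", {
  plan <- AcquisitionPlan("integrated", stepDeg = 120)
  model <- defaultMachineModel(seed = 4L)
  s1 <- simulateArc(model, plan)
  s2 <- simulateArc(model, plan)
  expect_identical(lapply(beamImages(s1$series), pixelData),
                   lapply(beamImages(s2$series), pixelData))
  r2 <- simulateArc(model, plan, replicateId = 2L)
  expect_equal(r2$truth, s1$truth)
  expect_false(identical(pixelData(beamImages(r2$series)[[1]]),
                         pixelData(beamImages(s1$series)[[1]])))
})

test_that("simulated series round-trip through DICOM files with a truth table", {
  dir <- file.path(tempdir(), "simfix")
  unlink(dir, recursive = TRUE)
  sim <- simulateArc(MachineModel(), AcquisitionPlan("integrated", stepDeg = 90),
                     dir = dir)
  expect_length(sim$files, 5L)
  expect_true(all(file.exists(sim$files)))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 5L)
  metCols <- setdiff(names(truth),
                     c("gantry_angle_deg", "misalignment_A", "misalignment_B"))
  expect_equal(max(abs(as.matrix(truth[metCols]))), 0)  # null model: all zero
  back <- loadArcSeries(sim$files)
  expect_equal(gantryAngle(back), normalizeGantryAngle(c(0, 90, 180, 270, 360)))
})

test_that("doubling the Gaussian noise roughly doubles detection scatter", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  scatter <- function(sd) {
    errs <- c()
    for (t in 1:8) {
      im <- renderBeamImage(fx$truth$markers, fx$truth$edges, geom,
                            gantryAngle = 0, gaussianSd = sd)
      m <- detectMarkers(im, geom)
      errs <- c(errs, markerPositions(m) - markerPositions(fx$truth$markers))
    }
    sqrt(mean(errs^2))
  }
  set.seed(31)
  ratio <- scatter(0.02) / scatter(0.01)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("model validity enforces the identifiability constraints", {
  expect_error(MachineModel(epidSagX = c(cos1 = 0.2)), "cos1")
  expect_error(MachineModel(epidSagY = c(sin1 = 0.2)), "sin1")
  expect_error(MachineModel(gantrySagX = c(sin1 = 20)), "range")
  expect_s4_class(MachineModel(epidSagX = c(sin1 = 0.1)), "MachineModel")
})
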