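test_that("gantry-angle normalisation maps [0,360) onto (-180,180] and is idempotent", {
  expect_equal(normalizeGantryAngle(c(0, 90, 180, 181, 270, 359, 360)),
               c(0, 90, 180, -179, -90, -1, 0))
  grid <- seq(0, 359.5, by = 0.5)
  norm <- normalizeGantryAngle(grid)
  expect_true(all(norm > -180 & norm <= 180))
  expect_equal(anyDuplicated(norm), 0L)          # bijective on [0, 360)
  expect_equal(normalizeGantryAngle(norm), norm) # idempotent
})

test_that("isocentre-plane conversion scales by 1000/SDD and is linear", {
  im <- BeamImage(matrix(0, 384, 512), sdd = 1500, pixelSpacing = c(0.75, 0.75))
  axis <- c((384 + 1) / 2, (512 + 1) / 2)
  # detector offset (1.5 mm, 0) -> 1.0 mm at isocentre
  p <- toIsocentreMM(axis[1], axis[2] + 2, im)   # 2 px * 0.75 = 1.5 mm
  expect_equal(unname(p[1, "x_mm"]), 1.0)
  expect_equal(unname(p[1, "y_mm"]), 0.0)
  # origin is a fixed point
  expect_equal(as.numeric(toIsocentreMM(axis[1], axis[2], im)), c(0, 0))
  # (3, -3) mm detector -> (2, -2); both axes scale
  p2 <- toIsocentreMM(axis[1] + 4, axis[2] + 4, im)
  expect_equal(as.numeric(p2), c(2, -2))
  # linearity in the detector offset
  a <- toIsocentreMM(axis[1] + 1.3, axis[2] - 2.6, im)
  b <- toIsocentreMM(axis[1] + 2.6, axis[2] - 5.2, im)
  expect_equal(as.numeric(b), 2 * as.numeric(a))
})

test_that("DICOM round trip preserves every metadata field and the pixels", {
  set.seed(11)
  px <- matrix(sample(0:40000, 384 * 512, replace = TRUE), 384, 512)
  im <- BeamImage(px, gantryAngle = 359, collimatorAngle = 90, sdd = 1500,
                  pixelSpacing = c(0.784, 0.784), mode = "integrated",
                  frameIndex = 7L)
  f <- tempfile(fileext = ".dcm")
  writeBeamImage(im, f)
  back <- readBeamImage(f)
  expect_equal(gantryAngle(back), -1)            # 359 stored, IEC on read
  expect_equal(collimatorAngle(back), 90)
  expect_equal(sdd(back), 1500)
  expect_equal(pixelSpacing(back), c(0.784, 0.784))
  expect_equal(acquisitionMode(back), "integrated")
  expect_equal(frameIndex(back), 7L)
  expect_identical(pixelData(back), px)
  expect_equal(back@beamAxisPx, im@beamAxisPx)
})

test_that("reader reports missing mandatory tags and rejects non-DICOM input", {
  f <- tempfile()
  writeBin(as.raw(rep(0, 200)), f)
  expect_error(readBeamImage(f), "DICM", class = "dicomFormatError")

  # a valid file with the gantry-angle element stripped out
  im <- BeamImage(matrix(100, 384, 512))
  g <- tempfile(fileext = ".dcm")
  writeBeamImage(im, g)
  bytes <- readBin(g, "raw", file.info(g)$size)
  tag <- c(epidArcQA:::.rawLE(0x300A, 2), epidArcQA:::.rawLE(0x011E, 2))
  pos <- NA
  for (i in seq_len(length(bytes) - 7)) {
    if (all(bytes[i:(i + 3)] == tag)) { pos <- i; break }
  }
  len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                 signed = FALSE, endian = "little")
  stripped <- bytes[-(pos:(pos + 7 + len))]
  h <- tempfile(fileext = ".dcm")
  writeBin(stripped, h)
  expect_error(readBeamImage(h), "GantryAngle", class = "dicomMetadataError")
})

test_that("arc series are sorted by acquisition order with the gantry-zero reference", {
  model <- MachineModel(gaussianSd = 0, saltFraction = 0)
  sim <- simulateArc(model, AcquisitionPlan("integrated", stepDeg = 60))
  imgs <- beamImages(sim$series)
  series <- loadArcSeries(imgs)
  expect_s4_class(series, "ArcSeries")
  expect_equal(referenceIndex(series), 1L)       # first 0-degree frame
  # shuffled input produces the same ordered series
  shuffled <- loadArcSeries(imgs[c(4, 1, 6, 2, 7, 3, 5)])
  expect_equal(gantryAngle(shuffled), gantryAngle(series))
  expect_equal(referenceIndex(shuffled), referenceIndex(series))
})

test_that("reference tie-break, reference tolerance and consistency checks", {
  mk <- function(angle, frame, coll = 0)
    BeamImage(matrix(100, 384, 512), gantryAngle = angle,
              collimatorAngle = coll, frameIndex = frame)
  # two frames at exactly zero: first in acquisition order wins
  imgs <- list(mk(0, 1L), mk(120, 2L), mk(240, 3L), mk(0, 4L))
  expect_equal(referenceIndex(loadArcSeries(imgs)), 1L)
  # no frame near zero
  far <- list(mk(10, 1L), mk(120, 2L), mk(250, 3L))
  expect_error(loadArcSeries(far), class = "referenceError")
  # mixed collimator angles
  mixed <- list(mk(0, 1L), mk(120, 2L, coll = 90), mk(240, 3L))
  expect_error(loadArcSeries(mixed), class = "consistencyError")
  # insufficient angular span
  narrow <- list(mk(0, 1L), mk(45, 2L), mk(90, 3L))
  expect_error(loadArcSeries(narrow), class = "coverageError")
})
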