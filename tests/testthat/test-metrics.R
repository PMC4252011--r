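angles37 <- seq(0, 360, by = 10)

test_that("misalignment fit recovers exact basis signals and the null case", {
  th <- seq(0, 350, by = 10)
  e <- cbind(1.0 * cos(th * pi / 180), 0)        # pure 1 mm lateral offset
  fit <- fitMisalignment(th, e)
  expect_equal(fit@A, 1.0, tolerance = 1e-12)
  expect_equal(fit@B, 0.0, tolerance = 1e-12)
  expect_equal(fit@residualRms, 0, tolerance = 1e-12)

  fit0 <- fitMisalignment(th, cbind(rep(0, length(th)), 0))
  expect_equal(c(fit0@A, fit0@B), c(0, 0))

  expect_error(fitMisalignment(seq(0, 90, by = 15), cbind(0, 0 * (0:6))),
               class = "coverageError")
})

test_that("EPID sag cancels a pure marker offset and is zero for a null machine", {
  geom <- fixGeometry()
  # pure e-marker offset, no true sag
  model <- MachineModel(eMarkerOffset = c(0.8, -0.5))
  ps <- projectSeries(model, angles37)
  arr <- epidArcQA:::.markerArray(ps$markers)
  fit <- fitMisalignment(ps$angles, arr[, "e", ])
  expect_equal(fit@A, 0.8, tolerance = 1e-9)
  expect_equal(fit@B, -0.5, tolerance = 1e-9)
  sag <- epidSag(ps$angles, arr[, "e", ], fit)
  expect_lt(max(abs(sag)), 0.02)
  # literal anchoring reproduces the unanchored form: value -A at gantry zero
  lit <- epidSag(ps$angles, arr[, "e", ], fit, anchor = "literal")
  expect_equal(unname(lit[1, "x"]), -0.8, tolerance = 1e-9)
  # null machine: sag identically zero
  ps0 <- projectSeries(MachineModel(), angles37)
  arr0 <- epidArcQA:::.markerArray(ps0$markers)
  sag0 <- epidSag(ps0$angles, arr0[, "e", ])
  expect_equal(max(abs(sag0)), 0, tolerance = 1e-12)
})

test_that("gantry sag plus EPID sag equals the mean head-marker displacement", {
  model <- defaultMachineModel()
  ps <- projectSeries(model, angles37)
  arr <- epidArcQA:::.markerArray(ps$markers)
  es <- epidSag(ps$angles, arr[, "e", ])
  gs <- gantrySag(arr, es, referenceIndex = 1L)
  mx <- rowMeans(arr[, c("a", "b", "c", "d"), "x"])
  my <- rowMeans(arr[, c("a", "b", "c", "d"), "y"])
  expect_equal(gs[, "x"] + es[, "x"], mx - mx[1], tolerance = 1e-12)
  expect_equal(gs[, "y"] + es[, "y"], my - my[1], tolerance = 1e-12)
})

test_that("SDD change follows the separation-ratio equation", {
  # constant separation ratio of 1 -> zero everywhere
  ps <- projectSeries(MachineModel(), angles37)
  arr <- epidArcQA:::.markerArray(ps$markers)
  expect_equal(max(abs(sddChange(arr, 1500, 1L))), 0)
  # separation ratio 1508.65/1500 at one angle -> 8.65 mm
  arr2 <- arr
  arr2[5, c("b", "d"), "x"] <- arr2[5, c("b", "d"), "x"] * 1508.65 / 1500
  arr2[5, c("a", "c"), "x"] <- arr2[5, c("a", "c"), "x"] * 1508.65 / 1500
  d <- sddChange(arr2, 1500, 1L)
  expect_equal(d[5], 8.65, tolerance = 1e-9)
  # near-zero reference separation is a geometry error
  arr3 <- arr; arr3[, , "x"] <- arr3[, , "x"] / 100
  expect_error(sddChange(arr3, 1500, 1L), class = "geometryError")
})

test_that("skewness measures rigid rotations consistently from either pair", {
  model <- MachineModel(skew = c(cos1 = -0.075))   # 0.15 deg at gantry 180
  ps <- projectSeries(model, angles37)
  arr <- epidArcQA:::.markerArray(ps$markers)
  sk <- skewness(arr, 1L)
  expect_equal(sk[19], 0.15, tolerance = 1e-9)     # gantry 180
  expect_equal(sk[1], 0)
  skAlt <- skewness(arr, 1L, pair = c("c", "d"))
  expect_lt(max(abs(sk - skAlt)), 0.01)            # rigid-body agreement
  expect_error(skewness(arr, 1L, pair = c("a", "c")), class = "geometryError")
})

test_that("tilt rejects common-mode SDD changes and flips sign with the pitch", {
  # pure SDD change: both pair estimates match, tilt = 0
  ps <- projectSeries(MachineModel(sddVariation = c(cos1 = -0.85)), angles37)
  tl <- epidTilt(epidArcQA:::.markerArray(ps$markers), 1500, 1L)
  expect_lt(max(abs(tl)), 1e-9)
  # injected pitch recovered with its sign
  up <- projectSeries(MachineModel(tiltY = c(cos1 = -0.05)), angles37)
  dn <- projectSeries(MachineModel(tiltY = c(cos1 = +0.05)), angles37)
  tUp <- epidTilt(epidArcQA:::.markerArray(up$markers), 1500, 1L)
  tDn <- epidTilt(epidArcQA:::.markerArray(dn$markers), 1500, 1L)
  expect_equal(unname(tUp[19, "tilt_y_deg"]), 0.10, tolerance = 1e-9)
  expect_equal(tUp[, "tilt_y_deg"], -tDn[, "tilt_y_deg"], tolerance = 1e-12)
})

test_that("MLC sag cancels rigid common-mode shifts", {
  # markers and edges shifted together (gantry sag): all four sags zero
  model <- MachineModel(gantrySagX = c(sin1 = 0.5), gantrySagY = c(cos1 = -0.4))
  ps <- projectSeries(model, angles37)
  ml <- mlcCarriageSag(ps$markers, ps$edges, 1L)
  expect_lt(max(abs(ml)), 1e-12)
})

test_that("analytic round trip recovers every curve of a rich model exactly", {
  model <- MachineModel(
    sdd0 = 1500,
    epidSagX = c(sin1 = 0.1, sin2 = -0.04), epidSagY = c(cos1 = -0.5, cos3 = 0.05),
    gantrySagX = c(sin1 = 0.2, step = 0.1), gantrySagY = c(cos2 = -0.3),
    sddVariation = c(cos1 = -0.85, sin2 = 0.3),
    skew = c(cos1 = -0.07, sin1 = 0.02),
    tiltX = c(sin1 = 0.01), tiltY = c(cos1 = -0.05, sin3 = 0.01),
    carriageL = c(sin1 = -0.4), carriageR = c(sin1 = 0.35),
    carriageG = c(cos1 = -0.17), carriageT = c(cos1 = 0.16),
    eMarkerOffset = c(0.8, -0.5))
  ps <- projectSeries(model, angles37)
  met <- computeArcMetrics(ps$markers, ps$edges, ps$angles, 1500)
  truth <- groundTruthMetrics(model, angles37)
  tab <- metricsTable(met)
  for (nm in names(tab))
    expect_lt(max(abs(tab[[nm]] - truth[[nm]])), 1e-9)
  expect_equal(misalignment(met)@A, 0.8, tolerance = 1e-9)
  expect_equal(misalignment(met)@B, -0.5, tolerance = 1e-9)
})

test_that("a global image translation common to all angles changes no metric", {
  model <- defaultMachineModel()
  ps <- projectSeries(model, angles37)
  met0 <- computeArcMetrics(ps$markers, ps$edges, ps$angles, 1500)
  shift <- c(0.7, -0.4)
  markersS <- lapply(ps$markers, function(m) {
    p <- markerPositions(m); p[, 1] <- p[, 1] + shift[1]; p[, 2] <- p[, 2] + shift[2]
    MarkerSet(p)
  })
  edgesS <- lapply(ps$edges, function(e) {
    v <- fieldEdges(e)
    FieldEdges(v[["L"]] + shift[1], v[["R"]] + shift[1],
               v[["G"]] + shift[2], v[["T"]] + shift[2])
  })
  metS <- computeArcMetrics(markersS, edgesS, ps$angles, 1500)
  expect_equal(metricsTable(metS), metricsTable(met0), tolerance = 1e-9)
})

test_that("series analysis tolerates isolated bad images but not a bad reference", {
  sim <- fixArc()
  imgs <- beamImages(sim$series)
  # corrupt one non-reference image completely
  bad <- initialize(imgs[[5]], pixels = matrix(400, 768, 1024))
  series <- new("ArcSeries", images = c(imgs[1:4], bad, imgs[6:13]),
                direction = "CW", collimator = 0, replicateId = 1L,
                referenceIndex = 1L)
  expect_warning(met <- analyzeArcSeries(series, fixGeometry()), "image 5")
  expect_equal(length(met), 12L)
  # too many unusable images aborts
  flat <- lapply(imgs, function(i) initialize(i, pixels = matrix(400, 768, 1024)))
  series2 <- new("ArcSeries", images = c(imgs[1:4], flat[5:13]),
                 direction = "CW", collimator = 0, replicateId = 1L,
                 referenceIndex = 1L)
  expect_error(suppressWarnings(analyzeArcSeries(series2, fixGeometry())),
               class = "detectionError")
})
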