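test_that("noiseless marker recovery matches the projected truth within 0.02 mm", {
  fx <- fixNoiselessImage()
  det <- detectMarkers(fx$image, fixGeometry())
  err <- abs(markerPositions(det) - markerPositions(fx$truth$markers))
  expect_lt(max(err), 0.02)
  expect_true(all(detectionScores(det) > 0.5))
})

test_that("markers and edges are translation equivariant", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  delta <- c(1.3, -0.9)
  pos <- markerPositions(fx$truth$markers)
  pos[, 1] <- pos[, 1] + delta[1]; pos[, 2] <- pos[, 2] + delta[2]
  e0 <- fieldEdges(fx$truth$edges)
  shifted <- renderBeamImage(MarkerSet(pos),
                             FieldEdges(e0[["L"]] + delta[1], e0[["R"]] + delta[1],
                                        e0[["G"]] + delta[2], e0[["T"]] + delta[2]),
                             geom, gantryAngle = 0)
  m0 <- detectMarkers(fx$image, geom)
  m1 <- detectMarkers(shifted, geom)
  shift <- markerPositions(m1) - markerPositions(m0)
  expect_lt(max(abs(shift[, "x"] - delta[1])), 0.01)
  expect_lt(max(abs(shift[, "y"] - delta[2])), 0.01)
  ed0 <- detectFieldEdges(fx$image, geom, m0)
  ed1 <- detectFieldEdges(shifted, geom, m1)
  d <- fieldEdges(ed1) - fieldEdges(ed0)
  expect_lt(max(abs(d[c("L", "R")] - delta[1])), 0.01)
  expect_lt(max(abs(d[c("G", "T")] - delta[2])), 0.01)
})

test_that("a missing marker raises a detection error reporting the count", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  im <- fx$image
  px <- pixelData(im)
  # paint marker d's shadow with the plateau level
  pos <- markerPositions(fx$truth$markers)["d", ]
  sp <- pixelSpacing(im); k <- sdd(im) / 1000; axis <- im@beamAxisPx
  r0 <- axis[1] - pos["y"] * k / sp[1]; c0 <- axis[2] + pos["x"] * k / sp[2]
  ri <- round(r0 + (-30:30)); ci <- round(c0 + (-30:30))
  px[ri, ci] <- 8000
  broken <- initialize(im, pixels = px)
  expect_error(detectMarkers(broken, geom), "4", class = "detectionError")
})

test_that("field edges recover a symmetric aperture and an injected bank shift", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  ed <- detectFieldEdges(fx$image, geom, fx$truth$markers)
  e <- fieldEdges(ed)
  expect_equal(unname(e[["L"]]), -90, tolerance = 0.02)
  expect_equal(unname(e[["R"]]), 90, tolerance = 0.02)
  expect_equal(unname(e[["G"]]), 90, tolerance = 0.02)
  expect_equal(unname(e[["T"]]), -90, tolerance = 0.02)
  expect_equal(unname(e[["L"]]), mean(ed@perLeafL))

  shifted <- renderBeamImage(fx$truth$markers,
                             FieldEdges(-90, 90.7, 90, -90), geom,
                             gantryAngle = 0)
  ed2 <- detectFieldEdges(shifted, geom, fx$truth$markers)
  expect_equal(unname(fieldEdges(ed2)[["R"]]), 90.7, tolerance = 0.05)
  expect_equal(unname(fieldEdges(ed2)[["L"]]), -90.0, tolerance = 0.05)
})

test_that("the 50% crossing is independent of the penumbra width", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  res <- vapply(c(1.5, 2.5, 4), function(p) {
    im <- renderBeamImage(fx$truth$markers, fx$truth$edges, geom,
                          gantryAngle = 0, penumbraMm = p)
    fieldEdges(detectFieldEdges(im, geom, fx$truth$markers))
  }, numeric(4))
  expect_lt(max(abs(res - c(-90, 90, 90, -90))), 0.02)
})

test_that("detection keeps sub-0.1 mm RMS precision under realistic noise", {
  geom <- fixGeometry()
  fx <- fixNoiselessImage()
  set.seed(21)
  errsM <- c(); errsE <- c()
  for (t in 1:12) {
    im <- renderBeamImage(fx$truth$markers, fx$truth$edges, geom,
                          gantryAngle = 0, gaussianSd = 0.01,
                          saltFraction = 0.002)
    m <- detectMarkers(im, geom)
    e <- detectFieldEdges(im, geom, m)
    errsM <- c(errsM, markerPositions(m) - markerPositions(fx$truth$markers))
    errsE <- c(errsE, fieldEdges(e) - fieldEdges(fx$truth$edges))
  }
  expect_lt(sqrt(mean(errsM^2)), 0.1)
  expect_lt(sqrt(mean(errsE^2)), 0.1)
})
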