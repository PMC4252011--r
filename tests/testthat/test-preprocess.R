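test_that("filters are identity on constant images", {
  m <- matrix(7, 20, 30)
  expect_equal(conservativeSmooth(m), m)
  expect_equal(rankFilter2x2(m, 4L), m)
  expect_equal(rankFilter2x2(m, 1L), m)
})

test_that("conservative smoothing clamps isolated spikes, preserves ramps", {
  m <- matrix(1, 9, 9)
  m[5, 5] <- 100                       # hot pixel
  m[2, 2] <- -50                       # cold pixel
  sm <- conservativeSmooth(m)
  expect_equal(sm[5, 5], 1)
  expect_equal(sm[2, 2], 1)
  ramp <- outer(1:15, 1:20, "+")       # monotone gradient: untouched
  expect_equal(conservativeSmooth(ramp), ramp)
})

test_that("2x2 rank filter takes the window order statistic, top-left aligned", {
  m <- matrix(c(1, 3, 2, 4, 6, 5, 7, 9, 8), 3, 3, byrow = TRUE)
  mx <- rankFilter2x2(m, 4L)
  expect_equal(mx[1, 1], 6)            # max of 1,3,4,6
  expect_equal(mx[2, 2], 9)            # max of 6,5,9,8
  mn <- rankFilter2x2(m, 1L)
  expect_equal(mn[1, 1], 1)
  expect_equal(mn[2, 2], 5)
  expect_error(rankFilter2x2(m, 2L), class = "inputError")
})

test_that("preprocessing is near-idempotent on noiseless simulator images", {
  # conservative smoothing is exactly idempotent
  im <- fixNoiselessImage()$image
  cs <- conservativeSmooth(pixelData(im))
  expect_identical(conservativeSmooth(cs), cs)
  # a second full pass only re-touches the intensity-transition bands
  # (penumbra and shadow edges), a small fraction of the panel
  once <- preprocessImage(im)
  twice <- preprocessImage(once)
  changed <- mean(pixelData(twice) != pixelData(once))
  expect_lt(changed, 0.02)
})

test_that("salt noise moves marker centroids by less than 0.05 mm", {
  geom <- fixGeometry()
  pr <- fixNoiselessImage()$truth
  clean <- detectMarkers(fixNoiselessImage()$image, geom)
  set.seed(3)
  salted <- renderBeamImage(pr$markers, pr$edges, geom, gantryAngle = 0,
                            gaussianSd = 0, saltFraction = 0.005)
  noisy <- detectMarkers(salted, geom)
  shift <- abs(markerPositions(noisy) - markerPositions(clean))
  expect_lt(max(shift), 0.05)
})
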