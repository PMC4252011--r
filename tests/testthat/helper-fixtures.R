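# Shared fixtures, built once per test run.

.fixtures <- new.env()

fixGeometry <- function() defaultPhantomGeometry()

# a small deformed, noisy arc (13 images, 30-degree steps) reused across files
fixArc <- function() {
  if (!exists("arc", envir = .fixtures)) {
    sim <- simulateArc(defaultMachineModel(),
                       AcquisitionPlan("integrated", stepDeg = 30),
                       fixGeometry())
    assign("arc", sim, envir = .fixtures)
  }
  get("arc", envir = .fixtures)
}

# one noiseless image of the undeformed machine at gantry zero
fixNoiselessImage <- function() {
  if (!exists("img0", envir = .fixtures)) {
    pr <- projectMarkers(MachineModel(gaussianSd = 0, saltFraction = 0), 0,
                         fixGeometry())
    img <- renderBeamImage(pr$markers, pr$edges, fixGeometry(),
                           gantryAngle = 0)
    assign("img0", list(image = img, truth = pr), envir = .fixtures)
  }
  get("img0", envir = .fixtures)
}

# analytic (image-free) marker/edge series for a model over an angle grid
projectSeries <- function(model, angles, geometry = fixGeometry()) {
  pr <- lapply(angles, function(a) projectMarkers(model, a, geometry))
  list(markers = lapply(pr, `[[`, "markers"),
       edges = lapply(pr, `[[`, "edges"),
       angles = normalizeGantryAngle(angles))
}

# ArcMetrics built directly from a truth table (for statistics tests)
metricsFromTruth <- function(truth, direction = "CW", collimator = 0,
                             replicateId = 1L) {
  ref <- which.min(abs(truth$gantry_angle_deg))
  new("ArcMetrics", anglesDeg = truth$gantry_angle_deg,
      metrics = truth[setdiff(names(truth), "gantry_angle_deg")],
      misalignment = new("MisalignmentFit", A = 0, B = 0, residualRms = 0),
      referenceIndex = ref, direction = direction,
      collimator = collimator, replicateId = as.integer(replicateId))
}
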