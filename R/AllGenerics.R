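#' @include AllClasses.R
NULL

#' Accessors for epidArcQA classes
#'
#' Standard accessor generics for the package's S4 containers.  Slots are
#' never accessed directly by user code.
#'
#' @param object an epidArcQA object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object, ...) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("gantryAngle", function(object, ...) standardGeneric("gantryAngle"))
#' @rdname accessors
#' @export
setGeneric("collimatorAngle", function(object, ...) standardGeneric("collimatorAngle"))
#' @rdname accessors
#' @export
setGeneric("sdd", function(object, ...) standardGeneric("sdd"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object, ...) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("acquisitionMode", function(object, ...) standardGeneric("acquisitionMode"))
#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object, ...) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setGeneric("beamImages", function(object, ...) standardGeneric("beamImages"))
#' @rdname accessors
#' @export
setGeneric("referenceIndex", function(object, ...) standardGeneric("referenceIndex"))
#' @rdname accessors
#' @export
setGeneric("arcDirection", function(object, ...) standardGeneric("arcDirection"))
#' @rdname accessors
#' @export
setGeneric("markerPositions", function(object, ...) standardGeneric("markerPositions"))
#' @rdname accessors
#' @export
setGeneric("detectionScores", function(object, ...) standardGeneric("detectionScores"))
#' @rdname accessors
#' @export
setGeneric("fieldEdges", function(object, ...) standardGeneric("fieldEdges"))
#' @rdname accessors
#' @export
setGeneric("anglesDeg", function(object, ...) standardGeneric("anglesDeg"))
#' @rdname accessors
#' @export
setGeneric("metricsTable", function(object, ...) standardGeneric("metricsTable"))
#' @rdname accessors
#' @export
setGeneric("misalignment", function(object, ...) standardGeneric("misalignment"))

setMethod("pixelData", "BeamImage", function(object, ...) object@pixels)
setMethod("gantryAngle", "BeamImage", function(object, ...) object@gantryAngle)
setMethod("collimatorAngle", "BeamImage", function(object, ...) object@collimatorAngle)
setMethod("sdd", "BeamImage", function(object, ...) object@sdd)
setMethod("pixelSpacing", "BeamImage", function(object, ...) object@pixelSpacing)
setMethod("acquisitionMode", "BeamImage", function(object, ...) object@mode)
setMethod("frameIndex", "BeamImage", function(object, ...) object@frameIndex)

setMethod("beamImages", "ArcSeries", function(object, ...) object@images)
setMethod("referenceIndex", "ArcSeries", function(object, ...) object@referenceIndex)
setMethod("arcDirection", "ArcSeries", function(object, ...) object@direction)
setMethod("collimatorAngle", "ArcSeries", function(object, ...) object@collimator)
setMethod("gantryAngle", "ArcSeries", function(object, ...)
  vapply(object@images, gantryAngle, numeric(1)))

#' @rdname accessors
#' @param i index
#' @param j unused
#' @export
setMethod("[[", "ArcSeries", function(x, i, j, ...) x@images[[i]])

#' @rdname accessors
#' @param x an ArcSeries or ArcMetrics
#' @export
setMethod("length", "ArcSeries", function(x) length(x@images))

setMethod("markerPositions", "MarkerSet", function(object, ...) object@positions)
setMethod("detectionScores", "MarkerSet", function(object, ...) object@scores)

setMethod("fieldEdges", "FieldEdges", function(object, ...)
  c(L = object@L, R = object@R, G = object@G, T = object@T))

setMethod("anglesDeg", "ArcMetrics", function(object, ...) object@anglesDeg)
setMethod("metricsTable", "ArcMetrics", function(object, ...) object@metrics)
setMethod("misalignment", "ArcMetrics", function(object, ...) object@misalignment)
setMethod("referenceIndex", "ArcMetrics", function(object, ...) object@referenceIndex)
setMethod("arcDirection", "ArcMetrics", function(object, ...) object@direction)
setMethod("length", "ArcMetrics", function(x) length(x@anglesDeg))

#' Coerce ArcMetrics to a data.frame
#'
#' One row per gantry angle, one column per metric, with the angle in the
#' first column.
#'
#' @param x an \linkS4class{ArcMetrics}.
#' @param ... unused.
#' @return a data.frame.
#' @export
setMethod("as.data.frame", "ArcMetrics", function(x, ...) {
  cbind(data.frame(gantry_angle_deg = x@anglesDeg), x@metrics)
})

setMethod("show", "BeamImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BeamImage %dx%d px | gantry %+0.1f deg | collimator %0.0f deg | SDD %0.1f mm | %s #%d\n",
              d[1], d[2], object@gantryAngle, object@collimatorAngle,
              object@sdd, object@mode, object@frameIndex))
})

setMethod("show", "ArcSeries", function(object) {
  ang <- gantryAngle(object)
  cat(sprintf("ArcSeries: %d images, %s, collimator %0.0f deg, replicate %d\n",
              length(object@images), object@direction, object@collimator,
              object@replicateId))
  cat(sprintf("  gantry angles %0.1f..%0.1f deg; reference image #%d (%+0.2f deg)\n",
              min(ang), max(ang), object@referenceIndex,
              ang[object@referenceIndex]))
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet (isocentre-plane mm):\n")
  print(round(object@positions, 3))
  cat("scores:", paste(sprintf("%.2f", object@scores), collapse = " "), "\n")
})

setMethod("show", "FieldEdges", function(object) {
  cat(sprintf("FieldEdges (mm): L %.2f  R %.2f  G %.2f  T %.2f  (%d+%d leaf crossings)\n",
              object@L, object@R, object@G, object@T,
              length(object@perLeafL), length(object@perLeafR)))
})

setMethod("show", "MisalignmentFit", function(object) {
  cat(sprintf("MisalignmentFit: A = %.3f mm (lateral), B = %.3f mm (vertical), residual RMS %.3f mm\n",
              object@A, object@B, object@residualRms))
})

setMethod("show", "ArcMetrics", function(object) {
  cat(sprintf("ArcMetrics: %d angles (%s, collimator %0.0f deg, replicate %d)\n",
              length(object@anglesDeg), object@direction, object@collimator,
              object@replicateId))
  rng <- vapply(object@metrics[.METRIC_COLUMNS],
                function(v) diff(range(v)), numeric(1))
  cat("  ranges (max-min):\n")
  print(round(rng, 3))
  show(object@misalignment)
})

setMethod("show", "MachineModel", function(object) {
  cat(sprintf("MachineModel: SDD0 = %.0f mm, e-marker offset (%.2f, %.2f) mm\n",
              object@sdd0, object@eMarkerOffset[1], object@eMarkerOffset[2]))
  for (s in c(.CURVE_SLOTS_MM, .CURVE_SLOTS_DEG)) {
    cf <- slot(object, s)
    if (length(cf) && any(cf != 0))
      cat(sprintf("  %-12s %s\n", s,
                  paste(sprintf("%s=%.3g", names(cf), cf), collapse = " ")))
  }
  cat(sprintf("  noise: gaussian sd %.3g x plateau, salt fraction %.3g, seed %d\n",
              object@gaussianSd, object@saltFraction, object@seed))
})

setMethod("show", "SummaryReport", function(object) {
  cat("SummaryReport\n-- per-metric ranges --\n")
  print(object@ranges, digits = 3)
  cat("-- tolerance verdicts --\n")
  print(object@verdicts, digits = 3)
})

#' @rdname accessors
#' @export
setGeneric("ranges", function(object, ...) standardGeneric("ranges"))
setMethod("ranges", "SummaryReport", function(object, ...) object@ranges)
#' @rdname accessors
#' @export
setGeneric("verdicts", function(object, ...) standardGeneric("verdicts"))
setMethod("verdicts", "SummaryReport", function(object, ...) object@verdicts)
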