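#' @import methods
NULL

# Coordinate conventions used throughout the package (stated once, here):
#   * Isocentre-plane frame: +X is the cross-plane axis, increasing toward the
#     right (R) field edge; +Y is the in-plane axis, increasing toward the
#     gun (G) side.  All public outputs are in mm at the isocentre plane
#     (except delta-SDD, which is a detector-plane quantity).
#   * Pixel grid: row 1 / column 1 is the top-left pixel; pixel centres sit at
#     integer (row, col) positions; +Y points up the image (decreasing row).
#   * Gantry angles follow IEC 61217 and are normalised to (-180, 180].

.PANEL_FORMATS <- list(aS500 = c(384L, 512L), aS1000 = c(768L, 1024L))

#' BeamImage: one megavoltage portal image with acquisition geometry
#'
#' A single EPID frame together with the metadata the arc analysis needs:
#' gantry and collimator angle, source-to-detector distance (SDD) and the
#' detector-plane pixel spacing.  Pixel intensities are kept as read
#' (dark-field/flood-field correction is assumed applied upstream by the
#' acquisition software).
#'
#' @slot pixels numeric matrix of pixel intensities (rows x columns).
#' @slot gantryAngle gantry angle in degrees, IEC 61217, in (-180, 180].
#' @slot collimatorAngle collimator angle in degrees.
#' @slot sdd source-to-detector distance in mm.
#' @slot pixelSpacing numeric(2), detector-plane (row, column) spacing in mm.
#' @slot mode acquisition mode, \code{"cine"} or \code{"integrated"}.
#' @slot frameIndex ordinal position in the acquisition.
#' @slot beamAxisPx numeric(2), continuous (row, col) pixel coordinates of the
#'   point where the beam axis meets the panel (from DICOM RT Image Position
#'   when present, else the geometric panel centre).
#'
#' @name BeamImage-class
#' @rdname BeamImage-class
#' @exportClass BeamImage
setClass("BeamImage",
  representation(
    pixels = "matrix",
    gantryAngle = "numeric",
    collimatorAngle = "numeric",
    sdd = "numeric",
    pixelSpacing = "numeric",
    mode = "character",
    frameIndex = "integer",
    beamAxisPx = "numeric"
  )
)

setValidity("BeamImage", function(object) {
  msg <- character()
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (row, col) in mm")
  if (length(object@sdd) != 1L || !is.finite(object@sdd) || object@sdd <= 1000)
    msg <- c(msg, "sdd must exceed the source-to-axis distance (1000 mm)")
  if (length(object@gantryAngle) != 1L || !is.finite(object@gantryAngle) ||
      object@gantryAngle <= -180 || object@gantryAngle > 180)
    msg <- c(msg, "gantryAngle must lie in (-180, 180] (IEC 61217)")
  dims <- dim(object@pixels)
  ok <- vapply(.PANEL_FORMATS, function(d) identical(dims, d), logical(1))
  if (!any(ok))
    msg <- c(msg, sprintf(
      "pixel grid %dx%d is not a supported panel format (384x512 or 768x1024)",
      dims[1], dims[2]))
  if (!object@mode %in% c("cine", "integrated"))
    msg <- c(msg, "mode must be 'cine' or 'integrated'")
  if (length(msg)) msg else TRUE
})

#' ArcSeries: an ordered set of portal images covering one gantry arc
#'
#' @slot images list of \linkS4class{BeamImage}, in acquisition order.
#' @slot direction rotation direction, \code{"CW"} or \code{"CCW"}.
#' @slot collimator common collimator setting in degrees (0 or 90).
#' @slot replicateId replicate ordinal (1-3 in a standard test).
#' @slot referenceIndex index of the gantry-zero reference image.
#'
#' @name ArcSeries-class
#' @rdname ArcSeries-class
#' @exportClass ArcSeries
setClass("ArcSeries",
  representation(
    images = "list",
    direction = "character",
    collimator = "numeric",
    replicateId = "integer",
    referenceIndex = "integer"
  )
)

setValidity("ArcSeries", function(object) {
  msg <- character()
  if (!all(vapply(object@images, is, logical(1), "BeamImage")))
    msg <- c(msg, "images must all be BeamImage objects")
  if (!object@direction %in% c("CW", "CCW"))
    msg <- c(msg, "direction must be 'CW' or 'CCW'")
  n <- length(object@images)
  if (length(object@referenceIndex) != 1L || object@referenceIndex < 1L ||
      object@referenceIndex > n)
    msg <- c(msg, "referenceIndex out of range")
  if (n) {
    modes <- vapply(object@images, function(im) im@mode, character(1))
    if (length(unique(modes)) > 1L)
      msg <- c(msg, "all images must share the acquisition mode")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomGeometry: the five ball-bearing phantom and field configuration
#'
#' Describes the QA phantom: four ball bearings (a, b, c, d) rigidly mounted
#' on the gantry head around the field, and one (e) fixed at the nominal
#' isocentre, plus the nominal MLC-defined aperture.  The \code{pairing}
#' list fixes which marker pairs feed each deformation metric (the roll/tilt
#' pairing is configurable because published formulations disagree with the
#' rectangular layout; the default uses the geometrically meaningful pairs).
#'
#' @slot bbDiameter physical ball-bearing diameter in mm (4.8).
#' @slot markerLayout 5 x 2 matrix of nominal isocentre-plane (x, y) positions
#'   with rownames \code{a, b, c, d, e}.  Default: a = gun-left, b = gun-right,
#'   c = target-left, d = target-right at (+-50, +-50); e at the origin.
#' @slot fieldSize numeric(2), nominal aperture (width, height) at the
#'   isocentre plane in mm (180 x 180).
#' @slot pairing named list of marker pairs per metric; see
#'   \code{\link{defaultPhantomGeometry}}.
#' @slot markerMagnification named numeric, projection magnification of each
#'   ball's shadow onto the detector (head-mounted markers sit closer to the
#'   source than the isocentre marker, so their shadows are larger).
#' @slot rankFilterRank rank used by the 2 x 2 rank filter in preprocessing:
#'   4 (maximum, the default) or 1 (minimum).
#'
#' @name PhantomGeometry-class
#' @rdname PhantomGeometry-class
#' @exportClass PhantomGeometry
setClass("PhantomGeometry",
  representation(
    bbDiameter = "numeric",
    markerLayout = "matrix",
    fieldSize = "numeric",
    pairing = "list",
    markerMagnification = "numeric",
    rankFilterRank = "integer"
  )
)

setValidity("PhantomGeometry", function(object) {
  msg <- character()
  lay <- object@markerLayout
  if (!identical(dim(lay), c(5L, 2L)) ||
      !identical(rownames(lay), c("a", "b", "c", "d", "e")))
    msg <- c(msg, "markerLayout must be 5x2 with rownames a, b, c, d, e")
  else {
    head4 <- lay[c("a", "b", "c", "d"), , drop = FALSE]
    d <- as.matrix(stats::dist(head4))
    if (any(d[upper.tri(d)] < 1e-6))
      msg <- c(msg, "head markers a-d must form a non-degenerate quadrilateral")
    pr <- object@pairing
    sep <- function(p) sqrt(sum((lay[p[1], ] - lay[p[2], ])^2))
    pairs <- c(pr$skew, pr$skewAlt, unlist(pr$sdd), pr$tiltG, pr$tiltT,
               pr$tiltL, pr$tiltR)
    if (length(pairs)) {
      ok <- TRUE
      for (nm in list(pr$skew, pr$tiltG, pr$tiltT, pr$tiltL, pr$tiltR))
        if (length(nm) == 2L && sep(nm) <= 10) ok <- FALSE
      if (!ok) msg <- c(msg, "metric marker pairs must be separated by > 10 mm")
    }
    if (any(abs(lay["e", ]) > 1e-9))
      msg <- c(msg, "marker e nominal position must be the origin")
  }
  if (object@bbDiameter <= 0) msg <- c(msg, "bbDiameter must be positive")
  if (!object@rankFilterRank %in% c(1L, 4L))
    msg <- c(msg, "rankFilterRank must be 1 (minimum) or 4 (maximum)")
  if (length(msg)) msg else TRUE
})

#' MarkerSet: sub-pixel ball-bearing positions for one image
#'
#' @slot positions 5 x 2 matrix (columns x, y; rownames a-e) of marker centres
#'   in isocentre-plane mm.
#' @slot scores per-marker detection quality in [0, 1].
#'
#' @name MarkerSet-class
#' @rdname MarkerSet-class
#' @exportClass MarkerSet
setClass("MarkerSet",
  representation(positions = "matrix", scores = "numeric")
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  if (!identical(dim(object@positions), c(5L, 2L)) ||
      !identical(rownames(object@positions), c("a", "b", "c", "d", "e")))
    msg <- c(msg, "positions must be 5x2 with rownames a, b, c, d, e")
  if (any(!is.finite(object@positions)))
    msg <- c(msg, "marker positions must be finite")
  if (length(object@scores) != 5L || any(object@scores < 0 | object@scores > 1))
    msg <- c(msg, "scores must be five values in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FieldEdges: MLC aperture edge positions for one image
#'
#' @slot L,R cross-plane positions (isocentre-plane mm) of the left and right
#'   leaf-bank edges, each the mean of the per-leaf 50\% crossings.
#' @slot G,T in-plane positions of the gun- and target-side edges.
#' @slot perLeafL,perLeafR individual leaf-row 50\% crossings contributing to
#'   L and R.
#'
#' @name FieldEdges-class
#' @rdname FieldEdges-class
#' @exportClass FieldEdges
setClass("FieldEdges",
  representation(L = "numeric", R = "numeric", G = "numeric", T = "numeric",
                 perLeafL = "numeric", perLeafR = "numeric")
)

setValidity("FieldEdges", function(object) {
  msg <- character()
  if (!(object@R > object@L)) msg <- c(msg, "R edge must exceed L edge")
  if (object@T == object@G) msg <- c(msg, "T and G edges must differ")
  if (length(msg)) msg else TRUE
})

#' MisalignmentFit: setup-misalignment amplitudes of the isocentre marker
#'
#' A ball bearing placed slightly off the true isocentre (or lasers slightly
#' off) traces a simple periodic path on the imager as the gantry rotates: a
#' lateral offset contributes A*cos(theta) to its cross-plane position and a
#' vertical offset contributes B*sin(theta) in-plane.  These amplitudes are
#' fitted over the arc and removed before the EPID sag is reported.
#'
#' @slot A lateral (cross-plane) amplitude in mm.
#' @slot B vertical-projection (in-plane) amplitude in mm.
#' @slot residualRms root-mean-square fit residual in mm (this is the part of
#'   the e-marker motion attributed to genuine EPID sag).
#'
#' @name MisalignmentFit-class
#' @rdname MisalignmentFit-class
#' @exportClass MisalignmentFit
setClass("MisalignmentFit",
  representation(A = "numeric", B = "numeric", residualRms = "numeric")
)

setValidity("MisalignmentFit", function(object) {
  if (abs(object@A) >= 10 || abs(object@B) >= 10)
    return("misalignment amplitudes must be below 10 mm (setup errors are small)")
  TRUE
})

#' ArcMetrics: per-angle mechanical deformation metrics for one arc
#'
#' Angle-indexed series of every deformation metric the method extracts from
#' one arc delivery, all relative to the gantry-zero reference image: EPID sag
#' (cross-plane/in-plane, mm), gantry sag (mm), change in source-to-detector
#' distance (detector-plane mm), EPID/collimator skewness (degrees), EPID tilt
#' (roll/pitch, degrees), and MLC carriage sag toward the left, right, gun and
#' target directions (mm).
#'
#' @slot anglesDeg gantry angles of the series, IEC degrees.
#' @slot metrics data.frame with one row per angle and columns
#'   \code{epid_sag_x, epid_sag_y, gantry_sag_x, gantry_sag_y, delta_sdd,
#'   skew_deg, tilt_x_deg, tilt_y_deg, mlc_sag_L, mlc_sag_R, mlc_sag_G,
#'   mlc_sag_T}.
#' @slot misalignment the \linkS4class{MisalignmentFit} removed from the
#'   e-marker trajectory.
#' @slot referenceIndex row index of the reference angle.
#' @slot direction,collimator,replicateId acquisition descriptors.
#'
#' @name ArcMetrics-class
#' @rdname ArcMetrics-class
#' @exportClass ArcMetrics
setClass("ArcMetrics",
  representation(
    anglesDeg = "numeric",
    metrics = "data.frame",
    misalignment = "MisalignmentFit",
    referenceIndex = "integer",
    direction = "character",
    collimator = "numeric",
    replicateId = "integer"
  )
)

.METRIC_COLUMNS <- c("epid_sag_x", "epid_sag_y", "gantry_sag_x", "gantry_sag_y",
                     "delta_sdd", "skew_deg", "tilt_x_deg", "tilt_y_deg",
                     "mlc_sag_L", "mlc_sag_R", "mlc_sag_G", "mlc_sag_T")

setValidity("ArcMetrics", function(object) {
  msg <- character()
  if (!all(.METRIC_COLUMNS %in% names(object@metrics)))
    msg <- c(msg, "metrics must contain all standard metric columns")
  if (nrow(object@metrics) != length(object@anglesDeg))
    msg <- c(msg, "metrics rows must match anglesDeg")
  if (any(!is.finite(as.matrix(object@metrics[.METRIC_COLUMNS]))))
    msg <- c(msg, "all per-angle metric values must be finite")
  i <- object@referenceIndex
  if (i < 1L || i > length(object@anglesDeg))
    msg <- c(msg, "referenceIndex out of range")
  else if (abs(object@metrics$delta_sdd[i]) > 1e-9 ||
           abs(object@metrics$skew_deg[i]) > 1e-9)
    msg <- c(msg, "delta_sdd and skew must be exactly 0 at the reference angle")
  if (length(msg)) msg else TRUE
})

#' MachineModel: parametric machine-deformation model for the simulator
#'
#' Ground truth driving the forward simulator.  Each deformation is a smooth
#' periodic function of gantry angle, parameterised as a low-order harmonic
#' series with coefficients named \code{sin1, sin2, sin3, cos1, cos2, cos3}
#' plus an optional \code{step} (a discontinuity at zero gantry angle, a
#' feature seen on real machines).  Cosine terms are evaluated as
#' \code{cos(k*theta) - 1} and the step as \code{1(theta < 0)}, so every curve
#' is exactly zero at the gantry-zero reference -- deformations are defined,
#' like the measurements, relative to the reference configuration.
#'
#' Identifiability: a \code{cos1} term in the cross-plane EPID sag is
#' indistinguishable from the lateral isocentre-marker offset A (and
#' \code{sin1} in the in-plane sag from B); those harmonics are reserved for
#' \code{eMarkerOffset} and rejected by the validity method.
#'
#' @slot sdd0 nominal source-to-detector distance in mm.
#' @slot epidSagX,epidSagY EPID sag curves (mm).
#' @slot gantrySagX,gantrySagY gantry sag curves (mm).
#' @slot sddVariation change in SDD (detector-plane mm).
#' @slot skew EPID/collimator skewness curve (degrees).
#' @slot tiltX,tiltY EPID roll and pitch curves (degrees).
#' @slot carriageL,carriageR,carriageG,carriageT MLC carriage sag curves (mm),
#'   defined as the marker-to-edge distance change each direction's metric
#'   reports.
#' @slot eMarkerOffset numeric(2): (lateral, vertical) displacement of ball
#'   bearing e from the true isocentre, in mm; generates the A cos / B sin
#'   signature.
#' @slot gaussianSd Gaussian pixel noise, as a fraction of the open-field
#'   plateau.
#' @slot saltFraction fraction of pixels replaced by bright noise spikes.
#' @slot seed base random seed for image noise.
#'
#' @name MachineModel-class
#' @rdname MachineModel-class
#' @exportClass MachineModel
setClass("MachineModel",
  representation(
    sdd0 = "numeric",
    epidSagX = "numeric", epidSagY = "numeric",
    gantrySagX = "numeric", gantrySagY = "numeric",
    sddVariation = "numeric",
    skew = "numeric",
    tiltX = "numeric", tiltY = "numeric",
    carriageL = "numeric", carriageR = "numeric",
    carriageG = "numeric", carriageT = "numeric",
    eMarkerOffset = "numeric",
    gaussianSd = "numeric",
    saltFraction = "numeric",
    seed = "integer"
  )
)

.CURVE_SLOTS_MM <- c("epidSagX", "epidSagY", "gantrySagX", "gantrySagY",
                     "sddVariation", "carriageL", "carriageR", "carriageG",
                     "carriageT")
.CURVE_SLOTS_DEG <- c("skew", "tiltX", "tiltY")
.CURVE_TERMS <- c("sin1", "sin2", "sin3", "cos1", "cos2", "cos3", "step")

setValidity("MachineModel", function(object) {
  msg <- character()
  for (s in c(.CURVE_SLOTS_MM, .CURVE_SLOTS_DEG)) {
    cf <- slot(object, s)
    if (length(cf) && (is.null(names(cf)) || !all(names(cf) %in% .CURVE_TERMS)))
      msg <- c(msg, sprintf("%s: coefficients must be named among %s",
                            s, paste(.CURVE_TERMS, collapse = ", ")))
    if (any(!is.finite(cf))) msg <- c(msg, sprintf("%s: non-finite coefficient", s))
    lim <- if (s %in% .CURVE_SLOTS_MM) 10 else 1   # mm or degrees
    if (length(cf) && sum(abs(cf)) > lim)
      msg <- c(msg, sprintf("%s: amplitudes exceed the documented physical range", s))
  }
  if (!is.na(match("cos1", names(object@epidSagX))) &&
      object@epidSagX[["cos1"]] != 0)
    msg <- c(msg, paste("epidSagX must not contain a cos1 term: it is",
                        "indistinguishable from the lateral e-marker offset A"))
  if (!is.na(match("sin1", names(object@epidSagY))) &&
      object@epidSagY[["sin1"]] != 0)
    msg <- c(msg, paste("epidSagY must not contain a sin1 term: it is",
                        "indistinguishable from the vertical e-marker offset B"))
  if (length(object@eMarkerOffset) != 2L || any(!is.finite(object@eMarkerOffset)))
    msg <- c(msg, "eMarkerOffset must be two finite values (lateral, vertical) mm")
  if (object@sdd0 <= 1000) msg <- c(msg, "sdd0 must exceed 1000 mm")
  if (object@gaussianSd < 0 || object@saltFraction < 0 || object@saltFraction > 0.05)
    msg <- c(msg, "noise parameters out of range")
  if (length(msg)) msg else TRUE
})

#' AcquisitionPlan: gantry angles and conditions of one simulated arc
#'
#' @slot mode \code{"cine"} (continuous acquisition, ~4 degrees per image on a
#'   full arc) or \code{"integrated"} (one image per static irradiation, e.g.
#'   10-degree steps giving 37 images over a full rotation).
#' @slot stepDeg angular step between images, degrees.
#' @slot direction \code{"CW"} or \code{"CCW"}.
#' @slot collimator collimator angle, 0 or 90 degrees.
#' @slot anglesDeg optional explicit angle list (acquisition order, native
#'   0-360 scale); when empty, a full rotation is generated from
#'   \code{stepDeg}.
#'
#' @name AcquisitionPlan-class
#' @rdname AcquisitionPlan-class
#' @exportClass AcquisitionPlan
setClass("AcquisitionPlan",
  representation(mode = "character", stepDeg = "numeric",
                 direction = "character", collimator = "numeric",
                 anglesDeg = "numeric")
)

setValidity("AcquisitionPlan", function(object) {
  msg <- character()
  if (!object@mode %in% c("cine", "integrated"))
    msg <- c(msg, "mode must be 'cine' or 'integrated'")
  if (!object@direction %in% c("CW", "CCW"))
    msg <- c(msg, "direction must be 'CW' or 'CCW'")
  if (!length(object@anglesDeg) && (!is.finite(object@stepDeg) ||
                                    object@stepDeg <= 0))
    msg <- c(msg, "stepDeg must be positive")
  if (length(object@anglesDeg) && length(object@anglesDeg) < 3L)
    msg <- c(msg, "an explicit schedule needs at least 3 angles")
  if (length(msg)) msg else TRUE
})

#' ToleranceConfig: TG-142 style mechanical tolerances
#'
#' Default thresholds follow the non-stereotactic values of the AAPM TG-142
#' report: 2 mm EPID positional deviation, 1 mm gantry sag, 5 mm SDD change
#' and 1 mm MLC positional deviation.  The 0.3 mm value is the published
#' recommendation for systematic MLC leaf-position errors and is reported as
#' informational only.
#'
#' @slot epidSagMm,gantrySagMm,sddChangeMm,mlcPositionMm thresholds in mm.
#' @slot mlcSystematicNoteMm informational systematic-error level in mm.
#'
#' @name ToleranceConfig-class
#' @rdname ToleranceConfig-class
#' @exportClass ToleranceConfig
setClass("ToleranceConfig",
  representation(epidSagMm = "numeric", gantrySagMm = "numeric",
                 sddChangeMm = "numeric", mlcPositionMm = "numeric",
                 mlcSystematicNoteMm = "numeric")
)

setValidity("ToleranceConfig", function(object) {
  v <- c(object@epidSagMm, object@gantrySagMm, object@sddChangeMm,
         object@mlcPositionMm, object@mlcSystematicNoteMm)
  if (any(!is.finite(v)) || any(v <= 0)) "all thresholds must be positive" else TRUE
})

#' SummaryReport: summary statistics and tolerance verdicts for arc metrics
#'
#' @slot ranges data.frame of per-metric range (max - min), extrema and their
#'   angles, mean, and maximum absolute value.
#' @slot verdicts data.frame of per-criterion pass/fail with margins.
#' @slot tolerances the \linkS4class{ToleranceConfig} used.
#'
#' @name SummaryReport-class
#' @rdname SummaryReport-class
#' @exportClass SummaryReport
setClass("SummaryReport",
  representation(ranges = "data.frame", verdicts = "data.frame",
                 tolerances = "ToleranceConfig")
)
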