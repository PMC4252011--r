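#' @include AllClasses.R
NULL

#' Construct a BeamImage
#'
#' @param pixels numeric matrix of intensities (rows x columns).
#' @param gantryAngle gantry angle in degrees (any convention; normalised to
#'   IEC (-180, 180]).
#' @param collimatorAngle collimator angle in degrees.
#' @param sdd source-to-detector distance in mm.
#' @param pixelSpacing numeric(2), (row, col) detector-plane spacing in mm.
#' @param mode \code{"cine"} or \code{"integrated"}.
#' @param frameIndex acquisition ordinal.
#' @param beamAxisPx continuous (row, col) pixel coordinates of the beam axis
#'   on the panel; defaults to the geometric centre.
#' @return a \linkS4class{BeamImage}.
#' @export
#' @examples
#' px <- matrix(100, 384, 512)
#' BeamImage(px, gantryAngle = 359, sdd = 1500)
BeamImage <- function(pixels, gantryAngle = 0, collimatorAngle = 0,
                      sdd = 1500, pixelSpacing = c(0.784, 0.784),
                      mode = "cine", frameIndex = 1L, beamAxisPx = NULL) {
  if (is.null(beamAxisPx))
    beamAxisPx <- c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2)
  new("BeamImage", pixels = pixels,
      gantryAngle = normalizeGantryAngle(gantryAngle),
      collimatorAngle = as.numeric(collimatorAngle), sdd = as.numeric(sdd),
      pixelSpacing = as.numeric(pixelSpacing), mode = mode,
      frameIndex = as.integer(frameIndex), beamAxisPx = as.numeric(beamAxisPx))
}

#' Default five ball-bearing phantom geometry
#'
#' The standard layout: four 4.8 mm tungsten-carbide ball bearings mounted on
#' the gantry head projecting to (+-50, +-50) mm at the isocentre plane
#' (a = gun-left, b = gun-right, c = target-left, d = target-right) around an
#' 18 x 18 cm2 MLC-defined field, and a fifth ball bearing (e) at the nominal
#' isocentre.
#'
#' Marker pairing defaults (configurable): the SDD change compares the
#' left-side pair (a, c) against the right-side pair (b, d); skewness uses
#' (a, b) with (c, d) as the cross-check pair; pitch compares the gun pair
#' (a, b) with the target pair (c, d); roll compares the left pair (a, c)
#' with the right pair (b, d).
#'
#' @param bbDiameter ball diameter, mm.
#' @param halfWidth,halfHeight half the marker spacing at the isocentre plane,
#'   mm.
#' @param fieldSize nominal aperture (width, height) at isocentre, mm.
#' @param headMagnification projection magnification of the head-mounted
#'   ball shadows (they sit about 600 mm from the source, so at SDD 1500 their
#'   shadows are magnified 2.5x; the isocentre ball is magnified SDD/1000).
#' @param isoMagnification projection magnification of ball e.
#' @param rankFilterRank 4 (2x2 maximum, default) or 1 (minimum).
#' @return a \linkS4class{PhantomGeometry}.
#' @export
#' @examples
#' geom <- defaultPhantomGeometry()
#' geom
defaultPhantomGeometry <- function(bbDiameter = 4.8, halfWidth = 50,
                                   halfHeight = 50, fieldSize = c(180, 180),
                                   headMagnification = 2.5,
                                   isoMagnification = 1.5,
                                   rankFilterRank = 4L) {
  layout <- rbind(
    a = c(-halfWidth,  halfHeight),
    b = c( halfWidth,  halfHeight),
    c = c(-halfWidth, -halfHeight),
    d = c( halfWidth, -halfHeight),
    e = c(0, 0))
  colnames(layout) <- c("x", "y")
  pairing <- list(
    sdd = list(neg = c("a", "c"), pos = c("b", "d")),
    skew = c("a", "b"), skewAlt = c("c", "d"),
    tiltG = c("a", "b"), tiltT = c("c", "d"),
    tiltL = c("a", "c"), tiltR = c("b", "d"))
  mag <- c(a = headMagnification, b = headMagnification,
           c = headMagnification, d = headMagnification,
           e = isoMagnification)
  new("PhantomGeometry", bbDiameter = bbDiameter, markerLayout = layout,
      fieldSize = as.numeric(fieldSize), pairing = pairing,
      markerMagnification = mag, rankFilterRank = as.integer(rankFilterRank))
}

setMethod("show", "PhantomGeometry", function(object) {
  cat(sprintf("PhantomGeometry: %.1f mm ball bearings, %g x %g mm field\n",
              object@bbDiameter, object@fieldSize[1], object@fieldSize[2]))
  print(object@markerLayout)
})

#' Construct a MarkerSet
#'
#' @param positions 5 x 2 matrix (x, y isocentre-plane mm), rows a-e.
#' @param scores per-marker detection quality in [0, 1].
#' @return a \linkS4class{MarkerSet}.
#' @export
MarkerSet <- function(positions, scores = rep(1, 5)) {
  positions <- as.matrix(positions)
  rownames(positions) <- c("a", "b", "c", "d", "e")
  colnames(positions) <- c("x", "y")
  new("MarkerSet", positions = positions, scores = as.numeric(scores))
}

#' Construct a FieldEdges object
#'
#' @param L,R,G,T edge positions in isocentre-plane mm.
#' @param perLeafL,perLeafR per-leaf 50\% crossings (default: the bank edge).
#' @return a \linkS4class{FieldEdges}.
#' @export
FieldEdges <- function(L, R, G, T, perLeafL = L, perLeafR = R) {
  new("FieldEdges", L = as.numeric(L), R = as.numeric(R), G = as.numeric(G),
      T = as.numeric(T), perLeafL = as.numeric(perLeafL),
      perLeafR = as.numeric(perLeafR))
}

#' Construct a machine-deformation model
#'
#' Each deformation curve is given as a named numeric vector of harmonic
#' coefficients (\code{sin1..sin3}, \code{cos1..cos3}, \code{step}); see
#' \linkS4class{MachineModel} for the evaluation convention (every curve is 0
#' at gantry zero).  All arguments default to zero deformation.
#'
#' @param sdd0 nominal SDD, mm.
#' @param epidSagX,epidSagY,gantrySagX,gantrySagY,sddVariation,skew,tiltX,tiltY
#'   deformation curves (mm, or degrees for skew/tilt).
#' @param carriageL,carriageR,carriageG,carriageT MLC carriage sag curves, mm.
#' @param eMarkerOffset numeric(2), (lateral, vertical) isocentre-marker
#'   offset, mm.
#' @param gaussianSd Gaussian pixel noise as a fraction of the open-field
#'   plateau.
#' @param saltFraction fraction of pixels hit by bright noise spikes.
#' @param seed base random seed for rendering noise.
#' @return a \linkS4class{MachineModel}.
#' @export
#' @examples
#' m <- MachineModel(skew = c(cos1 = -0.075))   # 0.15 degree skew range
#' m
MachineModel <- function(sdd0 = 1500,
                         epidSagX = numeric(), epidSagY = numeric(),
                         gantrySagX = numeric(), gantrySagY = numeric(),
                         sddVariation = numeric(), skew = numeric(),
                         tiltX = numeric(), tiltY = numeric(),
                         carriageL = numeric(), carriageR = numeric(),
                         carriageG = numeric(), carriageT = numeric(),
                         eMarkerOffset = c(0, 0),
                         gaussianSd = 0.01, saltFraction = 0.002,
                         seed = 1L) {
  new("MachineModel", sdd0 = sdd0,
      epidSagX = epidSagX, epidSagY = epidSagY,
      gantrySagX = gantrySagX, gantrySagY = gantrySagY,
      sddVariation = sddVariation, skew = skew, tiltX = tiltX, tiltY = tiltY,
      carriageL = carriageL, carriageR = carriageR, carriageG = carriageG,
      carriageT = carriageT, eMarkerOffset = as.numeric(eMarkerOffset),
      gaussianSd = gaussianSd, saltFraction = saltFraction,
      seed = as.integer(seed))
}

#' Reference machine-deformation model used for validation
#'
#' Deformation amplitudes emulate the behaviour reported for clinical Varian
#' machines: in-plane EPID sag range 1.0 mm and cross-plane 0.17 mm; gantry
#' sag ranges 0.70 mm (in-plane) and 0.42 mm (cross-plane); SDD variation up
#' to 1.7 mm; skewness range 0.15 degrees; pitch up to 0.10 and roll up to
#' 0.02 degrees; MLC carriage sag ranges 0.82/0.68 mm left/right (extremal
#' near gantry -90/+90 where gravity acts along the leaf travel) and
#' 0.34/0.32 mm gun/target; isocentre-marker setup offset (0.8, -0.5) mm.
#' In-plane (gravity-symmetric) deformations are cosine-type, cross-plane
#' ones sine-type.
#'
#' @param eMarkerOffset setup offset of ball bearing e, mm.
#' @param gaussianSd,saltFraction,seed noise settings (see
#'   \code{\link{MachineModel}}).
#' @return a \linkS4class{MachineModel}.
#' @export
#' @examples
#' defaultMachineModel()
defaultMachineModel <- function(eMarkerOffset = c(0.8, -0.5),
                                gaussianSd = 0.01, saltFraction = 0.002,
                                seed = 1L) {
  MachineModel(
    sdd0 = 1500,
    epidSagX = c(sin1 = 0.085),          # range 0.17 mm
    epidSagY = c(cos1 = -0.5),           # range 1.00 mm
    gantrySagX = c(sin1 = 0.21),         # range 0.42 mm
    gantrySagY = c(cos1 = -0.35),        # range 0.70 mm
    sddVariation = c(cos1 = -0.85),      # max 1.70 mm
    skew = c(cos1 = -0.075),             # range 0.15 deg
    tiltX = c(sin1 = 0.01),              # range 0.02 deg
    tiltY = c(cos1 = -0.05),             # range 0.10 deg
    carriageL = c(sin1 = -0.41),         # max at gantry -90, range 0.82 mm
    carriageR = c(sin1 = 0.34),          # min at gantry -90, range 0.68 mm
    carriageG = c(cos1 = -0.17),         # range 0.34 mm
    carriageT = c(cos1 = 0.16),          # range 0.32 mm
    eMarkerOffset = eMarkerOffset,
    gaussianSd = gaussianSd, saltFraction = saltFraction, seed = seed)
}

#' Construct an acquisition plan
#'
#' @param mode \code{"integrated"} (default 10-degree steps, 37 images per
#'   rotation) or \code{"cine"} (default 4-degree steps, 91 images).
#' @param stepDeg angular step in degrees; defaults to 10 (integrated) or 4
#'   (cine).
#' @param direction \code{"CW"} or \code{"CCW"}.
#' @param collimator collimator angle (0 or 90).
#' @param anglesDeg optional explicit schedule (native 0-360 scale, in
#'   acquisition order); overrides \code{stepDeg}.
#' @return an \linkS4class{AcquisitionPlan}.
#' @export
#' @examples
#' acquisitionSchedule(AcquisitionPlan("integrated"))   # 37 angles
AcquisitionPlan <- function(mode = c("integrated", "cine"), stepDeg = NULL,
                            direction = "CW", collimator = 0,
                            anglesDeg = numeric()) {
  mode <- match.arg(mode)
  if (is.null(stepDeg)) stepDeg <- if (mode == "integrated") 10 else 4
  new("AcquisitionPlan", mode = mode, stepDeg = as.numeric(stepDeg),
      direction = direction, collimator = as.numeric(collimator),
      anglesDeg = as.numeric(anglesDeg))
}

#' TG-142 style tolerance configuration
#'
#' @param epidSagMm EPID positional tolerance (non-stereotactic default 2 mm).
#' @param gantrySagMm gantry sag tolerance (1 mm).
#' @param sddChangeMm SDD change tolerance (5 mm).
#' @param mlcPositionMm MLC positional tolerance (1 mm).
#' @param mlcSystematicNoteMm informational systematic leaf-position level
#'   (0.3 mm).
#' @return a \linkS4class{ToleranceConfig}.
#' @export
ToleranceConfig <- function(epidSagMm = 2, gantrySagMm = 1, sddChangeMm = 5,
                            mlcPositionMm = 1, mlcSystematicNoteMm = 0.3) {
  new("ToleranceConfig", epidSagMm = epidSagMm, gantrySagMm = gantrySagMm,
      sddChangeMm = sddChangeMm, mlcPositionMm = mlcPositionMm,
      mlcSystematicNoteMm = mlcSystematicNoteMm)
}
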