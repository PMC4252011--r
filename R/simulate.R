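# Forward simulation of arc acquisitions of the five ball-bearing phantom.

#' Evaluate a deformation curve at gantry angles
#'
#' Harmonic coefficients are evaluated as \code{sin(k theta)} for
#' \code{sin1..sin3}, \code{cos(k theta) - 1} for \code{cos1..cos3}, and an
#' indicator \code{theta < 0} for \code{step} (a discontinuity at gantry
#' zero), so every curve is exactly 0 at the gantry-zero reference.
#'
#' @param coef named numeric vector of coefficients (may be empty).
#' @param thetaDeg gantry angles in degrees.
#' @return numeric vector of curve values.
#' @export
evalDeformation <- function(coef, thetaDeg) {
  th <- .deg2rad(thetaDeg)
  out <- numeric(length(th))
  for (nm in names(coef)) {
    out <- out + if (nm == "step") {
      coef[[nm]] * (normalizeGantryAngle(thetaDeg) < 0)
    } else {
      k <- as.integer(substr(nm, 4, 4))
      if (substr(nm, 1, 3) == "sin") coef[[nm]] * sin(k * th)
      else coef[[nm]] * (cos(k * th) - 1)
    }
  }
  out
}

#' Gantry-angle schedule of an acquisition plan
#'
#' Integrated mode steps over a full rotation including both endpoints
#' (0, s, ..., 360: 37 images for 10-degree steps); cine mode generates one
#' angle per configured angular increment the same way (91 images for the
#' ~4-degree spacing of a 360 MU cine arc).  CCW plans run the schedule in
#' reverse.  Angles are returned on the native 0-360 scale in acquisition
#' order.
#'
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @return numeric vector of gantry angles in acquisition order.
#' @export
#' @examples
#' length(acquisitionSchedule(AcquisitionPlan("integrated")))  # 37
#' length(acquisitionSchedule(AcquisitionPlan("cine")))        # 91
acquisitionSchedule <- function(plan) {
  ang <- if (length(plan@anglesDeg)) plan@anglesDeg
         else {
           if (plan@stepDeg <= 0) .err("inputError", "step must be positive")
           seq(0, 360, by = plan@stepDeg)
         }
  if (plan@direction == "CCW") ang <- rev(ang)
  ang
}

# rectangular layout half-extents; the analytic projection assumes the
# symmetric default layout
.layoutHalf <- function(geometry) {
  lay <- geometry@markerLayout
  w <- (lay["b", "x"] - lay["a", "x"]) / 2
  h <- (lay["a", "y"] - lay["c", "y"]) / 2
  rect <- abs(lay["a", "x"] + w) < 1e-9 && abs(lay["d", "x"] - w) < 1e-9 &&
          abs(lay["b", "y"] - h) < 1e-9 && abs(lay["d", "y"] + h) < 1e-9 &&
          abs(lay["c", "x"] + w) < 1e-9
  if (!rect || w <= 0 || h <= 0)
    .err("geometryError",
         "analytic projection requires the rectangular symmetric layout")
  c(w = w, h = h)
}

#' Project the phantom through a deformed machine at one gantry angle
#'
#' Computes the noiseless apparent isocentre-plane positions of the five ball
#' bearings and the four field edges under the machine model: head markers
#' carry the gantry-plus-EPID sag common mode, the pair separations scale
#' with the SDD change (differentially for tilt), pair lines rotate with
#' skew, marker e carries the EPID sag plus the setup-offset signature
#' (A cos / B sin), and edges carry the common mode plus the carriage sag.
#' The construction is the exact inverse of the analysis equations: running
#' the per-angle metrics on these positions returns the model curves to
#' numerical precision.
#'
#' @param model a \linkS4class{MachineModel}.
#' @param thetaDeg one gantry angle, degrees.
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @return list with elements \code{markers} (\linkS4class{MarkerSet}) and
#'   \code{edges} (\linkS4class{FieldEdges}).
#' @export
projectMarkers <- function(model, thetaDeg, geometry = defaultPhantomGeometry()) {
  half <- .layoutHalf(geometry)
  w <- half[["w"]]; h <- half[["h"]]
  sdd0 <- model@sdd0
  ev <- function(s) evalDeformation(slot(model, s), thetaDeg)

  sx <- ev("epidSagX"); sy <- ev("epidSagY")
  gx <- ev("gantrySagX"); gy <- ev("gantrySagY")
  dSdd <- ev("sddVariation")
  psi <- .deg2rad(ev("skew"))
  phiX <- .deg2rad(ev("tiltX")); phiY <- .deg2rad(ev("tiltY"))
  cL <- ev("carriageL"); cR <- ev("carriageR")
  cG <- ev("carriageG"); cT <- ev("carriageT")

  m <- 1 + dSdd / sdd0
  dG <- tan(phiY) * 2 * h * m / 2; dT <- -dG        # pitch: gun vs target
  dL <- tan(phiX) * (-2 * w * m) / 2; dR <- -dL     # roll: left vs right
  uG <- w * (m + dG / sdd0); uT <- w * (m + dT / sdd0)
  mL <- 1 + (dSdd + dL) / sdd0; mR <- 1 + (dSdd + dR) / sdd0

  cx <- gx + sx; cy <- gy + sy                       # common mode
  tpsi <- tan(psi)
  t0 <- cy - uG * tpsi + h * (mL + mR) / 2
  pos <- rbind(
    a = c(cx - uG, t0),
    b = c(cx + uG, t0 + 2 * uG * tpsi),
    c = c(cx - uT, t0 - 2 * h * mL),
    d = c(cx + uT, t0 + 2 * uG * tpsi - 2 * h * mR),
    e = c(model@eMarkerOffset[1] * cos(.deg2rad(thetaDeg)) + sx,
          model@eMarkerOffset[2] * sin(.deg2rad(thetaDeg)) + sy))
  colnames(pos) <- c("x", "y")

  wf <- geometry@fieldSize[1] / 2; hf <- geometry@fieldSize[2] / 2
  edges <- FieldEdges(L = -wf + cx - cL, R = wf + cx + cR,
                      G = hf + cy - cG, T = -hf + cy + cT)
  list(markers = MarkerSet(pos), edges = edges)
}

#' Ground-truth metric curves of a machine model
#'
#' The per-angle values every metric should recover from a (noiseless)
#' acquisition under the model, plus the injected misalignment amplitudes as
#' attributes \code{A} and \code{B}.
#'
#' @param model a \linkS4class{MachineModel}.
#' @param anglesDeg gantry angles, degrees.
#' @return data.frame with \code{gantry_angle_deg} and the twelve metric
#'   columns.
#' @export
groundTruthMetrics <- function(model, anglesDeg) {
  ev <- function(s) evalDeformation(slot(model, s), anglesDeg)
  out <- data.frame(
    gantry_angle_deg = normalizeGantryAngle(anglesDeg),
    epid_sag_x = ev("epidSagX"), epid_sag_y = ev("epidSagY"),
    gantry_sag_x = ev("gantrySagX"), gantry_sag_y = ev("gantrySagY"),
    delta_sdd = ev("sddVariation"), skew_deg = ev("skew"),
    tilt_x_deg = ev("tiltX"), tilt_y_deg = ev("tiltY"),
    mlc_sag_L = ev("carriageL"), mlc_sag_R = ev("carriageR"),
    mlc_sag_G = ev("carriageG"), mlc_sag_T = ev("carriageT"))
  attr(out, "A") <- model@eMarkerOffset[1]
  attr(out, "B") <- model@eMarkerOffset[2]
  out
}

#' Simulate a full arc acquisition
#'
#' Generates one portal image per scheduled gantry angle under the machine
#' model (optionally written as DICOM RT Image files) together with the
#' ground-truth metric table.  The random seed is derived from the model seed
#' and the replicate id, so a repeated call is bit-identical.
#'
#' @param model a \linkS4class{MachineModel}.
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @param dir output directory for DICOM files and \code{truth.csv}; NULL
#'   (default) keeps the series in memory only.
#' @param panel \code{"aS1000"} (1024 x 768, 0.392 mm pitch; default) or
#'   \code{"aS500"} (512 x 384, 0.784 mm).
#' @param replicateId replicate ordinal; offsets the noise seed so replicates
#'   share the truth but not the noise.
#' @return list with \code{series} (an \linkS4class{ArcSeries}),
#'   \code{truth} (data.frame), and \code{files} (character vector of DICOM
#'   paths, empty when \code{dir} is NULL).
#' @export
simulateArc <- function(model, plan, geometry = defaultPhantomGeometry(),
                        dir = NULL, panel = c("aS1000", "aS500"),
                        replicateId = 1L) {
  panel <- match.arg(panel)
  angles <- acquisitionSchedule(plan)
  truth <- groundTruthMetrics(model, angles)

  seed <- (model@seed * 1009L + as.integer(replicateId) * 131L) %% 2147483647L
  set.seed(seed)
  images <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    pr <- projectMarkers(model, angles[i], geometry)
    images[[i]] <- renderBeamImage(pr$markers, pr$edges, geometry,
                                   sdd0 = model@sdd0, panel = panel,
                                   gantryAngle = angles[i],
                                   collimatorAngle = plan@collimator,
                                   mode = plan@mode, frameIndex = i,
                                   gaussianSd = model@gaussianSd,
                                   saltFraction = model@saltFraction)
  }

  files <- character()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, sprintf("arc_%s_col%02d_rep%d_%03d.dcm",
                                    plan@direction, plan@collimator,
                                    replicateId, seq_along(angles)))
    for (i in seq_along(images)) writeBeamImage(images[[i]], files[i])
    tr <- truth
    tr$misalignment_A <- attr(truth, "A")
    tr$misalignment_B <- attr(truth, "B")
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }

  series <- new("ArcSeries", images = images, direction = plan@direction,
                collimator = plan@collimator,
                replicateId = as.integer(replicateId),
                referenceIndex = which.min(abs(normalizeGantryAngle(angles))))
  list(series = series, truth = truth, files = files)
}
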