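# Per-angle mechanical deformation metrics, all relative to the gantry-zero
# reference image.

# coerce a list of MarkerSet (or an N x 5 x 2 array) to an array
.markerArray <- function(markers) {
  if (is.array(markers) && length(dim(markers)) == 3L) return(markers)
  arr <- array(NA_real_, c(length(markers), 5, 2),
               dimnames = list(NULL, c("a", "b", "c", "d", "e"), c("x", "y")))
  for (i in seq_along(markers)) arr[i, , ] <- markerPositions(markers[[i]])
  arr
}

.checkCoverage <- function(anglesDeg, minN = 8L, minSpanDeg = 270) {
  native <- anglesDeg %% 360
  if (length(anglesDeg) < minN || diff(range(native)) < minSpanDeg)
    .err("coverageError",
         "need >= %d angles spanning >= %.0f deg (got %d over %.0f deg)",
         minN, minSpanDeg, length(anglesDeg), diff(range(native)))
}

#' Fit the isocentre-marker misalignment amplitudes
#'
#' The displacement of ball bearing e relative to the reference image is
#' regressed on the misalignment basis: \code{cos(theta) - 1} for the
#' cross-plane axis (lateral offset A) and \code{sin(theta)} for the in-plane
#' axis (vertical offset B), by ordinary least squares.  The basis is zero at
#' gantry zero, so the reference residual vanishes and genuine EPID sag that
#' is orthogonal to the basis is untouched.
#'
#' @param anglesDeg gantry angles (IEC degrees); at least 8 spanning at least
#'   270 degrees.
#' @param ePositions N x 2 matrix of e-marker positions (isocentre-plane mm).
#' @param referenceIndex index of the gantry-zero reference (default: the
#'   angle nearest zero).
#' @return a \linkS4class{MisalignmentFit}.
#' @export
#' @examples
#' th <- seq(0, 350, by = 10)
#' e <- cbind(1.0 * cos(th * pi / 180), 0)   # pure 1 mm lateral offset
#' fitMisalignment(th, e)                    # A = 1, B = 0, residual 0
fitMisalignment <- function(anglesDeg, ePositions,
                            referenceIndex = which.min(abs(normalizeGantryAngle(anglesDeg)))) {
  .checkCoverage(anglesDeg)
  th <- .deg2rad(anglesDeg)
  d <- sweep(as.matrix(ePositions), 2, as.matrix(ePositions)[referenceIndex, ])
  u <- cos(th) - 1
  v <- sin(th)
  A <- sum(u * d[, 1]) / sum(u^2)
  B <- sum(v * d[, 2]) / sum(v^2)
  res <- c(d[, 1] - A * u, d[, 2] - B * v)
  new("MisalignmentFit", A = A, B = B, residualRms = .rms(res))
}

#' EPID sag from the isocentre-marker trajectory
#'
#' The apparent displacement of ball bearing e, corrected for the fitted
#' setup-misalignment signature, is the EPID sag.  With the default
#' \code{anchor = "reference"} the correction terms are evaluated as
#' \code{A (cos(theta) - 1)} and \code{B sin(theta)} so the sag is exactly
#' zero at the gantry-zero reference; \code{anchor = "literal"} uses
#' \code{A cos(theta)} unanchored (in which case the value at gantry zero
#' is -A).
#'
#' @inheritParams fitMisalignment
#' @param fit a \linkS4class{MisalignmentFit} computed on the same series.
#' @param anchor \code{"reference"} (default) or \code{"literal"}.
#' @return N x 2 matrix with columns \code{x}, \code{y} (isocentre-plane mm).
#' @export
epidSag <- function(anglesDeg, ePositions, fit = NULL,
                    referenceIndex = which.min(abs(normalizeGantryAngle(anglesDeg))),
                    anchor = c("reference", "literal")) {
  anchor <- match.arg(anchor)
  if (is.null(fit))
    fit <- fitMisalignment(anglesDeg, ePositions, referenceIndex)
  th <- .deg2rad(anglesDeg)
  d <- sweep(as.matrix(ePositions), 2, as.matrix(ePositions)[referenceIndex, ])
  off <- if (anchor == "reference") c(1, 0) else c(0, 0)
  cbind(x = d[, 1] - fit@A * (cos(th) - off[1]),
        y = d[, 2] - fit@B * (sin(th) - off[2]))
}

#' Gantry sag from the head-marker centroid
#'
#' The mean position of the four head-mounted markers moves with both the
#' gantry head and the imaging panel; subtracting the EPID sag at each angle
#' isolates the gantry sag.  Values are relative to the reference image.
#'
#' @param markers list of \linkS4class{MarkerSet} (or N x 5 x 2 array).
#' @param epidSagXY N x 2 matrix from \code{\link{epidSag}}.
#' @param referenceIndex index of the reference image.
#' @return N x 2 matrix with columns \code{x}, \code{y} (mm).
#' @export
gantrySag <- function(markers, epidSagXY, referenceIndex) {
  arr <- .markerArray(markers)
  mx <- rowMeans(arr[, c("a", "b", "c", "d"), "x"])
  my <- rowMeans(arr[, c("a", "b", "c", "d"), "y"])
  cbind(x = (mx - mx[referenceIndex]) - epidSagXY[, 1],
        y = (my - my[referenceIndex]) - epidSagXY[, 2])
}

#' Change in source-to-detector distance
#'
#' The cross-plane separation between the left-side marker pair and the
#' right-side pair magnifies with the true SDD; its ratio to the reference
#' separation gives the SDD change.  Reported at the detector plane (this is
#' the one quantity not scaled to the isocentre).  Positive values mean the
#' detector moved away from the source.
#'
#' @inheritParams gantrySag
#' @param sdd0 source-to-detector distance at the reference angle, mm.
#' @param pairing list with elements \code{neg} and \code{pos}: marker names
#'   averaged on each side (defaults to (a, c) vs (b, d)).
#' @return numeric vector of delta-SDD, detector-plane mm.
#' @export
sddChange <- function(markers, sdd0, referenceIndex,
                      pairing = list(neg = c("a", "c"), pos = c("b", "d"))) {
  arr <- .markerArray(markers)
  sep <- rowMeans(arr[, pairing$neg, "x", drop = FALSE]) -
         rowMeans(arr[, pairing$pos, "x", drop = FALSE])
  if (abs(sep[referenceIndex]) < 10)
    .err("geometryError",
         "reference pair separation %.2f mm too small for SDD estimation",
         sep[referenceIndex])
  sdd0 * (sep / sep[referenceIndex] - 1)
}

#' EPID/collimator skewness
#'
#' In-plane rotation of the imaged marker pattern: the change, relative to the
#' reference image, of the angle of the line through a head-marker pair.
#'
#' @inheritParams sddChange
#' @param pair two marker names forming the skew pair; (a, b) by default,
#'   (c, d) as the rigid-body cross-check.
#' @return numeric vector of skew in degrees.
#' @export
skewness <- function(markers, referenceIndex, pair = c("a", "b")) {
  arr <- .markerArray(markers)
  dx <- arr[, pair[2], "x"] - arr[, pair[1], "x"]
  dy <- arr[, pair[2], "y"] - arr[, pair[1], "y"]
  if (abs(dx[referenceIndex]) < 10 ||
      abs(dx[referenceIndex]) < 2 * abs(dy[referenceIndex]))
    .err("geometryError",
         "skew pair (%s,%s) is not separated predominantly in x",
         pair[1], pair[2])
  .rad2deg(atan(dy / dx) - atan(dy[referenceIndex] / dx[referenceIndex]))
}

#' EPID tilt (pitch and roll)
#'
#' Out-of-plane rotation of the panel is detected as differential
#' magnification between marker pairs on opposite sides of the field.  Pitch
#' (in-plane tilt): the apparent SDD change estimated from the gun-side
#' pair's cross-plane separation minus the target-side pair's, over the
#' in-plane distance between the pair midpoints.  Roll (cross-plane tilt):
#' the analogue with the left/right pairs and in-plane separations.  A common
#' SDD change affects both pairs equally and cancels.
#'
#' @inheritParams sddChange
#' @param pairing named list of pairs \code{tiltG}, \code{tiltT} (pitch) and
#'   \code{tiltL}, \code{tiltR} (roll); defaults to the rectangular-layout
#'   pairs (a,b)/(c,d) and (a,c)/(b,d).
#' @return N x 2 matrix with columns \code{tilt_x_deg} (roll),
#'   \code{tilt_y_deg} (pitch).
#' @export
epidTilt <- function(markers, sdd0, referenceIndex,
                     pairing = list(tiltG = c("a", "b"), tiltT = c("c", "d"),
                                    tiltL = c("a", "c"), tiltR = c("b", "d"))) {
  arr <- .markerArray(markers)
  sep <- function(pair, axis) arr[, pair[1], axis] - arr[, pair[2], axis]
  mid <- function(pair, axis) (arr[, pair[1], axis] + arr[, pair[2], axis]) / 2

  dsdd <- function(pair, axis) {
    s <- sep(pair, axis)
    if (abs(s[referenceIndex]) < 10)
      .err("geometryError", "tilt pair (%s,%s) separation too small",
           pair[1], pair[2])
    sdd0 * (s / s[referenceIndex] - 1)
  }
  # pitch: gun vs target pairs, x separations, in-plane midpoint distance
  numY <- dsdd(pairing$tiltG, "x") - dsdd(pairing$tiltT, "x")
  denY <- mid(pairing$tiltG, "y") - mid(pairing$tiltT, "y")
  # roll: left vs right pairs, y separations, cross-plane midpoint distance
  numX <- dsdd(pairing$tiltL, "y") - dsdd(pairing$tiltR, "y")
  denX <- mid(pairing$tiltL, "x") - mid(pairing$tiltR, "x")
  if (any(abs(denY) < 10) || any(abs(denX) < 10))
    .err("geometryError", "degenerate midpoint distance in tilt estimation")
  cbind(tilt_x_deg = .rad2deg(atan(numX / denX)),
        tilt_y_deg = .rad2deg(atan(numY / denY)))
}

#' MLC carriage sag
#'
#' Distance between the head-marker centroid and each bank edge: left and gun
#' sags are centroid minus edge, right and target sags edge minus centroid
#' (so that for every direction a larger value means the bank moved away from
#' the head markers, i.e. sagged outward on that side).  Each series is
#' re-referenced so its value at the gantry-zero image is 0.
#'
#' @inheritParams gantrySag
#' @param edges list of \linkS4class{FieldEdges}, one per angle.
#' @return N x 4 matrix with columns \code{L}, \code{R}, \code{G}, \code{T}
#'   (isocentre-plane mm).
#' @export
mlcCarriageSag <- function(markers, edges, referenceIndex) {
  arr <- .markerArray(markers)
  mx <- rowMeans(arr[, c("a", "b", "c", "d"), "x"])
  my <- rowMeans(arr[, c("a", "b", "c", "d"), "y"])
  e <- t(vapply(edges, fieldEdges, numeric(4)))
  raw <- cbind(L = mx - e[, "L"], R = e[, "R"] - mx,
               G = my - e[, "G"], T = e[, "T"] - my)
  sweep(raw, 2, raw[referenceIndex, ])
}

#' Compute all deformation metrics for one arc
#'
#' Applies the full set of per-angle metrics to detected marker and edge
#' positions: EPID sag (with misalignment correction), gantry sag, SDD
#' change, skewness, tilt and MLC carriage sag.
#'
#' @param markers list of \linkS4class{MarkerSet} (one per image).
#' @param edges list of \linkS4class{FieldEdges} (one per image).
#' @param anglesDeg gantry angles (IEC degrees).
#' @param sdd0 reference SDD in mm.
#' @param referenceIndex index of the gantry-zero image (default: nearest 0).
#' @param geometry \linkS4class{PhantomGeometry} supplying the metric pairing.
#' @param direction,collimator,replicateId acquisition descriptors stored in
#'   the result.
#' @return an \linkS4class{ArcMetrics}.
#' @export
computeArcMetrics <- function(markers, edges, anglesDeg, sdd0,
                              referenceIndex = which.min(abs(normalizeGantryAngle(anglesDeg))),
                              geometry = defaultPhantomGeometry(),
                              direction = "CW", collimator = 0,
                              replicateId = 1L) {
  arr <- .markerArray(markers)
  eP <- arr[, "e", ]
  fit <- fitMisalignment(anglesDeg, eP, referenceIndex)
  es <- epidSag(anglesDeg, eP, fit, referenceIndex)
  gs <- gantrySag(arr, es, referenceIndex)
  pr <- geometry@pairing
  dsdd <- sddChange(arr, sdd0, referenceIndex, pairing = pr$sdd)
  sk <- skewness(arr, referenceIndex, pair = pr$skew)
  tl <- epidTilt(arr, sdd0, referenceIndex,
                 pairing = pr[c("tiltG", "tiltT", "tiltL", "tiltR")])
  ml <- mlcCarriageSag(arr, edges, referenceIndex)

  metrics <- data.frame(
    epid_sag_x = es[, "x"], epid_sag_y = es[, "y"],
    gantry_sag_x = gs[, "x"], gantry_sag_y = gs[, "y"],
    delta_sdd = dsdd, skew_deg = sk,
    tilt_x_deg = tl[, "tilt_x_deg"], tilt_y_deg = tl[, "tilt_y_deg"],
    mlc_sag_L = ml[, "L"], mlc_sag_R = ml[, "R"],
    mlc_sag_G = ml[, "G"], mlc_sag_T = ml[, "T"])
  new("ArcMetrics", anglesDeg = as.numeric(anglesDeg), metrics = metrics,
      misalignment = fit, referenceIndex = as.integer(referenceIndex),
      direction = direction, collimator = as.numeric(collimator),
      replicateId = as.integer(replicateId))
}

#' Analyse a full arc series of portal images
#'
#' Runs detection (preprocessing, ball-bearing localisation, field-edge
#' extraction) on every image of the series, then computes all deformation
#' metrics.  Images on which detection fails are reported and skipped; the
#' analysis continues as long as at least \code{minUsable} of the images
#' (and the reference image) remain usable, and aborts otherwise.
#'
#' @param series an \linkS4class{ArcSeries}.
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @param minUsable minimum usable fraction of images (default 0.8).
#' @param verbose print per-image detection summaries.
#' @return an \linkS4class{ArcMetrics}.
#' @export
analyzeArcSeries <- function(series, geometry = defaultPhantomGeometry(),
                             minUsable = 0.8, verbose = FALSE) {
  imgs <- beamImages(series)
  n <- length(imgs)
  markers <- vector("list", n)
  edges <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      chain <- .preprocChain(imgs[[i]], geometry@rankFilterRank)
      m <- .detectMarkersCore(imgs[[i]], chain, geometry)
      e <- .detectEdgesCore(imgs[[i]], chain, geometry, markers = m)
      list(m = m, e = e)
    }, epidArcQAError = function(err) err)
    if (inherits(res, "condition")) {
      warning(sprintf("image %d (gantry %+.1f deg): %s", i,
                      gantryAngle(imgs[[i]]), conditionMessage(res)),
              call. = FALSE)
      next
    }
    markers[[i]] <- res$m; edges[[i]] <- res$e; ok[i] <- TRUE
    if (verbose)
      message(sprintf("image %3d  gantry %+7.1f deg  scores %s", i,
                      gantryAngle(imgs[[i]]),
                      paste(sprintf("%.2f", detectionScores(res$m)),
                            collapse = " ")))
  }
  if (mean(ok) < minUsable)
    .err("detectionError", "only %d of %d images usable (< %.0f%%)",
         sum(ok), n, 100 * minUsable)
  if (!ok[referenceIndex(series)])
    .err("referenceError", "detection failed on the reference image")

  ang <- vapply(imgs, gantryAngle, numeric(1))[ok]
  refIdx <- which.min(abs(ang))
  computeArcMetrics(markers[ok], edges[ok], ang, sdd0 = sdd(imgs[[1]]),
                    referenceIndex = refIdx, geometry = geometry,
                    direction = arcDirection(series),
                    collimator = collimatorAngle(series),
                    replicateId = series@replicateId)
}
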