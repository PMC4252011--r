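#' Convert pixel coordinates to isocentre-plane millimetres
#'
#' Fractional pixel coordinates (pixel centres at integer positions) are
#' converted to detector-plane mm offsets from the beam-axis reference point,
#' then scaled by 1000 / SDD (the source-to-axis distance is 1000 mm) to
#' express them at the isocentre plane.  +x is cross-plane toward the right
#' field edge, +y is in-plane toward the gun (up the image).
#'
#' @param pixelRow,pixelCol numeric vectors of (fractional) pixel coordinates.
#' @param image the \linkS4class{BeamImage} providing spacing, SDD and the
#'   beam-axis reference point.
#' @return a matrix with columns \code{x_mm}, \code{y_mm}.
#' @export
#' @examples
#' im <- BeamImage(matrix(0, 384, 512), sdd = 1500)
#' toIsocentreMM(192.5, 256.5, im)   # beam axis -> (0, 0)
toIsocentreMM <- function(pixelRow, pixelCol, image) {
  sp <- pixelSpacing(image)
  axis <- image@beamAxisPx
  xDet <- (pixelCol - axis[2]) * sp[2]
  yDet <- (axis[1] - pixelRow) * sp[1]
  k <- 1000 / sdd(image)
  cbind(x_mm = xDet * k, y_mm = yDet * k)
}

# inverse of toIsocentreMM, used by the renderer and tests
.isoToPixel <- function(xMm, yMm, image) {
  sp <- pixelSpacing(image)
  axis <- image@beamAxisPx
  k <- sdd(image) / 1000
  cbind(row = axis[1] - yMm * k / sp[1], col = axis[2] + xMm * k / sp[2])
}

#' Load an ordered arc series of portal images
#'
#' Reads a set of portal images (file paths or in-memory
#' \linkS4class{BeamImage} objects), sorts them by acquisition order (frame
#' index), checks consistency, and identifies the gantry-zero reference image:
#' the frame with the smallest absolute gantry angle, which must lie within
#' \code{referenceTolDeg} of zero; ties are broken by acquisition order.
#'
#' @param sources character vector of DICOM file paths, or a list of
#'   \linkS4class{BeamImage} objects.
#' @param direction rotation direction, \code{"CW"} or \code{"CCW"}.
#' @param collimator nominal collimator setting in degrees.
#' @param replicateId replicate ordinal.
#' @param referenceTolDeg maximum |gantry angle| of the reference frame
#'   (default 2 degrees; cine sampling is ~4 degrees per image).
#' @return an \linkS4class{ArcSeries}.
#' @export
loadArcSeries <- function(sources, direction = "CW", collimator = 0,
                          replicateId = 1L, referenceTolDeg = 2) {
  images <- if (is.character(sources)) lapply(sources, readBeamImage)
            else sources
  if (length(images) < 3L)
    .err("inputError", "an arc series needs at least 3 images, got %d",
         length(images))
  images <- images[order(vapply(images, frameIndex, integer(1)))]

  coll <- vapply(images, collimatorAngle, numeric(1))
  if (diff(range(coll)) > 0.5)
    .err("consistencyError",
         "mixed collimator angles in one series (%.1f to %.1f deg)",
         min(coll), max(coll))

  ang <- vapply(images, gantryAngle, numeric(1))
  native <- ang %% 360
  if (diff(range(native)) <= 180)
    .err("coverageError", "arc span %.0f deg; need more than 180 deg",
         diff(range(native)))

  refIdx <- which.min(abs(ang))        # which.min takes the first on ties
  if (abs(ang[refIdx]) > referenceTolDeg)
    .err("referenceError",
         "no frame within %.1f deg of gantry zero (closest: %.1f deg)",
         referenceTolDeg, ang[refIdx])

  new("ArcSeries", images = images, direction = direction,
      collimator = as.numeric(collimator), replicateId = as.integer(replicateId),
      referenceIndex = as.integer(refIdx))
}
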