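# Rasterisation of one synthetic portal image.

.PANEL_SPECS <- list(
  aS500 = list(nrow = 384L, ncol = 512L, spacing = c(0.784, 0.784)),
  aS1000 = list(nrow = 768L, ncol = 1024L, spacing = c(0.392, 0.392)))

#' Render a synthetic portal image from ground-truth geometry
#'
#' Rasterises the open-field plateau, the blocked-region baseline, linear
#' penumbrae at the four MLC edges, and disc-shaped ball-bearing attenuation
#' shadows with area-weighted (anti-aliased) coverage, then adds Gaussian
#' pixel noise and bright salt spikes using the current RNG state.  Ball
#' shadows are pure attenuation discs -- sufficient for geometric validation,
#' with no scatter or energy modelling.
#'
#' @param markers ground-truth \linkS4class{MarkerSet} (apparent
#'   isocentre-plane mm).
#' @param edges ground-truth \linkS4class{FieldEdges}.
#' @param geometry the \linkS4class{PhantomGeometry} (ball diameter and
#'   per-marker magnification).
#' @param sdd0 nominal SDD written to the image metadata, mm.
#' @param panel \code{"aS1000"} (default) or \code{"aS500"}, or a list with
#'   \code{nrow}, \code{ncol}, \code{spacing}.
#' @param gantryAngle,collimatorAngle,mode,frameIndex image metadata.
#' @param gaussianSd Gaussian noise, fraction of the plateau.
#' @param saltFraction fraction of pixels replaced by bright spikes.
#' @param plateau open-field level in counts.
#' @param baselineFrac blocked-region transmission as a fraction of plateau.
#' @param penumbraMm linear penumbra width at the detector plane, mm.
#' @param bbDepth shadow depth of a ball bearing as a fraction of the local
#'   intensity.
#' @return a \linkS4class{BeamImage}.
#' @export
renderBeamImage <- function(markers, edges, geometry = defaultPhantomGeometry(),
                            sdd0 = 1500, panel = "aS1000",
                            gantryAngle = 0, collimatorAngle = 0,
                            mode = "cine", frameIndex = 1L,
                            gaussianSd = 0, saltFraction = 0,
                            plateau = 8000, baselineFrac = 0.05,
                            penumbraMm = 2.5, bbDepth = 0.6) {
  spec <- if (is.character(panel)) .PANEL_SPECS[[match.arg(panel, names(.PANEL_SPECS))]]
          else panel
  nr <- spec$nrow; nc <- spec$ncol; sp <- spec$spacing
  axis <- c((nr + 1) / 2, (nc + 1) / 2)
  k <- sdd0 / 1000

  xs <- (seq_len(nc) - axis[2]) * sp[2]       # detector mm, + right
  ys <- (axis[1] - seq_len(nr)) * sp[1]       # detector mm, + up (gun)

  e <- fieldEdges(edges) * k
  ramp <- function(v, lo, hi) pmin(pmax((v - lo) / (hi - lo), 0), 1)
  p2 <- penumbraMm / 2
  tx <- pmin(ramp(xs, e[["L"]] - p2, e[["L"]] + p2),
             ramp(-xs, -e[["R"]] - p2, -e[["R"]] + p2))
  ty <- pmin(ramp(ys, e[["T"]] - p2, e[["T"]] + p2),
             ramp(-ys, -e[["G"]] - p2, -e[["G"]] + p2))
  base <- baselineFrac * plateau
  img <- base + (plateau - base) * outer(ty, tx)

  pos <- markerPositions(markers)
  for (r in seq_len(nrow(pos))) {
    mag <- geometry@markerMagnification[[rownames(pos)[r]]]
    rad <- geometry@bbDiameter / 2 * mag      # detector mm
    xm <- pos[r, "x"] * k; ym <- pos[r, "y"] * k
    ci <- which(abs(xs - xm) <= rad + 2 * sp[2])
    ri <- which(abs(ys - ym) <= rad + 2 * sp[1])
    if (!length(ci) || !length(ri))
      .err("renderError", "marker %s projects outside the panel",
           rownames(pos)[r])
    d <- sqrt(outer((ys[ri] - ym)^2, (xs[ci] - xm)^2, "+"))
    cov <- pmin(pmax((rad - d) / mean(sp) + 0.5, 0), 1)
    img[ri, ci] <- img[ri, ci] * (1 - bbDepth * cov)
  }

  if (gaussianSd > 0)
    img <- img + stats::rnorm(length(img), sd = gaussianSd * plateau)
  if (saltFraction > 0) {
    nSalt <- round(saltFraction * length(img))
    if (nSalt > 0) {
      idx <- sample.int(length(img), nSalt)
      img[idx] <- plateau * (1.3 + 0.7 * stats::runif(nSalt))
    }
  }
  img <- pmin(pmax(round(img), 0), 65535)

  BeamImage(img, gantryAngle = gantryAngle, collimatorAngle = collimatorAngle,
            sdd = sdd0, pixelSpacing = sp, mode = mode,
            frameIndex = frameIndex, beamAxisPx = axis)
}
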