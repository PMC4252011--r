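# Sub-pixel localisation of ball-bearing shadows and MLC field edges.

# iso-plane coordinates of pixel rows/columns, optionally phase-shifted by
# half a pixel (the 2x2 rank filter aligns its output to the window's
# top-left corner, so post-filter features live at index + 0.5)
.gridIso <- function(image, phasePx = 0) {
  sp <- pixelSpacing(image)
  axis <- image@beamAxisPx
  k <- 1000 / sdd(image)
  list(
    x = ((seq_len(ncol(pixelData(image))) + phasePx) - axis[2]) * sp[2] * k,
    y = (axis[1] - (seq_len(nrow(pixelData(image))) + phasePx)) * sp[1] * k,
    isoPerPxX = sp[2] * k, isoPerPxY = sp[1] * k)
}

# open-field plateau and blocked-region baseline (median estimates)
.fieldLevels <- function(px, grid, geometry) {
  w2 <- geometry@fieldSize[1] / 2; h2 <- geometry@fieldSize[2] / 2
  inX <- abs(grid$x) < 0.5 * w2; inY <- abs(grid$y) < 0.5 * h2
  plateau <- stats::median(px[inY, inX])
  outX <- abs(grid$x) > w2 + 8; outY <- abs(grid$y) > h2 + 8
  outside <- px[outY, , drop = FALSE]
  if (any(outX)) outside <- c(outside, px[!outY, outX])
  baseline <- stats::median(unlist(outside))
  if (!(plateau > baseline))
    .err("detectionError", "cannot separate open-field plateau from baseline")
  list(plateau = plateau, baseline = baseline)
}

.discKernel <- function(radiusPx) {
  h <- ceiling(radiusPx)
  g <- expand.grid(r = -h:h, c = -h:h)
  k <- matrix(as.numeric(sqrt(g$r^2 + g$c^2) <= radiusPx), 2 * h + 1, 2 * h + 1)
  k / sum(k)
}

# both preprocessing stages, computed once per image
.preprocChain <- function(image, rank) {
  smoothed <- conservativeSmooth(pixelData(image))
  list(smoothed = smoothed, filtered = rankFilter2x2(smoothed, rank = rank))
}

# refine a blob centre on the conservatively smoothed image by regressing
# pixel radius on the edge-coverage value: with area-weighted rasterisation a
# transition pixel's intensity is (locally) linear in its signed distance to
# the shadow edge, so for pixels in the transition band
#   d_i = r0 + dCol cos(phi_i) + dRow sin(phi_i) + w (0.5 - s_i),
# where s_i is the normalised shadow depth -- an interpolation-free linear
# least-squares problem in centre offset, radius and edge width, with an
# outlier-rejection pass against residual noise spikes.
.ringRegression <- function(inv, ctr, radiusPx, iterations = 3L) {
  hw <- ceiling(radiusPx + 4)
  i0 <- round(ctr[1]); j0 <- round(ctr[2])
  ri <- max(1, i0 - hw):min(nrow(inv), i0 + hw)
  ci <- max(1, j0 - hw):min(ncol(inv), j0 + hw)
  v <- as.vector(inv[ri, ci])
  pr <- rep(ri, times = length(ci)); pc <- rep(ci, each = length(ri))
  for (it in seq_len(iterations)) {
    dr <- pr - ctr[1]; dc <- pc - ctr[2]
    d <- sqrt(dr^2 + dc^2)
    innerLvl <- stats::median(v[d < radiusPx - 1.5])
    outerLvl <- stats::median(v[d > radiusPx + 1.5 & d < radiusPx + 3.5])
    depth <- innerLvl - outerLvl
    if (!is.finite(depth) || depth <= 0) return(ctr)
    s <- (v - outerLvl) / depth
    tr <- which(s > 0.15 & s < 0.85 & d > radiusPx - 3 & d < radiusPx + 3)
    if (length(tr) < 12L) return(ctr)
    phi <- atan2(dr[tr], dc[tr])
    X <- cbind(1, cos(phi), sin(phi), 0.5 - s[tr])
    y <- d[tr]
    keep <- rep(TRUE, length(y))
    beta <- NULL
    for (pass in 1:2) {
      beta <- tryCatch(solve(crossprod(X[keep, , drop = FALSE]),
                             crossprod(X[keep, , drop = FALSE], y[keep])),
                       error = function(e) NULL)
      if (is.null(beta)) return(ctr)
      res <- y - as.vector(X %*% beta)
      tol <- max(3 * stats::mad(res[keep]), 0.25)
      keep <- abs(res) <= tol
      if (sum(keep) < 12L) return(ctr)
    }
    ctr <- ctr + pmin(pmax(c(beta[3], beta[2]), -1), 1)
  }
  ctr
}

.detectMarkersCore <- function(image, chain, geometry) {
  px <- chain$filtered
  phase <- 0.5
  grid <- .gridIso(image, phasePx = phase)
  lev <- .fieldLevels(px, grid, geometry)
  depth <- lev$plateau - lev$baseline

  k <- sdd(image) / 1000
  spDet <- pixelSpacing(image)
  radiusPx <- geometry@bbDiameter / 2 * geometry@markerMagnification /
    mean(spDet)                                  # per-role projected radius

  # candidate search restricted to the aperture interior
  inv <- lev$plateau - px
  w2 <- geometry@fieldSize[1] / 2; h2 <- geometry@fieldSize[2] / 2
  interior <- outer(abs(grid$y) < h2 - 12, abs(grid$x) < w2 - 12)
  inv[!interior] <- 0

  score <- EBImage::filter2(inv, .discKernel(min(radiusPx)))
  mask <- score >= 0.4 * max(score)
  lab <- EBImage::bwlabel(mask + 0)
  nlab <- max(lab)
  if (nlab < 5L)
    .err("detectionError", "found %d ball-bearing candidates, need 5", nlab)
  idx <- which(mask, arr.ind = TRUE)
  labs <- lab[mask]
  cand <- t(vapply(seq_len(nlab), function(l) {
    sel <- labs == l
    w <- score[idx[sel, , drop = FALSE]]
    c(row = sum(idx[sel, 1] * w) / sum(w),
      col = sum(idx[sel, 2] * w) / sum(w),
      peak = max(w))
  }, numeric(3)))
  cand <- cand[order(-cand[, "peak"]), , drop = FALSE]
  if (nrow(cand) > 10L) cand <- cand[1:10, , drop = FALSE]
  nc <- nrow(cand)
  candIso <- cbind(x = (cand[, "col"] + phase - image@beamAxisPx[2]) * spDet[2] / k,
                   y = (image@beamAxisPx[1] - (cand[, "row"] + phase)) * spDet[1] / k)

  # global translation fit: hypothesis from every candidate/role pairing,
  # keep the translation supported by the most roles
  lay <- geometry@markerLayout
  roleTol <- 15
  best <- NULL; bestSupport <- -1L
  for (i in seq_len(nc)) for (r in 1:5) {
    tr <- candIso[i, ] - lay[r, ]
    d <- vapply(1:5, function(rr) {
      min(sqrt((candIso[, 1] - (lay[rr, 1] + tr[1]))^2 +
               (candIso[, 2] - (lay[rr, 2] + tr[2]))^2))
    }, numeric(1))
    support <- sum(d < roleTol)
    if (support > bestSupport) { bestSupport <- support; best <- tr }
  }
  if (bestSupport < 5L)
    .err("detectionError",
         "only %d of 5 marker roles matched the phantom layout", bestSupport)
  assign <- vapply(1:5, function(rr) {
    d <- sqrt((candIso[, 1] - (lay[rr, 1] + best[1]))^2 +
              (candIso[, 2] - (lay[rr, 2] + best[2]))^2)
    which.min(d)
  }, integer(1))
  if (anyDuplicated(assign))
    .err("assignmentError", "two marker roles map to the same candidate blob")

  # sub-pixel refinement on the conservatively smoothed image (the rank
  # filter would re-sample the edge ring anisotropically); candidate
  # positions shift by the half-pixel filter phase between the two grids
  roles <- rownames(lay)
  pos <- matrix(NA_real_, 5, 2, dimnames = list(roles, c("x", "y")))
  scores <- numeric(5)
  invSmooth <- lev$plateau - chain$smoothed
  for (r in 1:5) {
    start <- cand[assign[r], c("row", "col")] + phase
    ctr <- .ringRegression(invSmooth, start, radiusPx[[roles[r]]])
    pos[r, ] <- c((ctr[2] - image@beamAxisPx[2]) * spDet[2] / k,
                  (image@beamAxisPx[1] - ctr[1]) * spDet[1] / k)
    scores[r] <- min(1, cand[assign[r], "peak"] / (0.5 * depth))
  }

  # sanity: pairwise separations close to the nominal layout
  dNom <- as.matrix(stats::dist(lay))
  dObs <- as.matrix(stats::dist(pos))
  rel <- abs(dObs - dNom) / pmax(dNom, 1)
  if (any(rel[upper.tri(rel)] > 0.25))
    .err("assignmentError",
         "marker separations deviate more than 25%% from the nominal layout")

  MarkerSet(pos, scores)
}

#' Detect the five ball-bearing shadows with sub-pixel precision
#'
#' The image is preprocessed (conservative smoothing, then the 2 x 2 rank
#' filter); matched filtering with a disc kernel of the isocentre ball's
#' projected radius locates candidate shadows on the filtered image; roles
#' a-e are assigned by a global translation fit against the nominal layout;
#' each marker centre is then refined on the conservatively smoothed image by
#' a ring regression of the shadow's 50\% edge band (pixel radius regressed
#' on normalised depth over the transition pixels), which is
#' interpolation-free and approaches the localisation bound.  Positions are
#' returned in isocentre-plane mm.
#'
#' @param image a \linkS4class{BeamImage} (raw; preprocessing is applied
#'   internally).
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @return a \linkS4class{MarkerSet}.
#' @export
detectMarkers <- function(image, geometry) {
  chain <- .preprocChain(image, geometry@rankFilterRank)
  .detectMarkersCore(image, chain, geometry)
}

# 50% crossing of a profile by linear interpolation, searched around a
# nominal position
.halfCrossing <- function(coord, profile, level, nominal, window, rising) {
  sel <- which(abs(coord - nominal) <= window)
  if (length(sel) < 3L) return(NA_real_)
  p <- profile[sel]; x <- coord[sel]
  above <- p >= level
  if (!any(above) || all(above)) return(NA_real_)
  cross <- which(above[-1] != above[-length(above)])
  if (!length(cross)) return(NA_real_)
  # prefer the crossing with the expected direction nearest the nominal edge
  dir <- (p[cross + 1] > p[cross])
  ok <- if (rising) cross[dir] else cross[!dir]
  if (!length(ok)) return(NA_real_)
  mid <- (x[ok] + x[ok + 1]) / 2
  jc <- ok[which.min(abs(mid - nominal))]
  x[jc] + (level - p[jc]) * (x[jc + 1] - x[jc]) / (p[jc + 1] - p[jc])
}

.detectEdgesCore <- function(image, chain, geometry, markers = NULL,
                             leafWidthMm = 5) {
  px <- chain$filtered
  phase <- 0.5
  grid <- .gridIso(image, phasePx = phase)
  lev <- .fieldLevels(px, grid, geometry)
  level <- lev$baseline + 0.5 * (lev$plateau - lev$baseline)

  # rank-filter edge advance: half a pixel toward the dark side (rank 4)
  edgeComp <- if (geometry@rankFilterRank == 4L) 0.5 else -0.5
  compX <- edgeComp * grid$isoPerPxX
  compY <- edgeComp * grid$isoPerPxY

  # mask marker shadows
  if (!is.null(markers)) {
    pos <- markerPositions(markers)
    for (r in seq_len(nrow(pos))) {
      rad <- geometry@bbDiameter *
        geometry@markerMagnification[[rownames(pos)[r]]] * 1000 / sdd(image)
      ri <- which(abs(grid$y - pos[r, "y"]) <= rad)
      ci <- which(abs(grid$x - pos[r, "x"]) <= rad)
      if (length(ri) && length(ci)) px[ri, ci] <- NA
    }
  }

  w2 <- geometry@fieldSize[1] / 2; h2 <- geometry@fieldSize[2] / 2
  window <- 15

  # per-leaf crossings for the left and right banks
  bandEdges <- seq(-h2 + 8, h2 - 8, by = leafWidthMm)
  perLeafL <- perLeafR <- numeric()
  for (b in seq_len(length(bandEdges) - 1L)) {
    rows <- which(grid$y > bandEdges[b] & grid$y <= bandEdges[b + 1])
    if (length(rows) < 2L) next
    prof <- colMeans(px[rows, , drop = FALSE], na.rm = TRUE)
    xl <- .halfCrossing(grid$x, prof, level, -w2, window, rising = TRUE)
    xr <- .halfCrossing(grid$x, prof, level, +w2, window, rising = FALSE)
    if (!is.na(xl)) perLeafL <- c(perLeafL, xl + compX)
    if (!is.na(xr)) perLeafR <- c(perLeafR, xr - compX)
  }
  if (!length(perLeafL))
    .err("edgeError", "no 50%% crossing found for the left bank edge")
  if (!length(perLeafR))
    .err("edgeError", "no 50%% crossing found for the right bank edge")

  # gun/target edges from the central third of the aperture width
  cols <- which(abs(grid$x) <= w2 / 3)
  profY <- rowMeans(px[, cols, drop = FALSE], na.rm = TRUE)
  # grid$y decreases with row index; .halfCrossing needs ordered coords
  ordY <- order(grid$y)
  yG <- .halfCrossing(grid$y[ordY], profY[ordY], level, +h2, window,
                      rising = FALSE)
  yT <- .halfCrossing(grid$y[ordY], profY[ordY], level, -h2, window,
                      rising = TRUE)
  if (is.na(yG)) .err("edgeError", "no 50%% crossing found for the gun edge")
  if (is.na(yT)) .err("edgeError", "no 50%% crossing found for the target edge")
  yG <- yG - compY
  yT <- yT + compY

  L <- mean(perLeafL); R <- mean(perLeafR)
  if (abs((R - L) - geometry@fieldSize[1]) > 0.1 * geometry@fieldSize[1] ||
      abs((yG - yT) - geometry@fieldSize[2]) > 0.1 * geometry@fieldSize[2])
    .err("edgeError", "detected aperture %.1f x %.1f mm deviates >10%% from nominal",
         R - L, yG - yT)

  FieldEdges(L = L, R = R, G = yG, T = yT,
             perLeafL = perLeafL, perLeafR = perLeafR)
}

#' Detect the MLC-defined field edges
#'
#' Left and right bank edges: for each leaf row intersecting the aperture, the
#' 50\%-of-plateau crossing of the cross-plane profile is found by linear
#' interpolation on the preprocessed image; the bank edge is the mean of the
#' per-leaf crossings.  Gun and target edges: 50\% crossings of the in-plane
#' profile averaged over the central third of the aperture width.  Marker
#' footprints are masked before profiles are extracted.  The rank-4 (maximum)
#' filter advances each 50\% crossing half a pixel toward the dark side; the
#' detector compensates by the same amount toward the bright side (sign
#' flipped for rank 1).  All positions are isocentre-plane mm.
#'
#' @param image a \linkS4class{BeamImage} (raw; preprocessing is applied
#'   internally).
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @param markers the \linkS4class{MarkerSet} already detected on this image
#'   (used to mask the shadows); optional.
#' @param leafWidthMm leaf width at the isocentre plane (5 mm for the inner
#'   leaves of a Millennium 120 MLC).
#' @return a \linkS4class{FieldEdges}.
#' @export
detectFieldEdges <- function(image, geometry, markers = NULL,
                             leafWidthMm = 5) {
  chain <- .preprocChain(image, geometry@rankFilterRank)
  .detectEdgesCore(image, chain, geometry, markers, leafWidthMm)
}
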