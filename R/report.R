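# Summary statistics, tolerance verdicts and report writers.

#' Per-metric range summary
#'
#' For every metric series: the range (max - min, the quantity tabulated per
#' machine in routine reporting), the extrema and the gantry angles at which
#' they occur, the mean, and the maximum absolute value.
#'
#' @param metrics an \linkS4class{ArcMetrics}.
#' @return data.frame with one row per metric.
#' @export
rangeSummary <- function(metrics) {
  ang <- anglesDeg(metrics)
  tab <- metricsTable(metrics)[.METRIC_COLUMNS]
  do.call(rbind, lapply(names(tab), function(nm) {
    v <- tab[[nm]]
    data.frame(metric = nm, range = max(v) - min(v), min = min(v),
               max = max(v), angle_min_deg = ang[which.min(v)],
               angle_max_deg = ang[which.max(v)], mean = mean(v),
               max_abs = max(abs(v)))
  }))
}

#' Reproducibility across replicate arcs
#'
#' Sample standard deviation per angle per metric over repeated measurements,
#' and its maximum over angles (the "worst reproducibility" statistic).
#' Angles are matched to the first replicate's grid by nearest neighbour
#' within \code{matchTolDeg}.
#'
#' @param replicates list of at least two \linkS4class{ArcMetrics} sharing
#'   the acquisition plan.
#' @param matchTolDeg maximum angle mismatch when pairing frames, degrees.
#' @return list with \code{perAngle} (data.frame of per-angle SDs) and
#'   \code{maxSd} (named numeric, per metric).
#' @export
reproducibility <- function(replicates, matchTolDeg = 2) {
  if (length(replicates) < 2L)
    .err("inputError", "reproducibility needs at least 2 replicates, got %d",
         length(replicates))
  grid <- anglesDeg(replicates[[1]])
  aligned <- lapply(replicates, function(m) {
    ang <- anglesDeg(m)
    idx <- vapply(grid, function(a) {
      j <- which.min(abs(normalizeGantryAngle(ang - a)))
      if (abs(normalizeGantryAngle(ang[j] - a)) > matchTolDeg)
        .err("inputError",
             "replicates do not share the acquisition plan (no frame near %+.1f deg)",
             a)
      j
    }, integer(1))
    metricsTable(m)[idx, .METRIC_COLUMNS]
  })
  perAngle <- data.frame(gantry_angle_deg = grid)
  maxSd <- numeric()
  for (nm in .METRIC_COLUMNS) {
    mat <- vapply(aligned, function(d) d[[nm]], numeric(length(grid)))
    sdv <- apply(mat, 1, stats::sd)
    perAngle[[nm]] <- sdv
    maxSd[nm] <- max(sdv)
  }
  list(perAngle = perAngle, maxSd = maxSd)
}

#' RMSD between two arc measurements
#'
#' Root-mean-square deviation per metric between two series (e.g. CW vs CCW
#' rotation, or collimator 0 vs 90), after linear interpolation of both onto
#' the union of their angle grids restricted to the common angular range.
#' Series are ordered by the physical IEC gantry angle, so a CCW series pairs
#' correctly with a CW one.
#'
#' @param series1,series2 \linkS4class{ArcMetrics} objects with overlapping
#'   angular coverage of at least \code{minOverlapDeg}.
#' @param minOverlapDeg required common angular span, degrees.
#' @return named numeric vector of RMSDs, one per metric.
#' @export
rmsdCompare <- function(series1, series2, minOverlapDeg = 270) {
  prep <- function(m) {
    a <- normalizeGantryAngle(anglesDeg(m))
    o <- order(a)
    list(ang = a[o], tab = metricsTable(m)[o, .METRIC_COLUMNS])
  }
  s1 <- prep(series1); s2 <- prep(series2)
  lo <- max(min(s1$ang), min(s2$ang))
  hi <- min(max(s1$ang), max(s2$ang))
  if (hi - lo < minOverlapDeg)
    .err("coverageError", "angular overlap %.0f deg < %.0f deg required",
         hi - lo, minOverlapDeg)
  grid <- sort(unique(c(s1$ang, s2$ang)))
  grid <- grid[grid >= lo & grid <= hi]
  out <- numeric()
  for (nm in .METRIC_COLUMNS) {
    v1 <- stats::approx(s1$ang, s1$tab[[nm]], xout = grid, ties = mean)$y
    v2 <- stats::approx(s2$ang, s2$tab[[nm]], xout = grid, ties = mean)$y
    out[nm] <- .rms(v1 - v2)
  }
  out
}

#' TG-142 style tolerance verdicts
#'
#' EPID and gantry sag are judged on the maximum absolute per-angle value
#' (per axis), the SDD change on the maximum absolute delta-SDD, and MLC
#' carriage sag on the range per direction (a carriage offset is a systematic
#' field-edge error).  Skew and tilt have no TG-142 threshold and are
#' reported as informational.  The margin is threshold minus observed value
#' (positive = pass).
#'
#' @param metrics an \linkS4class{ArcMetrics}.
#' @param config a \linkS4class{ToleranceConfig}.
#' @return data.frame with columns metric, quantity, value, threshold,
#'   margin, pass.
#' @export
toleranceCheck <- function(metrics, config = ToleranceConfig()) {
  tab <- metricsTable(metrics)
  rows <- list(
    list("epid_sag_x", "max_abs", max(abs(tab$epid_sag_x)), config@epidSagMm),
    list("epid_sag_y", "max_abs", max(abs(tab$epid_sag_y)), config@epidSagMm),
    list("gantry_sag_x", "max_abs", max(abs(tab$gantry_sag_x)), config@gantrySagMm),
    list("gantry_sag_y", "max_abs", max(abs(tab$gantry_sag_y)), config@gantrySagMm),
    list("delta_sdd", "max_abs", max(abs(tab$delta_sdd)), config@sddChangeMm),
    list("mlc_sag_L", "range", diff(range(tab$mlc_sag_L)), config@mlcPositionMm),
    list("mlc_sag_R", "range", diff(range(tab$mlc_sag_R)), config@mlcPositionMm),
    list("mlc_sag_G", "range", diff(range(tab$mlc_sag_G)), config@mlcPositionMm),
    list("mlc_sag_T", "range", diff(range(tab$mlc_sag_T)), config@mlcPositionMm),
    list("skew_deg", "max_abs", max(abs(tab$skew_deg)), NA_real_),
    list("tilt_x_deg", "max_abs", max(abs(tab$tilt_x_deg)), NA_real_),
    list("tilt_y_deg", "max_abs", max(abs(tab$tilt_y_deg)), NA_real_))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(metric = r[[1]], quantity = r[[2]], value = r[[3]],
               threshold = r[[4]], margin = r[[4]] - r[[3]],
               pass = if (is.na(r[[4]])) NA else r[[3]] <= r[[4]])))
  rownames(out) <- NULL
  out
}

#' Summary report with ranges and tolerance verdicts
#'
#' @param metrics an \linkS4class{ArcMetrics}.
#' @param tolerances a \linkS4class{ToleranceConfig}.
#' @return a \linkS4class{SummaryReport}.
#' @export
summaryReport <- function(metrics, tolerances = ToleranceConfig()) {
  new("SummaryReport", ranges = rangeSummary(metrics),
      verdicts = toleranceCheck(metrics, tolerances), tolerances = tolerances)
}

#' Dosimetric impact of an SDD change
#'
#' A detector displaced along the beam axis magnifies the image by
#' SDD-change / SDD and, by the inverse-square law to first order, changes
#' the measured dose by twice that fraction -- relevant when the EPID is used
#' for absolute dosimetry.
#'
#' @param deltaSddMm change in source-to-detector distance, mm.
#' @param sdd0Mm reference SDD, mm.
#' @return named numeric: \code{magnification_pct}, \code{dose_change_pct}.
#' @export
#' @examples
#' round(magnificationImpact(8.65, 1500), 2)   # 0.58% and 1.15%
magnificationImpact <- function(deltaSddMm, sdd0Mm) {
  mag <- 100 * deltaSddMm / sdd0Mm
  c(magnification_pct = mag, dose_change_pct = 2 * mag)
}

#' Write arc metrics to CSV
#'
#' One row per gantry angle, one column per metric.
#'
#' @param metrics an \linkS4class{ArcMetrics}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMetricsCsv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' Write a summary report as JSON
#'
#' @param report a \linkS4class{SummaryReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportJson <- function(report, path) {
  payload <- list(ranges = ranges(report), verdicts = verdicts(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Debug overlay of detected markers and field edges
#'
#' Renders the portal image with the detected ball-bearing centres and the
#' four field-edge positions drawn on top -- a visual sanity check for
#' detection problems.
#'
#' @param image the \linkS4class{BeamImage}.
#' @param markers a \linkS4class{MarkerSet}.
#' @param edges a \linkS4class{FieldEdges}, optional.
#' @param file optional PNG path; plots to the active device when NULL.
#' @return invisibly, NULL.
#' @export
plotDetectionOverlay <- function(image, markers, edges = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  px <- pixelData(image)
  sp <- pixelSpacing(image); axis <- image@beamAxisPx
  k <- 1000 / sdd(image)
  xs <- (seq_len(ncol(px)) - axis[2]) * sp[2] * k
  ys <- (axis[1] - seq_len(nrow(px))) * sp[1] * k
  graphics::image(xs, rev(ys), t(px[nrow(px):1, ]),
                  col = grDevices::gray.colors(128, 0, 1),
                  xlab = "x (isocentre mm)", ylab = "y (isocentre mm)",
                  main = sprintf("gantry %+.1f deg", gantryAngle(image)),
                  useRaster = TRUE)
  pos <- markerPositions(markers)
  graphics::points(pos[, "x"], pos[, "y"], col = "red", pch = 3, cex = 1.5)
  graphics::text(pos[, "x"], pos[, "y"], rownames(pos), col = "red", pos = 4)
  if (!is.null(edges)) {
    e <- fieldEdges(edges)
    graphics::abline(v = e[c("L", "R")], h = e[c("G", "T")],
                     col = "cyan", lty = 2)
  }
  invisible(NULL)
}

#' Plot arc metric series
#'
#' One panel per metric, gantry angle on the abscissa.
#'
#' @param metrics an \linkS4class{ArcMetrics}.
#' @param which character vector of metric columns (default: all twelve).
#' @param file optional PNG path; plots to the active device when NULL.
#' @return invisibly, NULL.
#' @export
plotArcMetrics <- function(metrics, which = .METRIC_COLUMNS, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 300 * ceiling(length(which) / 3))
    on.exit(grDevices::dev.off())
  }
  ang <- normalizeGantryAngle(anglesDeg(metrics))
  o <- order(ang)
  tab <- metricsTable(metrics)
  op <- graphics::par(mfrow = c(ceiling(length(which) / 3), 3),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (nm in which) {
    unit <- if (grepl("deg$", nm)) "deg" else "mm"
    graphics::plot(ang[o], tab[[nm]][o], type = "l",
                   xlab = "gantry angle (deg)", ylab = unit, main = nm)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(NULL)
}
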