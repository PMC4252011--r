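# Noise-spike removal used before marker/edge detection.

.padReplicate <- function(m, n = 1L) {
  r <- nrow(m); c <- ncol(m)
  ri <- c(rep(1L, n), seq_len(r), rep(r, n))
  ci <- c(rep(1L, n), seq_len(c), rep(c, n))
  m[ri, ci, drop = FALSE]
}

#' Conservative smoothing
#'
#' Each pixel whose value lies outside the [min, max] envelope of its eight
#' neighbours is clamped to the nearer bound; all other pixels are untouched.
#' This removes isolated noise spikes without blurring high spatial
#' frequencies (penumbra, ball-bearing shadows).  Borders are handled by edge
#' replication.
#'
#' @param m numeric matrix.
#' @return a matrix of the same dimensions.
#' @export
#' @examples
#' m <- matrix(1, 5, 5); m[3, 3] <- 100
#' conservativeSmooth(m)[3, 3]   # clamped to 1
conservativeSmooth <- function(m) {
  p <- .padReplicate(m, 1L)
  r <- nrow(m); c <- ncol(m)
  sub <- function(dr, dc) p[(1 + dr):(r + dr), (1 + dc):(c + dc), drop = FALSE]
  nmin <- NULL; nmax <- NULL
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1 && dc == 1) next
    s <- sub(dr, dc)
    nmin <- if (is.null(nmin)) s else pmin(nmin, s)
    nmax <- if (is.null(nmax)) s else pmax(nmax, s)
  }
  pmin(pmax(m, nmin), nmax)
}

#' 2 x 2 rank filter
#'
#' Replaces each pixel by the \code{rank}-th order statistic of the 2 x 2
#' window whose top-left corner it is: rank 4 is the window maximum (the
#' default; suppresses single-pixel dark dropouts, which matters because the
#' ball-bearing shadows are detected as local minima), rank 1 the minimum.
#' The output grid is aligned to the window's top-left corner, so the filter
#' carries a known half-pixel phase shift toward the bottom-right; the
#' measurement code compensates for it (see \code{\link{detectMarkers}}).
#'
#' @param m numeric matrix.
#' @param rank 1 (minimum) or 4 (maximum).
#' @return a matrix of the same dimensions.
#' @export
rankFilter2x2 <- function(m, rank = 4L) {
  if (!rank %in% c(1L, 4L))
    .err("inputError", "2x2 rank filter supports rank 1 or 4, got %s", rank)
  p <- .padReplicate(m, 1L)[-1, -1, drop = FALSE]   # pad bottom/right only
  r <- nrow(m); c <- ncol(m)
  w <- list(p[1:r, 1:c], p[2:(r + 1), 1:c], p[1:r, 2:(c + 1)],
            p[2:(r + 1), 2:(c + 1)])
  if (rank == 4L) pmax(w[[1]], w[[2]], w[[3]], w[[4]])
  else pmin(w[[1]], w[[2]], w[[3]], w[[4]])
}

#' Preprocess a portal image for detection
#'
#' Applies (i) conservative smoothing, removing isolated intensity spikes
#' while preserving detail, then (ii) the 2 x 2 rank filter (rank 4 by
#' default, i.e. window maximum).  Intensities are otherwise preserved.
#'
#' @param image a \linkS4class{BeamImage}.
#' @param rank rank of the 2 x 2 filter (4 or 1).
#' @return a \linkS4class{BeamImage} with filtered pixels and identical
#'   metadata.
#' @export
preprocessImage <- function(image, rank = 4L) {
  px <- rankFilter2x2(conservativeSmooth(pixelData(image)), rank = rank)
  initialize(image, pixels = px)
}
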