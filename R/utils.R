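#' Normalise a gantry angle to the IEC (-180, 180] interval
#'
#' Angles stored on the machine's native 0-360 scale are mapped onto
#' (-180, 180]: 359 becomes -1, 360 becomes 0, 180 stays 180.  The mapping is
#' idempotent and bijective from [0, 360) onto (-180, 180].
#'
#' @param angleDeg numeric vector of angles in degrees.
#' @return numeric vector of angles in (-180, 180].
#' @export
#' @examples
#' normalizeGantryAngle(c(0, 90, 180, 181, 359, 360, -1))
normalizeGantryAngle <- function(angleDeg) {
  a <- angleDeg %% 360           # [0, 360)
  ifelse(a > 180, a - 360, a)
}

# error constructors: condition classes let callers distinguish failure modes
.err <- function(class, fmt, ...) {
  stop(structure(class = c(class, "epidArcQAError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.rms <- function(x) sqrt(mean(x^2))

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi
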