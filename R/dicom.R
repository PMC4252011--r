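# Minimal DICOM RT Image reader/writer (explicit VR little endian).
#
# Scope: exactly the single-frame 16-bit grayscale RT Image files this
# package's simulator writes and clinical Varian portal exports resemble.
# Unknown data elements are skipped; sequences are not supported.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_RTIMAGE <- "1.2.840.10008.5.1.4.1.1.481.1"

# deterministic SOP instance UID from the image metadata: repeated simulation
# runs must produce byte-identical fixtures
.uid <- function(image) {
  sprintf("1.2.826.0.1.3680043.9999.1.%d.%d.%d.%d",
          frameIndex(image),
          round((gantryAngle(image) %% 360) * 100),
          round(collimatorAngle(image)),
          round(sdd(image)))
}

.rawLE <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                     endian = "little")

.evenPad <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2L) r <- c(r, pad)
  r
}

# one explicit-VR data element as raw bytes
.element <- function(group, element, vr, value) {
  tag <- c(.rawLE(group, 2), .rawLE(element, 2))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    body <- value  # raw
    c(tag, charToRaw(vr), as.raw(c(0, 0)), .rawLE(length(body), 4), body)
  } else if (vr == "US") {
    body <- .rawLE(value, 2)
    c(tag, charToRaw(vr), .rawLE(length(body), 2), body)
  } else if (vr == "UL") {
    body <- .rawLE(value, 4)
    c(tag, charToRaw(vr), .rawLE(length(body), 2), body)
  } else {  # string VRs: UI, DS, IS, CS, LO, SH
    body <- .evenPad(as.character(value),
                     pad = if (vr == "UI") as.raw(0) else charToRaw(" "))
    c(tag, charToRaw(vr), .rawLE(length(body), 2), body)
  }
}

.ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

#' Write a BeamImage as a DICOM RT Image file
#'
#' Writes a single-frame 16-bit MONOCHROME2 RT Image (explicit VR little
#' endian) carrying the gantry angle, collimator angle, SDD, pixel spacing,
#' image position and acquisition-mode metadata that
#' \code{\link{readBeamImage}} consumes.  Pixel values are rounded and clamped
#' to [0, 65535].
#'
#' @param image a \linkS4class{BeamImage}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
#' @examples
#' im <- BeamImage(matrix(100, 384, 512), gantryAngle = -1, sdd = 1500)
#' f <- tempfile(fileext = ".dcm")
#' writeBeamImage(im, f)
#' gantryAngle(readBeamImage(f))   # -1
writeBeamImage <- function(image, path) {
  px <- pixelData(image)
  nr <- nrow(px); nc <- ncol(px)
  counts <- as.integer(pmin(pmax(round(t(px)), 0), 65535))  # row-major
  # R writeBin size=2 needs values in signed range; map to -32768..32767
  counts <- ifelse(counts > 32767L, counts - 65536L, counts)
  pixBytes <- writeBin(counts, raw(), size = 2, endian = "little")

  sp <- pixelSpacing(image)
  axis <- image@beamAxisPx
  x0 <- -(axis[2] - 1) * sp[2]          # x of upper-left pixel centre
  y0 <- (axis[1] - 1) * sp[1]           # y of upper-left pixel centre
  storedAngle <- gantryAngle(image) %% 360
  imgType <- paste("ORIGINAL", "PRIMARY", "PORTAL",
                   toupper(acquisitionMode(image)), sep = "\\")
  sopInstance <- .uid(image)

  meta <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .element(0x0002, 0x0002, "UI", .SOP_RTIMAGE),
    .element(0x0002, 0x0003, "UI", sopInstance),
    .element(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.0.1"))
  meta <- c(.element(0x0002, 0x0000, "UL", length(meta)), meta)

  body <- c(
    .element(0x0008, 0x0008, "CS", imgType),
    .element(0x0008, 0x0016, "UI", .SOP_RTIMAGE),
    .element(0x0008, 0x0018, "UI", sopInstance),
    .element(0x0008, 0x0060, "CS", "RTIMAGE"),
    .element(0x0020, 0x0013, "IS", as.character(frameIndex(image))),
    .element(0x0028, 0x0002, "US", 1L),
    .element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .element(0x0028, 0x0010, "US", nr),
    .element(0x0028, 0x0011, "US", nc),
    .element(0x0028, 0x0100, "US", 16L),
    .element(0x0028, 0x0101, "US", 16L),
    .element(0x0028, 0x0102, "US", 15L),
    .element(0x0028, 0x0103, "US", 0L),
    .element(0x3002, 0x0011, "DS", .ds(sp)),
    .element(0x3002, 0x0012, "DS", .ds(c(x0, y0))),
    .element(0x3002, 0x0026, "DS", .ds(sdd(image))),
    .element(0x300A, 0x011E, "DS", .ds(storedAngle)),
    .element(0x300A, 0x0120, "DS", .ds(collimatorAngle(image))),
    .element(0x7FE0, 0x0010, "OW", pixBytes))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# parse all explicit-VR elements of a raw DICOM stream into a named list
.parseDicom <- function(bytes) {
  n <- length(bytes)
  if (n < 132L || rawToChar(bytes[129:132]) != "DICM")
    .err("dicomFormatError", "not a DICOM file (missing DICM magic)")
  pos <- 133L
  out <- list()
  u16 <- function(i) readBin(bytes[i:(i + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(bytes[i:(i + 3L)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      start <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      start <- pos + 8L
    }
    if (len < 0 || start + len - 1L > n)
      .err("dicomFormatError", "truncated DICOM element at tag (%04X,%04X)",
           group, element)
    key <- sprintf("%04X%04X", group, element)
    val <- bytes[start:(start + len - 1L)]
    out[[key]] <- list(vr = vr, bytes = val)
    pos <- start + len
  }
  out
}

.dicomString <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))
}

.dicomNumbers <- function(el) {
  if (is.null(el)) return(NULL)
  if (el$vr == "US")
    return(readBin(el$bytes, "integer", n = length(el$bytes) / 2, size = 2,
                   signed = FALSE, endian = "little"))
  if (el$vr == "UL")
    return(readBin(el$bytes, "integer", n = length(el$bytes) / 4, size = 4,
                   endian = "little"))
  as.numeric(strsplit(.dicomString(el), "\\\\")[[1]])
}

#' Read a DICOM RT Image file into a BeamImage
#'
#' Parses an explicit-VR little-endian RT Image and populates a
#' \linkS4class{BeamImage}: the gantry angle is normalised to IEC
#' (-180, 180], pixel intensities are returned unmodified (dark-field and
#' flood-field correction is assumed already applied by the acquisition
#' software), and the beam-axis reference point on the panel is taken from RT
#' Image Position when present, else the geometric panel centre.
#'
#' @param source path to a DICOM file, or a raw vector holding its bytes.
#' @return a \linkS4class{BeamImage}.
#' @export
readBeamImage <- function(source) {
  bytes <- if (is.raw(source)) source else
    readBin(source, "raw", n = file.info(source)$size)
  els <- .parseDicom(bytes)

  need <- function(key, what) {
    if (is.null(els[[key]]))
      .err("dicomMetadataError", "missing mandatory DICOM tag (%s,%s): %s",
           substr(key, 1, 4), substr(key, 5, 8), what)
    els[[key]]
  }
  rows <- .dicomNumbers(need("00280010", "Rows"))
  cols <- .dicomNumbers(need("00280011", "Columns"))
  spacing <- .dicomNumbers(need("30020011", "ImagePlanePixelSpacing"))
  sid <- .dicomNumbers(need("30020026", "RTImageSID"))
  gantry <- .dicomNumbers(need("300A011E", "GantryAngle"))
  collim <- .dicomNumbers(need("300A0120", "BeamLimitingDeviceAngle"))
  pix <- need("7FE00010", "PixelData")
  if (length(pix$bytes) != 2 * rows * cols)
    .err("dicomFormatError", "pixel data size does not match %dx%d 16-bit grid",
         rows, cols)
  counts <- readBin(pix$bytes, "integer", n = rows * cols, size = 2,
                    signed = FALSE, endian = "little")
  px <- matrix(counts, nrow = rows, ncol = cols, byrow = TRUE)

  imgType <- .dicomString(els[["00080008"]])
  mode <- if (!is.null(imgType) && grepl("INTEGRATED", imgType))
    "integrated" else "cine"
  inst <- .dicomNumbers(els[["00200013"]])
  if (is.null(inst)) inst <- 1

  posEl <- .dicomNumbers(els[["30020012"]])
  if (!is.null(posEl) && length(posEl) == 2) {
    beamAxisPx <- c(1 + posEl[2] / spacing[1], 1 - posEl[1] / spacing[2])
  } else {
    beamAxisPx <- c((rows + 1) / 2, (cols + 1) / 2)
  }

  BeamImage(px, gantryAngle = gantry, collimatorAngle = collim, sdd = sid,
            pixelSpacing = spacing, mode = mode, frameIndex = as.integer(inst),
            beamAxisPx = beamAxisPx)
}
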