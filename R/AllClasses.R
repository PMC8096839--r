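#' @import methods
NULL

#' Spring-sensor calibration parameters
#'
#' Parameters of the linear force-extension model of the flagelliform
#' spring peptide together with the Förster distance of the FRET pair.
#' The model is F = (r - b*n - c) / (a*n), where r is the separation of
#' the two fluorophores obtained from the FRET efficiency via
#' r = R0 * ((1 - E) / E)^(1/6).
#'
#' @slot a compliance per amino acid (nm/pN).
#' @slot b collapsed length per amino acid (nm).
#' @slot n number of amino acids between the fluorophores.
#' @slot c constant linker length (nm); `NA_real_` until calibrated from a
#'   zero-force measurement (see [calibrateLinker()]).
#' @slot R0 Förster distance of the dye pair (nm).
#' @export
setClass("CalibrationParams",
  representation(a = "numeric", b = "numeric", n = "numeric",
                 c = "numeric", R0 = "numeric"),
  prototype(a = 0.0122, b = 0.044, n = 29, c = NA_real_, R0 = 5.1))

setValidity("CalibrationParams", function(object) {
  msg <- character()
  if (length(object@a) != 1 || object@a <= 0) msg <- c(msg, "a must be a single positive number")
  if (length(object@b) != 1 || object@b <= 0) msg <- c(msg, "b must be a single positive number")
  if (length(object@n) != 1 || object@n < 1)  msg <- c(msg, "n must be >= 1")
  if (length(object@R0) != 1 || object@R0 <= 0) msg <- c(msg, "R0 must be a single positive number")
  if (length(object@c) != 1 || (!is.na(object@c) && object@c < 0))
    msg <- c(msg, "c must be >= 0 (or NA before calibration)")
  if (length(msg)) msg else TRUE
})

#' Construct calibration parameters
#'
#' Defaults describe the 29-residue flagelliform sensor with the
#' AF555/AF647 FRET pair: a = 0.0122 nm/pN, b = 0.044 nm, n = 29,
#' R0 = 5.1 nm. The linker constant `c` is inferred at run time from a
#' zero-force FRET efficiency via [calibrateLinker()].
#'
#' @param a compliance per amino acid (nm/pN).
#' @param b collapsed length per amino acid (nm).
#' @param n number of amino acids between fluorophores.
#' @param c constant linker length (nm), `NA` if not yet calibrated.
#' @param R0 Förster distance (nm).
#' @return A [CalibrationParams-class] object.
#' @examples
#' calibrateLinker(0.87, CalibrationParams())
#' @export
CalibrationParams <- function(a = 0.0122, b = 0.044, n = 29, c = NA_real_,
                              R0 = 5.1) {
  new("CalibrationParams", a = a, b = b, n = n, c = as.numeric(c), R0 = R0)
}

setMethod("show", "CalibrationParams", function(object) {
  cat("CalibrationParams\n")
  cat(sprintf("  a  = %.4f nm/pN (compliance per amino acid)\n", object@a))
  cat(sprintf("  b  = %.4f nm (collapsed length per amino acid)\n", object@b))
  cat(sprintf("  n  = %d amino acids\n", as.integer(object@n)))
  cat(sprintf("  c  = %s nm (linker)\n",
              if (is.na(object@c)) "<uncalibrated>" else sprintf("%.1f", object@c)))
  cat(sprintf("  R0 = %.2f nm\n", object@R0))
})

#' Dynamic range of the force sensor
#'
#' FRET-efficiency bounds of resolvable sensor states and the tensile
#' forces they map to. By construction `fMin = fretToForce(eMax)` and
#' `fMax = fretToForce(eMin)` (force decreases with FRET efficiency).
#'
#' @slot eMin,eMax FRET efficiency bounds (unitless, in (0,1)).
#' @slot fMin,fMax force bounds (pN).
#' @export
setClass("DynamicRange",
  representation(eMin = "numeric", eMax = "numeric",
                 fMin = "numeric", fMax = "numeric"))

setValidity("DynamicRange", function(object) {
  msg <- character()
  if (!(object@eMin > 0 && object@eMin < object@eMax && object@eMax < 1))
    msg <- c(msg, "need 0 < eMin < eMax < 1")
  if (!(object@fMin > 0 && object@fMin < object@fMax))
    msg <- c(msg, "need 0 < fMin < fMax")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DynamicRange", function(object) {
  cat(sprintf("DynamicRange: E in [%.2f, %.2f]  <->  F in [%.1f, %.1f] pN\n",
              object@eMin, object@eMax, object@fMin, object@fMax))
})

#' EMCCD camera parameters
#'
#' @slot photonsPerCount conversion efficiency (photons per digital count).
#' @slot emGain electron-multiplying gain (unitless).
#' @slot pixelSize pixel size in the sample plane (nm).
#' @slot readNoiseSd Gaussian read noise (counts).
#' @slot offset camera offset (counts).
#' @export
setClass("CameraParams",
  representation(photonsPerCount = "numeric", emGain = "numeric",
                 pixelSize = "numeric", readNoiseSd = "numeric",
                 offset = "numeric"),
  prototype(photonsPerCount = 15.7, emGain = 300, pixelSize = 160,
            readNoiseSd = 1, offset = 100))

setValidity("CameraParams", function(object) {
  msg <- character()
  if (object@photonsPerCount <= 0) msg <- c(msg, "photonsPerCount must be > 0")
  if (object@emGain < 1) msg <- c(msg, "emGain must be >= 1")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param photonsPerCount,emGain,pixelSize,readNoiseSd,offset see slots.
#' @rdname CameraParams-class
#' @export
CameraParams <- function(photonsPerCount = 15.7, emGain = 300,
                         pixelSize = 160, readNoiseSd = 1, offset = 100) {
  new("CameraParams", photonsPerCount = photonsPerCount, emGain = emGain,
      pixelSize = pixelSize, readNoiseSd = readNoiseSd, offset = offset)
}

setMethod("show", "CameraParams", function(object) {
  cat(sprintf(
    "CameraParams: %.1f photons/count, EM gain %g, %g nm px, read noise %g counts, offset %g\n",
    object@photonsPerCount, object@emGain, object@pixelSize,
    object@readNoiseSd, object@offset))
})

#' Alternating-excitation timing parameters
#'
#' A recording consists of `nFramePairs` green/red doublets: a donor
#' excitation frame (yielding the DD and DA images), a short green-to-red
#' delay `tGr`, an acceptor excitation frame (AA image), and a doublet
#' delay `tDelay`.
#'
#' @slot tIll illumination time per frame (ms).
#' @slot tGr delay between green and red frame of one doublet (ms).
#' @slot tDelay delay between consecutive doublets (ms).
#' @slot nFramePairs number of green/red doublets.
#' @export
setClass("TimingParams",
  representation(tIll = "numeric", tGr = "numeric", tDelay = "numeric",
                 nFramePairs = "numeric"),
  prototype(tIll = 5, tGr = 5, tDelay = 85, nFramePairs = 300))

setValidity("TimingParams", function(object) {
  if (any(c(object@tIll, object@tGr, object@tDelay) <= 0) ||
      object@nFramePairs < 1)
    "all timing values must be positive and nFramePairs >= 1" else TRUE
})

#' @param tIll,tGr,tDelay,nFramePairs see slots.
#' @rdname TimingParams-class
#' @export
TimingParams <- function(tIll = 5, tGr = 5, tDelay = 85, nFramePairs = 300) {
  new("TimingParams", tIll = tIll, tGr = tGr, tDelay = tDelay,
      nFramePairs = nFramePairs)
}

#' Frame-pair interval in seconds
#'
#' Time between consecutive green/red doublets.
#' @param timing a [TimingParams-class] object.
#' @return interval (s).
#' @export
frameInterval <- function(timing) {
  (2 * timing@tIll + timing@tGr + timing@tDelay) / 1000
}

#' ALEX spectral correction factors
#'
#' @slot alpha donor emission bleedthrough into the acceptor channel.
#' @slot delta direct excitation of the acceptor by the donor laser.
#' @slot gamma detection-efficiency ratio of acceptor over donor channel.
#' @slot beta excitation-efficiency factor scaling f_AA.
#' @export
setClass("CorrectionFactors",
  representation(alpha = "numeric", delta = "numeric",
                 gamma = "numeric", beta = "numeric"),
  prototype(alpha = 0, delta = 0, gamma = 1, beta = 1))

setValidity("CorrectionFactors", function(object) {
  v <- c(object@alpha, object@delta, object@gamma, object@beta)
  if (any(v < 0) || object@gamma <= 0 || object@beta <= 0)
    "alpha, delta >= 0 and gamma, beta > 0 required" else TRUE
})

#' @param alpha,delta,gamma,beta see slots.
#' @rdname CorrectionFactors-class
#' @export
CorrectionFactors <- function(alpha = 0, delta = 0, gamma = 1, beta = 1) {
  new("CorrectionFactors", alpha = alpha, delta = delta, gamma = gamma,
      beta = beta)
}

setMethod("show", "CorrectionFactors", function(object) {
  cat(sprintf("CorrectionFactors: alpha=%.3f delta=%.3f gamma=%.3f beta=%.3f\n",
              object@alpha, object@delta, object@gamma, object@beta))
})

#' Affine channel transform
#'
#' Maps donor-channel coordinates onto acceptor-channel geometry:
#' y = A x + t, with 0-based pixel-centre coordinates.
#'
#' @slot linear 2x2 matrix A.
#' @slot offset length-2 translation t (px).
#' @export
setClass("AffineTransform",
  representation(linear = "matrix", offset = "numeric"),
  prototype(linear = diag(2), offset = c(0, 0)))

setValidity("AffineTransform", function(object) {
  if (!all(dim(object@linear) == c(2, 2)) || length(object@offset) != 2)
    return("linear must be 2x2 and offset length 2")
  if (abs(det(object@linear)) <= 1e-6)
    return("linear part must be invertible (|det| > 1e-6)")
  TRUE
})

#' @param linear,offset see slots.
#' @rdname AffineTransform-class
#' @export
AffineTransform <- function(linear = diag(2), offset = c(0, 0)) {
  new("AffineTransform", linear = linear, offset = offset)
}

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (donor -> acceptor, px):\n")
  m <- cbind(object@linear, object@offset)
  dimnames(m) <- list(c("x", "y"), c("a11", "a12", "t"))
  print(round(m, 5))
})

#' Three-channel alternating-excitation movie
#'
#' Container for a simulated or loaded recording: one photon-count (or raw
#' count) image stack per channel plus acquisition metadata and, for
#' simulated movies, the generating ground truth.
#'
#' Images are matrices indexed `[row, col] = [y + 1, x + 1]` with 0-based
#' pixel-centre coordinates (x, y).
#'
#' @slot dd,da,aa arrays `[height, width, nFramePairs]`: donor emission at
#'   donor excitation, acceptor emission at donor excitation, acceptor
#'   emission at acceptor excitation.
#' @slot times frame-pair start times (s).
#' @slot camera a [CameraParams-class].
#' @slot timing a [TimingParams-class].
#' @slot truth list with elements `molecules` (scene table) and `records`
#'   (per-molecule, per-frame ground truth); empty for real data.
#' @slot unit `"counts"` or `"photons"`.
#' @export
setClass("FretMovie",
  representation(dd = "array", da = "array", aa = "array",
                 times = "numeric", camera = "CameraParams",
                 timing = "TimingParams", truth = "list", unit = "character"))

setValidity("FretMovie", function(object) {
  d <- dim(object@dd)
  if (length(d) != 3) return("channel stacks must be 3D arrays")
  if (!identical(d, dim(object@da)) || !identical(d, dim(object@aa)))
    return("all three channel stacks must have identical dimensions")
  if (length(object@times) != d[3])
    return("times must have one entry per frame pair")
  if (is.unsorted(object@times, strictly = TRUE))
    return("frame times must be strictly increasing")
  if (!object@unit %in% c("counts", "photons"))
    return("unit must be 'counts' or 'photons'")
  TRUE
})

setMethod("show", "FretMovie", function(object) {
  d <- dim(object@dd)
  cat(sprintf("FretMovie: %d x %d px, %d frame pairs (%s)\n",
              d[2], d[1], d[3], object@unit))
  if (length(object@truth))
    cat(sprintf("  ground truth: %d molecules\n", nrow(object@truth$molecules)))
})

#' Number of frame pairs in a movie
#' @param movie a [FretMovie-class].
#' @export
nFramePairs <- function(movie) dim(movie@dd)[3]

#' Movie field size in pixels
#' @param movie a [FretMovie-class].
#' @return c(width, height).
#' @export
fieldSize <- function(movie) dim(movie@dd)[c(2, 1)]
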