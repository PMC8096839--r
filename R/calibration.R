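#' Fluorophore separation from FRET efficiency
#'
#' Inverts the Förster relation E = 1 / (1 + (r/R0)^6).
#'
#' @param e FRET efficiency, strictly inside (0, 1). Vectorised.
#' @param R0 Förster distance (nm).
#' @return separation r (nm), strictly decreasing in `e`.
#' @export
fretToDistance <- function(e, R0 = 5.1) {
  stopifnot(is.numeric(e), R0 > 0)
  if (any(e <= 0 | e >= 1))
    stop("FRET efficiency must lie strictly inside (0, 1)")
  R0 * ((1 - e) / e)^(1 / 6)
}

#' Tensile force from fluorophore separation
#'
#' Linear force-extension law of the flagelliform spring:
#' F = (r - b*n - c) / (a*n). Values of r below the collapsed length
#' b*n + c give negative forces; these are returned as-is (callers decide
#' whether to clamp) so that zero-force noise stays symmetric.
#'
#' @param r separation (nm), >= 0. Vectorised.
#' @param params a calibrated [CalibrationParams-class] (slot `c` set).
#' @return force (pN).
#' @export
distanceToForce <- function(r, params) {
  stopifnot(is(params, "CalibrationParams"))
  if (is.na(params@c))
    stop("params not calibrated: linker constant c is NA (run calibrateLinker)")
  if (any(r < 0)) stop("separation r must be >= 0")
  (r - params@b * params@n - params@c) / (params@a * params@n)
}

#' Tensile force from FRET efficiency
#'
#' Composition of [fretToDistance()] and [distanceToForce()]; strictly
#' decreasing in `e`.
#'
#' @inheritParams fretToDistance
#' @inheritParams distanceToForce
#' @return force (pN).
#' @examples
#' p <- calibrateLinker(0.87, CalibrationParams())
#' fretToForce(0.11, p)  # ~10 pN, the upper end of the linear regime
#' @export
fretToForce <- function(e, params) {
  distanceToForce(fretToDistance(e, params@R0), params)
}

#' FRET efficiency from tensile force
#'
#' Exact inverse of [fretToForce()].
#'
#' @param f force (pN); must satisfy a*n*f + b*n + c > 0. Vectorised.
#' @inheritParams distanceToForce
#' @return FRET efficiency in (0, 1).
#' @export
forceToFret <- function(f, params) {
  stopifnot(is(params, "CalibrationParams"))
  if (is.na(params@c))
    stop("params not calibrated: linker constant c is NA (run calibrateLinker)")
  r <- params@a * params@n * f + params@b * params@n + params@c
  if (any(r <= 0)) stop("force maps to non-positive separation")
  1 / (1 + (r / params@R0)^6)
}

#' Infer the linker constant from a zero-force measurement
#'
#' The constant linker length c is determined from the FRET efficiency E0
#' of the collapsed (force-free) sensor, as measured on bilayers without
#' cells: c = r(E0) - b*n. The returned parameters reproduce F = 0 at E0.
#' The value is carried unrounded; the printed summary rounds to 0.1 nm.
#'
#' @param e0 zero-force FRET efficiency, in (0, 1).
#' @param params a [CalibrationParams-class]; slot `c` is ignored.
#' @return `params` with slot `c` set.
#' @examples
#' p <- calibrateLinker(0.87, CalibrationParams())
#' round(p@c, 1)  # 2.4 nm
#' @export
calibrateLinker <- function(e0, params = CalibrationParams()) {
  stopifnot(length(e0) == 1)
  cc <- fretToDistance(e0, params@R0) - params@b * params@n
  if (cc < 0)
    stop(sprintf(
      "inconsistent calibration: E0 = %.3g implies negative linker length (c = %.3g nm)",
      e0, cc))
  initialize(params, c = cc)
}

#' Assemble the sensor's dynamic range from FRET-efficiency bounds
#'
#' @param params calibrated [CalibrationParams-class].
#' @param eMin,eMax FRET-efficiency bounds, 0 < eMin < eMax < 1. `eMin` is
#'   the smallest resolvable efficiency (highest force), `eMax` the largest
#'   efficiency still distinguishable from the collapsed-state peak.
#' @return a [DynamicRange-class] with `fMin = fretToForce(eMax)` and
#'   `fMax = fretToForce(eMin)`.
#' @export
computeDynamicRange <- function(params, eMin, eMax) {
  if (!(eMin > 0 && eMin < eMax && eMax < 1))
    stop("need 0 < eMin < eMax < 1")
  new("DynamicRange", eMin = eMin, eMax = eMax,
      fMin = fretToForce(eMax, params), fMax = fretToForce(eMin, params))
}

#' Propagate a FRET peak through the calibration to a force distribution
#'
#' Transforms a Gaussian FRET-efficiency peak, truncated to the sensor's
#' dynamic range, through the nonlinear efficiency-to-force map and reports
#' the mean and standard deviation of the resulting force distribution.
#' Deterministic trapezoidal quadrature on >= 2001 nodes is used; no Monte
#' Carlo is involved.
#'
#' @param peakMean,peakSd mean and sd of the Gaussian efficiency peak.
#' @param params calibrated [CalibrationParams-class].
#' @param range a [DynamicRange-class] delimiting the truncation interval.
#' @param nNodes number of quadrature nodes (>= 2001 recommended).
#' @return list with `mean` (pN), `sd` (pN), and `outsideRange` (TRUE with a
#'   warning when the peak mean falls outside the dynamic range, in which
#'   case the integration is still clamped to the range).
#' @examples
#' p <- calibrateLinker(0.87, CalibrationParams())
#' dr <- computeDynamicRange(p, 0.11, 0.8)
#' propagatePeakToForce(0.42, 0.22, p, dr)$mean  # ~4.9 pN
#' @export
propagatePeakToForce <- function(peakMean, peakSd, params, range,
                                 nNodes = 2001) {
  stopifnot(peakMean > 0, peakMean < 1, peakSd > 0, nNodes >= 3,
            is(range, "DynamicRange"))
  outside <- peakMean < range@eMin || peakMean > range@eMax
  if (outside)
    warning("peak mean lies outside the dynamic range; integration clamped")
  # concentrate the nodes on the effective support of the truncated Gaussian
  lo <- max(range@eMin, peakMean - 10 * peakSd)
  hi <- min(range@eMax, peakMean + 10 * peakSd)
  if (!(lo < hi)) {
    lo <- range@eMin
    hi <- range@eMax
  }
  e <- seq(lo, hi, length.out = nNodes)
  w <- stats::dnorm(e, peakMean, peakSd)
  # trapezoid weights
  tw <- c(0.5, rep(1, nNodes - 2), 0.5)
  w <- w * tw
  w <- w / sum(w)
  f <- fretToForce(e, params)
  m <- sum(w * f)
  v <- sum(w * (f - m)^2)
  list(mean = m, sd = sqrt(v), outsideRange = outside)
}

#' Default sensor calibration
#'
#' Convenience wrapper: standard flagelliform-sensor constants with the
#' linker inferred from the collapsed-state efficiency.
#'
#' @param e0 zero-force FRET efficiency (default 0.87).
#' @return calibrated [CalibrationParams-class].
#' @export
defaultCalibration <- function(e0 = 0.87) {
  calibrateLinker(e0, CalibrationParams())
}

#' Conversion table over the dynamic range
#'
#' @param params calibrated [CalibrationParams-class].
#' @param range a [DynamicRange-class].
#' @param n number of rows.
#' @return data.frame with columns `e`, `r_nm`, `force_pn`.
#' @export
calibrationTable <- function(params, range, n = 25) {
  e <- seq(range@eMin, range@eMax, length.out = n)
  data.frame(e = e, r_nm = fretToDistance(e, params@R0),
             force_pn = fretToForce(e, params))
}

#' Read and write calibration objects as JSON
#'
#' @param params a [CalibrationParams-class].
#' @param range a [DynamicRange-class] or NULL.
#' @param path file path.
#' @return `readCalibrationParams` returns a list with elements `params`
#'   and (if stored) `range`.
#' @export
writeCalibrationParams <- function(params, path, range = NULL) {
  x <- list(a = params@a, b = params@b, n = params@n, c = params@c,
            R0 = params@R0)
  if (!is.null(range))
    x$range <- list(eMin = range@eMin, eMax = range@eMax,
                    fMin = range@fMin, fMax = range@fMax)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationParams
#' @export
readCalibrationParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(params = CalibrationParams(a = x$a, b = x$b, n = x$n,
                                         c = x$c, R0 = x$R0))
  if (!is.null(x$range))
    out$range <- new("DynamicRange", eMin = x$range$eMin, eMax = x$range$eMax,
                     fMin = x$range$fMin, fMax = x$range$fMax)
  out
}
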