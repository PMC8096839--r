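# Simulation-based determination of the largest detectable low-FRET
# efficiency E_max, and assembly of the sensor's full dynamic range.

#' Detectability of a low-FRET peak by Kolmogorov-Smirnov testing
#'
#' For each replicate, draws a mixture sample (weight `weight` from the low
#' peak, the rest from the high collapsed-state peak) and an equally sized
#' pure high-peak sample, and computes the two-sample KS p-value. Low
#' p-values mean the low-FRET peak is distinguishable.
#'
#' @param lowMean,lowSd Gaussian parameters of the low-FRET peak.
#' @param weight relative weight of the low-FRET peak, in (0, 1).
#' @param n sample size per draw (default 2300, a typical dataset size).
#' @param high c(mean, sd) of the collapsed-state peak (default 0.87, 0.12).
#' @param nReps number of replicates.
#' @param seed integer seed.
#' @return list with `medianP` and the vector `p`.
#' @export
ksDetectability <- function(lowMean, lowSd, weight, n = 2300,
                            high = c(0.87, 0.12), nReps = 50, seed = NULL) {
  stopifnot(weight >= 0, weight < 1, n >= 100)
  if (!is.null(seed)) set.seed(seed)
  p <- vapply(seq_len(nReps), function(r) {
    isLow <- stats::runif(n) < weight
    mix <- ifelse(isLow, stats::rnorm(n, lowMean, lowSd),
                  stats::rnorm(n, high[1], high[2]))
    pure <- stats::rnorm(n, high[1], high[2])
    suppressWarnings(stats::ks.test(mix, pure)$p.value)
  }, 0)
  list(medianP = stats::median(p), p = p)
}

#' Largest detectable low-FRET efficiency E_max
#'
#' Computes the median KS p-value over a grid of low-peak means and sds and
#' returns the largest mean (at the sd column closest to `refSd`) whose
#' median p-value is below `alpha` — beyond that mean, the low-FRET peak can
#' no longer be discriminated from the collapsed-state peak.
#'
#' @param lowMeans,lowSds grid of low-peak parameters.
#' @param weight low-peak weight (0.15 is the conservative standard choice).
#' @param alpha significance cut on the median p-value.
#' @param n sample size per draw.
#' @param high collapsed-state peak c(mean, sd).
#' @param nReps replicates per grid point (median-aggregated).
#' @param refSd representative sd at which E_max is read off.
#' @param seed integer seed.
#' @return list with `eMax`, `pMap` (matrix lowMeans x lowSds of median
#'   p-values), `lowMeans`, `lowSds`.
#' @export
eMaxThreshold <- function(lowMeans = seq(0.1, 0.85, by = 0.05),
                          lowSds = seq(0.05, 0.3, by = 0.05),
                          weight = 0.15, alpha = 0.05, n = 2300,
                          high = c(0.87, 0.12), nReps = 50, refSd = 0.12,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pMap <- matrix(NA_real_, length(lowMeans), length(lowSds),
                 dimnames = list(lowMeans, lowSds))
  for (i in seq_along(lowMeans))
    for (j in seq_along(lowSds))
      pMap[i, j] <- ksDetectability(lowMeans[i], lowSds[j], weight, n = n,
                                    high = high, nReps = nReps)$medianP
  jRef <- which.min(abs(lowSds - refSd))
  det <- which(pMap[, jRef] < alpha)
  eMax <- if (length(det)) lowMeans[max(det)] else NA_real_
  list(eMax = eMax, pMap = pMap, lowMeans = lowMeans, lowSds = lowSds)
}

#' Assemble the sensor's dynamic range
#'
#' E_min is set by the force at which the spring leaves its linear
#' force-extension regime (`fLinearLimit`, default 10 pN); E_max comes from
#' the KS detectability analysis (or the standard value 0.8).
#'
#' @param params calibrated [CalibrationParams-class].
#' @param fLinearLimit upper linear-regime force (pN).
#' @param eMax largest detectable low-FRET efficiency.
#' @return a [DynamicRange-class].
#' @examples
#' assembleDynamicRange(defaultCalibration())  # E in [0.11, 0.8]
#' @export
assembleDynamicRange <- function(params, fLinearLimit = 10, eMax = 0.8) {
  computeDynamicRange(params, forceToFret(fLinearLimit, params), eMax)
}
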