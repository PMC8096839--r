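# Gaussian mixture fitting of the 2D (S, E) point cloud and conversion of
# fitted FRET peaks to force-distribution summaries.

#' @importFrom mclust Mclust mclustBIC priorControl em emVVV meVVV estepVVV
NULL

#' Gaussian mixture fit of (S, E) data
#'
#' @slot weights component weights (sum to 1).
#' @slot means k x 2 matrix, columns `e`, `s`.
#' @slot covariances 2 x 2 x k array.
#' @slot nPoints number of fitted points.
#' @slot fallback TRUE when the two-component fit was rejected (low-FRET
#'   component beyond eMax or weight below the minimum) and a single
#'   Gaussian is reported.
#' @slot logLik model log-likelihood.
#' @export
setClass("MixtureFit",
  representation(weights = "numeric", means = "matrix",
                 covariances = "array", nPoints = "numeric",
                 fallback = "logical", logLik = "numeric"))

setValidity("MixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be >= 0")
  for (k in seq_along(object@weights)) {
    ev <- eigen(object@covariances[, , k], symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev <= 0)) return("covariances must be positive definite")
  }
  TRUE
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: %d component(s), n = %d%s\n",
              length(object@weights), object@nPoints,
              if (object@fallback) " [fallback: single Gaussian]" else ""))
  for (k in seq_along(object@weights))
    cat(sprintf("  comp %d: weight %.3f, E = %.3f (sd %.3f), S = %.3f\n",
                k, object@weights[k], object@means[k, 1],
                sqrt(object@covariances[1, 1, k]), object@means[k, 2]))
})

mclustToFit <- function(mc, fallback) {
  k <- mc$G
  means <- t(mc$parameters$mean)          # k x 2 (e, s)
  colnames(means) <- c("e", "s")
  sig <- mc$parameters$variance$sigma
  if (is.null(sig))
    sig <- array(mc$parameters$variance$Sigma, c(2, 2, k))
  new("MixtureFit", weights = as.numeric(mc$parameters$pro), means = means,
      covariances = sig, nPoints = mc$n, fallback = fallback,
      logLik = mc$loglik)
}

#' Fit the (S, E) point cloud with a Gaussian mixture
#'
#' Maximum-likelihood fit (EM with deterministic model-based hierarchical
#' initialisation) with up to `maxComponents` full-covariance components.
#' Fallback rule: when the low-FRET component's mean efficiency exceeds the
#' maximum detectable value `eMax`, or its relative weight is below
#' `minWeight`, the result of a single-component fit is reported instead and
#' the fallback flag set. Degenerate covariances trigger a regularised
#' (conjugate-prior) refit.
#'
#' @param points data.frame with columns `e`, `s` (non-finite rows dropped).
#' @param maxComponents maximum number of components (default 2).
#' @param eMax largest detectable low-FRET efficiency.
#' @param minWeight minimum relative weight of the low-FRET component.
#' @param minPoints minimum number of points required.
#' @return a [MixtureFit-class].
#' @export
fitESMixture <- function(points, maxComponents = 2, eMax = 0.8,
                         minWeight = 0.1, minPoints = 100) {
  x <- points[is.finite(points$e) & is.finite(points$s), c("e", "s")]
  if (nrow(x) < minPoints)
    stop(sprintf("need at least %d points, got %d", minPoints, nrow(x)))
  # deterministic subset for the hierarchical initialisation on large data
  init <- if (nrow(x) > 5000)
    list(subset = unique(round(seq(1, nrow(x), length.out = 2000))))
  else NULL
  fitG <- function(g) {
    mc <- tryCatch(
      suppressWarnings(mclust::Mclust(x, G = g, modelNames = "VVV",
                                      initialization = init,
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(mc))
      mc <- suppressWarnings(mclust::Mclust(
        x, G = g, modelNames = "VVV", verbose = FALSE, initialization = init,
        prior = mclust::priorControl()))
    mc
  }
  if (maxComponents >= 2) {
    mc <- fitG(2)
    if (!is.null(mc)) {
      low <- which.min(mc$parameters$mean[1, ])
      if (mc$parameters$pro[low] >= minWeight &&
          mc$parameters$mean[1, low] <= eMax) {
        out <- mclustToFit(mc, fallback = FALSE)
        attr(out, "mclust") <- mc
        return(out)
      }
    }
  }
  mc1 <- fitG(1)
  out <- mclustToFit(mc1, fallback = maxComponents >= 2)
  attr(out, "mclust") <- mc1
  out
}

#' Bootstrap standard errors of the mixture fit
#'
#' Draws `nBoot` resamples with replacement (each the size of the original
#' data), refits the chosen model (same number of components; the fallback
#' rule is not re-applied, since the model selection has already been made
#' on the full data), matches components to the original fit by proximity
#' of the mean efficiencies (resolving label switching), and reports the
#' standard deviation of each parameter over the resamples.
#'
#' @param points the fitted data (columns `e`, `s`).
#' @param fit the original [MixtureFit-class].
#' @param nBoot number of bootstrap samples (default 100).
#' @param seed integer seed; fixed seeds give identical standard errors.
#' @return list with `se` (data.frame per component: weight, meanE, meanS,
#'   sdE) and `samples` (array nBoot x k x 4 of the matched estimates).
#' @export
bootstrapFit <- function(points, fit, nBoot = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- points[is.finite(points$e) & is.finite(points$s), c("e", "s")]
  k <- length(fit@weights)
  samples <- array(NA_real_, c(nBoot, k, 4),
                   dimnames = list(NULL, NULL,
                                   c("weight", "meanE", "meanS", "sdE")))
  mc <- attr(fit, "mclust")
  for (b in seq_len(nBoot)) {
    xb <- as.matrix(x[sample.int(nrow(x), nrow(x), replace = TRUE), ])
    # EM restarted from the full-data solution keeps every resample in the
    # same likelihood basin (avoids label switching and spurious re-splits)
    pars <- NULL
    if (!is.null(mc)) {
      fe <- tryCatch(suppressWarnings(
        mclust::em(data = xb, modelName = mc$modelName,
                   parameters = mc$parameters)),
        error = function(e) NULL)
      if (!is.null(fe) && !is.null(fe$parameters$pro) &&
          all(is.finite(fe$parameters$pro)))
        pars <- list(w = fe$parameters$pro, m = t(fe$parameters$mean),
                     s = fe$parameters$variance$sigma)
    }
    if (is.null(pars)) {
      fb <- tryCatch(fitESMixture(as.data.frame(xb), maxComponents = k,
                                  eMax = 1, minWeight = 0),
                     error = function(e) NULL)
      if (is.null(fb)) next
      pars <- list(w = fb@weights, m = fb@means, s = fb@covariances)
    }
    if (is.null(dim(pars$s))) pars$s <- array(pars$s, c(2, 2, 1))
    # match bootstrap components to the original by nearest mean E
    for (j in seq_len(k)) {
      jj <- which.min(abs(pars$m[, 1] - fit@means[j, 1]))
      samples[b, j, ] <- c(pars$w[jj], pars$m[jj, 1], pars$m[jj, 2],
                           sqrt(pars$s[1, 1, jj]))
    }
  }
  se <- apply(samples, c(2, 3), stats::sd, na.rm = TRUE)
  list(se = as.data.frame(se), samples = samples)
}

#' Convert fitted FRET peaks to force summaries
#'
#' The component with the highest mean efficiency is the collapsed
#' (zero-force) reference; every other component's efficiency marginal is
#' propagated through the calibration (truncated-Gaussian quadrature, see
#' [propagatePeakToForce()]) to a force mean and sd.
#'
#' @param fit a [MixtureFit-class].
#' @param params calibrated [CalibrationParams-class].
#' @param range a [DynamicRange-class].
#' @return data.frame with one row per component: `component`, `role`,
#'   `weight`, `meanE`, `sdE`, `meanForce`, `sdForce`, `outsideRange`.
#' @export
summarizeForcePeaks <- function(fit, params, range) {
  k <- length(fit@weights)
  ord <- order(fit@means[, 1], decreasing = TRUE)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    j <- ord[i]
    meanE <- fit@means[j, 1]
    sdE <- sqrt(fit@covariances[1, 1, j])
    if (i == 1) {  # collapsed reference
      out[[i]] <- data.frame(component = j, role = "collapsed",
                             weight = fit@weights[j], meanE = meanE,
                             sdE = sdE, meanForce = 0, sdForce = NA_real_,
                             outsideRange = FALSE)
    } else {
      flagged <- meanE <= 0 || meanE >= 1
      if (flagged) {
        pk <- list(mean = NA_real_, sd = NA_real_, outsideRange = TRUE)
      } else {
        pk <- withCallingHandlers(
          propagatePeakToForce(meanE, sdE, params, range),
          warning = function(w) invokeRestart("muffleWarning"))
      }
      out[[i]] <- data.frame(component = j, role = "stretched",
                             weight = fit@weights[j], meanE = meanE,
                             sdE = sdE, meanForce = pk$mean,
                             sdForce = pk$sd,
                             outsideRange = flagged || pk$outsideRange)
    }
  }
  do.call(rbind, out)
}

#' Per-record point forces for display
#'
#' Point transform E -> F per datum, for histogram rendering only (peak
#' inference uses the fitted mixture). Efficiencies are clamped to the
#' dynamic range before conversion and flagged.
#'
#' @param e efficiencies.
#' @param params calibrated [CalibrationParams-class].
#' @param range a [DynamicRange-class].
#' @return data.frame with `force` and `clamped`.
#' @export
pointForces <- function(e, params, range) {
  clamped <- e < range@eMin | e > range@eMax
  ec <- pmin(pmax(e, range@eMin), range@eMax)
  data.frame(force = fretToForce(ec, params), clamped = clamped)
}
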