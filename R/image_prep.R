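# Separable convolution with whole-sample symmetric (reflective) padding.
# Reflective boundaries together with a normalised kernel conserve the total
# image sum exactly, which the brightness estimators downstream rely on.

convMatrix1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r >= n) stop("kernel radius must be smaller than the image extent")
  # padded index -> source index under reflect-with-edge padding
  padIdx <- c(r:1, 1:n, n:(n - r + 1L))[seq_len(n + 2L * r)]
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    src <- padIdx[(1:n) + j - 1L]
    K[cbind(1:n, src)] <- K[cbind(1:n, src)] + kernel[j]
  }
  K
}

gaussKernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with reflective boundaries
#'
#' Separable Gaussian convolution used before spot detection and brightness
#' measurement. The kernel is normalised and boundaries are reflected, so
#' the integrated intensity is conserved (to numerical precision for
#' interior spots; see the methods vignette for the boundary caveat).
#'
#' @param image numeric matrix.
#' @param sigma kernel width (px), default 1.
#' @return blurred matrix of the same shape.
#' @export
blurForDetection <- function(image, sigma = 1) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- gaussKernel1d(sigma, radius = min(ceiling(4 * sigma),
                                         min(dim(image)) - 1L))
  Ky <- convMatrix1d(nrow(image), k)
  Kx <- convMatrix1d(ncol(image), k)
  Ky %*% image %*% t(Kx)
}

boxBlur <- function(image, size) {
  # local mean over a size x size block (size odd), reflective boundaries
  stopifnot(size %% 2 == 1)
  k <- rep(1 / size, size)
  Ky <- convMatrix1d(nrow(image), k)
  Kx <- convMatrix1d(ncol(image), k)
  Ky %*% image %*% t(Kx)
}

#' Convert camera counts to photons
#'
#' photons = (counts - offset) * photonsPerCount / emGain. The offset is
#' subtracted before conversion when `subtractOffset = TRUE` (default); set
#' it to `FALSE` for data that are already offset-free.
#'
#' @param counts numeric matrix or array of raw camera counts.
#' @param camera a [CameraParams-class].
#' @param subtractOffset subtract `camera@offset` first?
#' @return object of the same shape, in photons.
#' @export
countsToPhotons <- function(counts, camera, subtractOffset = TRUE) {
  stopifnot(is(camera, "CameraParams"))
  off <- if (subtractOffset) camera@offset else 0
  (counts - off) * camera@photonsPerCount / camera@emGain
}

#' Convert a whole movie from counts to photons
#'
#' @param movie a [FretMovie-class] in counts.
#' @param subtractOffset subtract the camera offset first?
#' @return the movie with all three stacks converted and `unit = "photons"`.
#' @export
movieToPhotons <- function(movie, subtractOffset = TRUE) {
  if (movie@unit == "photons") return(movie)
  initialize(movie,
             dd = countsToPhotons(movie@dd, movie@camera, subtractOffset),
             da = countsToPhotons(movie@da, movie@camera, subtractOffset),
             aa = countsToPhotons(movie@aa, movie@camera, subtractOffset),
             unit = "photons")
}

#' Estimate the excitation laser profile
#'
#' From an image of a heavily stained sample: Gaussian blur with sigma = 10
#' px, then scaling to a maximum of exactly 1. Brightness values are later
#' divided by this profile at the molecule position.
#'
#' @param image numeric matrix (stained-sample recording, photons or counts).
#' @param sigma blur width (px).
#' @return matrix in (0, 1] with `max == 1`.
#' @export
estimateLaserProfile <- function(image, sigma = 10) {
  stopifnot(is.matrix(image))
  if (all(image <= 0)) stop("profile image has no positive signal")
  b <- blurForDetection(image, sigma)
  b / max(b)
}

profileAt <- function(profile, x, y) {
  # nearest-pixel lookup, 0-based coordinates
  i <- pmin(pmax(round(y), 0), nrow(profile) - 1L) + 1L
  j <- pmin(pmax(round(x), 0), ncol(profile) - 1L) + 1L
  profile[cbind(i, j)]
}

#' Write / read a three-channel movie as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_dd.tif`, `_da.tif`,
#' `_aa.tif`) plus a YAML sidecar with camera, timing and scaling metadata.
#' Counts are stored as value/65535 as is conventional for 16-bit TIFF.
#'
#' @param movie a [FretMovie-class] in counts.
#' @param prefix path prefix for the output files.
#' @return `writeChannelStacks` the prefix, invisibly; `readChannelStacks`
#'   a [FretMovie-class] (without ground truth).
#' @export
writeChannelStacks <- function(movie, prefix) {
  stopifnot(movie@unit == "counts")
  for (ch in c("dd", "da", "aa")) {
    a <- slot(movie, ch)
    pages <- lapply(seq_len(dim(a)[3]), function(k)
      pmin(pmax(a[, , k] / 65535, 0), 1))
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 16L)
  }
  meta <- list(
    scale = 65535,
    times = movie@times,
    camera = list(photonsPerCount = movie@camera@photonsPerCount,
                  emGain = movie@camera@emGain,
                  pixelSize = movie@camera@pixelSize,
                  readNoiseSd = movie@camera@readNoiseSd,
                  offset = movie@camera@offset),
    timing = list(tIll = movie@timing@tIll, tGr = movie@timing@tGr,
                  tDelay = movie@timing@tDelay,
                  nFramePairs = movie@timing@nFramePairs))
  yaml::write_yaml(meta, paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @param prefix path prefix used when writing.
#' @rdname writeChannelStacks
#' @export
readChannelStacks <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  readCh <- function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    a <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]] * meta$scale
    a
  }
  cam <- do.call(CameraParams, meta$camera)
  tim <- do.call(TimingParams, meta$timing)
  new("FretMovie", dd = readCh("dd"), da = readCh("da"), aa = readCh("aa"),
      times = as.numeric(meta$times), camera = cam, timing = tim,
      truth = list(), unit = "counts")
}
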