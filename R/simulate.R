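# Synthetic three-channel ALEX movies with full ground truth.
#
# Emission model for a donor/acceptor pair with donor-excitation photon
# budget B (photons per frame the donor would emit at E = 0) and correction
# factors (alpha, delta, gamma, beta):
#   f_DD = B * (1 - E)                donor channel, green excitation
#   FRET = gamma * B * E              sensitised acceptor emission
#   f_AA = beta * gamma * B           acceptor channel, red excitation
# The DA image receives FRET + alpha * f_DD + delta * f_AA (bleedthrough and
# direct excitation), all scaled by the green laser profile since those
# photons originate from green excitation. This makes the spectral-factor
# estimators exactly identifiable from simulated data. With these
# definitions an intact pair has corrected E equal to the scheduled state
# and S = 0.5; double-donor and double-acceptor species land at S = 2/3 and
# S = 1/3 respectively.

#' One synthetic molecule
#'
#' @param x,y initial position (px, 0-based pixel centres).
#' @param d diffusion coefficient (um^2/s); 0 for immobile molecules.
#' @param brightness donor-excitation photon budget B (photons/frame).
#' @param e FRET efficiency state in `[0, 1]`.
#' @param bleachA,bleachD acceptor / donor photobleaching times (s); `Inf`
#'   for no bleaching within the movie.
#' @param class one of `"pair"`, `"donor_only"`, `"acceptor_only"`,
#'   `"double_donor"`, `"double_acceptor"`.
#' @return one-row data.frame; rbind rows to build a scene.
#' @export
moleculeSpec <- function(x, y, d = 0, brightness = 600, e = 0.87,
                         bleachA = Inf, bleachD = Inf, class = "pair") {
  class <- match.arg(class, c("pair", "donor_only", "acceptor_only",
                              "double_donor", "double_acceptor"))
  stopifnot(e >= 0, e <= 1, bleachA >= 0, bleachD >= 0, d >= 0,
            brightness > 0)
  data.frame(x = x, y = y, d = d, brightness = brightness, e = e,
             bleachA = bleachA, bleachD = bleachD, class = class,
             stringsAsFactors = FALSE)
}

#' A movie scene: field size plus molecule table
#'
#' @param width,height field size (px).
#' @param molecules data.frame of [moleculeSpec()] rows; may carry an
#'   optional list column `eSchedule` of `data.frame(time, e)` state
#'   schedules that override the static `e` (state at time t is the last
#'   entry with `time <= t`).
#' @return list of class `movieScene`.
#' @export
movieScene <- function(width, height, molecules) {
  stopifnot(width >= 8, height >= 8, nrow(molecules) >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 molecules = molecules), class = "movieScene")
}

# integrated 2D Gaussian PSF: photon mass per pixel via error-function
# integration, so sub-pixel positions are rendered exactly
addSpot <- function(img, x, y, total, sigma) {
  if (total <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(4 * sigma + 1)
  ix <- max(0, floor(x - rad)):min(w - 1, ceiling(x + rad))
  iy <- max(0, floor(y - rad)):min(h - 1, ceiling(y + rad))
  if (!length(ix) || !length(iy) || ix[1] > ix[length(ix)] ||
      x < -rad || x > w - 1 + rad || y < -rad || y > h - 1 + rad)
    return(img)  # molecule outside the field: silently clipped
  wx <- stats::pnorm((ix + 0.5 - x) / sigma) - stats::pnorm((ix - 0.5 - x) / sigma)
  wy <- stats::pnorm((iy + 0.5 - y) / sigma) - stats::pnorm((iy - 0.5 - y) / sigma)
  img[iy + 1, ix + 1] <- img[iy + 1, ix + 1] + total * outer(wy, wx)
  img
}

scheduledE <- function(mol, i, t) {
  if (!is.null(mol$eSchedule) && !is.null(mol$eSchedule[[i]])) {
    sch <- mol$eSchedule[[i]]
    sch$e[max(which(sch$time <= t + 1e-12))]
  } else mol$e[i]
}

emissionComponents <- function(class, B, e, gamma, beta, aBleached, dBleached) {
  fdd <- ffret <- faa <- 0
  if (class == "donor_only") {
    if (!dBleached) fdd <- B
  } else if (class == "acceptor_only") {
    if (!aBleached) faa <- beta * gamma * B
  } else {
    nD <- if (class == "double_donor") 2 else 1
    nA <- if (class == "double_acceptor") 2 else 1
    if (!dBleached && !aBleached) {
      fdd <- B * (nD - e)
      ffret <- gamma * B * e
    } else if (!dBleached) {
      fdd <- B * nD
    }
    if (!aBleached) faa <- nA * beta * gamma * B
  }
  c(fdd = fdd, ffret = ffret, faa = faa)
}

#' Render a synthetic alternating-excitation movie
#'
#' Generates the three channel stacks (DD, DA, AA) for a scene of diffusing,
#' photobleaching molecules, together with frame-resolved ground truth.
#' Expected photons per pixel come from integrated Gaussian PSFs scaled by
#' the laser profiles; Poisson shot noise is applied to (signal +
#' background) photons, which are then converted to camera counts
#' (counts = photons * emGain / photonsPerCount + offset) with additive
#' Gaussian read noise. The EM conversion itself is a deterministic scale.
#'
#' @param scene a [movieScene()].
#' @param camera a [CameraParams-class].
#' @param timing a [TimingParams-class]; `timing@nFramePairs` frame pairs
#'   are rendered.
#' @param psfSigma PSF width (px); the default 1 matches a PSF whose
#'   Gaussian sigma equals the pixel size.
#' @param factors [CorrectionFactors-class] used to mix bleedthrough and
#'   direct excitation into the DA channel.
#' @param greenProfile,redProfile laser profile matrices in (0, 1] (height x
#'   width), or NULL for uniform illumination.
#' @param background background photons per pixel per frame.
#' @param seed integer seed; fixing it reproduces the stacks bit-identically.
#' @return a [FretMovie-class] in counts whose `truth` holds the scene table
#'   and a per-molecule, per-frame record table (positions in px, expected
#'   brightness triplets in photons, scheduled E, bleach flags).
#' @export
renderMovie <- function(scene, camera = CameraParams(),
                        timing = TimingParams(), psfSigma = 1,
                        factors = CorrectionFactors(),
                        greenProfile = NULL, redProfile = NULL,
                        background = 2, seed = NULL) {
  stopifnot(inherits(scene, "movieScene"))
  if (!is.null(seed)) set.seed(seed)
  w <- scene$width; h <- scene$height
  mol <- scene$molecules
  nm <- nrow(mol)
  n <- as.integer(timing@nFramePairs)
  dt <- frameInterval(timing)
  times <- (seq_len(n) - 1) * dt
  stepSd <- sqrt(2 * mol$d * dt) * 1000 / camera@pixelSize  # px per axis

  dd <- da <- aa <- array(0, c(h, w, n))
  rec <- vector("list", n)
  x <- mol$x; y <- mol$y
  for (k in seq_len(n)) {
    t <- times[k]
    if (k > 1 && nm > 0) {
      x <- x + stats::rnorm(nm, 0, stepSd)
      y <- y + stats::rnorm(nm, 0, stepSd)
    }
    imDD <- matrix(0, h, w); imDA <- matrix(0, h, w); imAA <- matrix(0, h, w)
    if (nm > 0) {
      pg <- if (is.null(greenProfile)) rep(1, nm) else profileAt(greenProfile, x, y)
      pr <- if (is.null(redProfile)) rep(1, nm) else profileAt(redProfile, x, y)
      eNow <- vapply(seq_len(nm), function(i) scheduledE(mol, i, t), 0)
      comp <- vapply(seq_len(nm), function(i)
        emissionComponents(mol$class[i], mol$brightness[i], eNow[i],
                           factors@gamma, factors@beta,
                           t >= mol$bleachA[i], t >= mol$bleachD[i]),
        c(fdd = 0, ffret = 0, faa = 0))
      fdd <- comp["fdd", ]; ffret <- comp["ffret", ]; faa <- comp["faa", ]
      fdaImg <- (ffret + factors@alpha * fdd + factors@delta * faa) * pg
      for (i in seq_len(nm)) {
        imDD <- addSpot(imDD, x[i], y[i], fdd[i] * pg[i], psfSigma)
        imDA <- addSpot(imDA, x[i], y[i], fdaImg[i], psfSigma)
        imAA <- addSpot(imAA, x[i], y[i], faa[i] * pr[i], psfSigma)
      }
      rec[[k]] <- data.frame(
        molecule = seq_len(nm), frame = k - 1L, t = t, x = x, y = y,
        f_dd = fdd * pg, f_da = fdaImg, f_aa = faa * pr, e = eNow,
        bleachedA = t >= mol$bleachA, bleachedD = t >= mol$bleachD)
    }
    dd[, , k] <- imDD; da[, , k] <- imDA; aa[, , k] <- imAA
  }
  toCounts <- function(lambda) {
    ph <- stats::rpois(length(lambda), lambda + background)
    cnt <- ph * camera@emGain / camera@photonsPerCount + camera@offset +
      stats::rnorm(length(lambda), 0, camera@readNoiseSd)
    array(cnt, dim(lambda))
  }
  truthRecords <- if (nm > 0) do.call(rbind, rec) else data.frame()
  new("FretMovie", dd = toCounts(dd), da = toCounts(da), aa = toCounts(aa),
      times = times, camera = camera, timing = timing,
      truth = list(molecules = mol, records = truthRecords,
                   background = background, factors = factors,
                   psfSigma = psfSigma),
      unit = "counts")
}

#' Render a fiducial-bead image pair for channel registration
#'
#' Bead positions in the second (acceptor) image are the true affine
#' transform applied to the first (donor) image positions.
#'
#' @param nBeads number of beads (>= 3).
#' @param trueAffine an [AffineTransform-class].
#' @param camera a [CameraParams-class].
#' @param imgSize c(width, height) px.
#' @param brightness photons per bead per frame.
#' @param background background photons per pixel.
#' @param psfSigma PSF width (px).
#' @param seed integer seed.
#' @return list with count images `donor`, `acceptor`, true coordinate
#'   matrices `donorXY`, `acceptorXY`, and a logical `collinear` flag for
#'   degenerate bead geometry.
#' @export
renderFiducialPair <- function(nBeads, trueAffine, camera = CameraParams(),
                               imgSize = c(64, 64), brightness = 5000,
                               background = 2, psfSigma = 1, seed = NULL) {
  stopifnot(nBeads >= 3)
  if (!is.null(seed)) set.seed(seed)
  w <- imgSize[1]; h <- imgSize[2]
  xy <- cbind(stats::runif(nBeads, 8, w - 9), stats::runif(nBeads, 8, h - 9))
  xy2 <- applyAffine(trueAffine, xy)
  collinear <- qr(cbind(xy, 1))$rank < 3
  render <- function(pts) {
    img <- matrix(0, h, w)
    for (i in seq_len(nrow(pts)))
      img <- addSpot(img, pts[i, 1], pts[i, 2], brightness, psfSigma)
    ph <- stats::rpois(length(img), img + background)
    matrix(ph * camera@emGain / camera@photonsPerCount + camera@offset +
             stats::rnorm(length(img), 0, camera@readNoiseSd), h, w)
  }
  list(donor = render(xy), acceptor = render(xy2),
       donorXY = xy, acceptorXY = xy2, collinear = collinear)
}

#' Render a cell-indicator image with known mask
#'
#' Smooth bright discs (cells loaded with a cytosolic indicator dye) on a
#' noisy background, plus the true binary mask, for validating adaptive
#' threshold segmentation.
#'
#' @param blobs data.frame with columns `x`, `y` (px), `radius` (px),
#'   `intensity` (photons/px above background); zero rows give an empty mask.
#' @param camera a [CameraParams-class].
#' @param imgSize c(width, height) px.
#' @param background background photons per pixel.
#' @param edgeSigma blur applied to the discs (px) so edges are smooth.
#' @param seed integer seed.
#' @return list with count `image` and logical `mask` (union of the discs).
#' @export
renderCellImage <- function(blobs, camera = CameraParams(),
                            imgSize = c(96, 96), background = 10,
                            edgeSigma = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- imgSize[1]; h <- imgSize[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  lambda <- matrix(0, h, w)
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(blobs))) {
    inside <- (xs - blobs$x[i])^2 + (ys - blobs$y[i])^2 <= blobs$radius[i]^2
    lambda <- lambda + blobs$intensity[i] * inside
    mask <- mask | inside
  }
  if (edgeSigma > 0 && nrow(blobs) > 0)
    lambda <- blurForDetection(lambda, edgeSigma)
  ph <- stats::rpois(length(lambda), lambda + background)
  img <- matrix(ph * camera@emGain / camera@photonsPerCount + camera@offset +
                  stats::rnorm(length(lambda), 0, camera@readNoiseSd), h, w)
  list(image = img, mask = mask)
}

#' Sample (E, S) points from a 2D Gaussian mixture
#'
#' @param n number of points.
#' @param components data.frame with columns `weight`, `meanE`, `sdE`,
#'   `meanS`, `sdS`; weights must sum to 1.
#' @param seed integer seed; fixed seeds reproduce identical samples.
#' @return data.frame with columns `e`, `s`, `component`.
#' @export
sampleESMixture <- function(n, components, seed = NULL) {
  stopifnot(abs(sum(components$weight) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(nrow(components), n, replace = TRUE,
                  prob = components$weight)
  data.frame(e = stats::rnorm(n, components$meanE[k], components$sdE[k]),
             s = stats::rnorm(n, components$meanS[k], components$sdS[k]),
             component = k)
}

#' Simulate a single-molecule force-ramp FRET trace
#'
#' Force rises linearly at `loadingRate` until `peakForce`, then drops
#' step-wise to zero (load-fail event). The observed trace is
#' E(t) = forceToFret(F(t)) plus Gaussian noise.
#'
#' @param loadingRate pN/s, > 0.
#' @param peakForce pN; must lie inside the sensor's dynamic range.
#' @param frameRate frames per second.
#' @param noiseSdE Gaussian noise on the efficiency readout.
#' @param params calibrated [CalibrationParams-class].
#' @param range a [DynamicRange-class]; default spans the linear regime up
#'   to 10 pN with eMax = 0.8.
#' @param duration trace length (s); default 1.4x the rise time.
#' @param seed integer seed.
#' @return data.frame with columns `time`, `e`, `forceTrue`.
#' @export
simulateForceRampTrace <- function(loadingRate, peakForce, frameRate = 10,
                                   noiseSdE = 0.05,
                                   params = defaultCalibration(),
                                   range = NULL, duration = NULL,
                                   seed = NULL) {
  stopifnot(loadingRate > 0, peakForce > 0)
  if (is.null(range))
    range <- computeDynamicRange(params, forceToFret(10, params), 0.8)
  if (peakForce > range@fMax)
    stop("peakForce lies beyond the sensor's dynamic range")
  if (!is.null(seed)) set.seed(seed)
  tRise <- peakForce / loadingRate
  if (is.null(duration)) duration <- 1.4 * tRise
  tt <- seq(0, duration, by = 1 / frameRate)
  f <- ifelse(tt <= tRise, loadingRate * tt, 0)
  e <- forceToFret(f, params) + stats::rnorm(length(tt), 0, noiseSdE)
  data.frame(time = tt, e = e, forceTrue = f)
}

#' Render a donor-channel image pair before/after acceptor photobleaching
#'
#' For validating ensemble FRET via donor recovery: the pre image shows the
#' donor dimmed by FRET (brightness B(1-E)); in the post image all acceptors
#' are bleached (brightness B). Acceptor photobleaching is modelled as
#' complete.
#'
#' @param molecules data.frame with columns `x`, `y` (px), `brightness`
#'   (photons/frame), `e`.
#' @param camera a [CameraParams-class].
#' @param imgSize c(width, height) px.
#' @param background background photons per pixel.
#' @param psfSigma PSF width (px).
#' @param seed integer seed.
#' @return list with count images `pre` and `post`.
#' @export
renderDraapPair <- function(molecules, camera = CameraParams(),
                            imgSize = c(64, 64), background = 1,
                            psfSigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- imgSize[1]; h <- imgSize[2]
  render <- function(bright) {
    img <- matrix(0, h, w)
    for (i in seq_len(nrow(molecules)))
      img <- addSpot(img, molecules$x[i], molecules$y[i], bright[i], psfSigma)
    ph <- stats::rpois(length(img), img + background)
    matrix(ph * camera@emGain / camera@photonsPerCount + camera@offset +
             stats::rnorm(length(img), 0, camera@readNoiseSd), h, w)
  }
  list(pre = render(molecules$brightness * (1 - molecules$e)),
       post = render(molecules$brightness))
}

#' Simulate Brownian trajectories with localization noise
#'
#' Position tables for diffusion and mobility analyses, bypassing the image
#' pipeline.
#'
#' @param nTracks number of trajectories.
#' @param d diffusion coefficient (um^2/s); recycled across tracks.
#' @param nFrames frames per trajectory.
#' @param dt frame interval (s).
#' @param locNoise localization uncertainty sd per axis (um).
#' @param seed integer seed.
#' @return data.frame with columns `molecule`, `frame`, `t`, `x_um`, `y_um`.
#' @export
simulateBrownianTracks <- function(nTracks, d, nFrames, dt,
                                   locNoise = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- rep_len(d, nTracks)
  out <- vector("list", nTracks)
  for (i in seq_len(nTracks)) {
    sx <- cumsum(c(stats::runif(1, 0, 10),
                   stats::rnorm(nFrames - 1, 0, sqrt(2 * d[i] * dt))))
    sy <- cumsum(c(stats::runif(1, 0, 10),
                   stats::rnorm(nFrames - 1, 0, sqrt(2 * d[i] * dt))))
    out[[i]] <- data.frame(
      molecule = i, frame = seq_len(nFrames) - 1L,
      t = (seq_len(nFrames) - 1L) * dt,
      x_um = sx + stats::rnorm(nFrames, 0, locNoise),
      y_um = sy + stats::rnorm(nFrames, 0, locNoise))
  }
  do.call(rbind, out)
}

#' Write a scene to YAML / ground truth to CSV
#'
#' @param scene a [movieScene()].
#' @param path output file.
#' @export
writeScene <- function(scene, path) {
  mols <- scene$molecules
  mols$eSchedule <- NULL
  yaml::write_yaml(list(width = scene$width, height = scene$height,
                        molecules = lapply(seq_len(nrow(mols)), function(i)
                          as.list(mols[i, ]))), path)
  invisible(path)
}

#' @param path YAML file written by [writeScene()].
#' @rdname writeScene
#' @export
readScene <- function(path) {
  x <- yaml::read_yaml(path)
  mols <- do.call(rbind, lapply(x$molecules, function(m)
    do.call(moleculeSpec, m[c("x", "y", "d", "brightness", "e",
                              "bleachA", "bleachD", "class")])))
  movieScene(x$width, x$height, mols)
}
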