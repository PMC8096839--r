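# Spot detection, trajectory linking, and brightness measurement.

# 2D Gaussian least-squares refinement of one candidate on the raw image.
# The model is an integrated Gaussian (per-pixel error-function mass) plus a
# constant background; fitted with Levenberg-Marquardt.
fitGaussianSpot <- function(image, cx, cy, psfSigma = 1, fitRadius = 4) {
  h <- nrow(image); w <- ncol(image)
  ix <- max(0, cx - fitRadius):min(w - 1, cx + fitRadius)
  iy <- max(0, cy - fitRadius):min(h - 1, cy + fitRadius)
  v <- image[iy + 1, ix + 1]
  bg0 <- stats::median(v)
  a0 <- max(sum(v - bg0), 1)
  wgt <- pmax(v - bg0, 0)
  x0 <- if (sum(wgt) > 0) sum(outer(rep(1, length(iy)), ix) * wgt) / sum(wgt) else cx
  y0 <- if (sum(wgt) > 0) sum(outer(iy, rep(1, length(ix))) * wgt) / sum(wgt) else cy
  res <- function(p) {
    wx <- stats::pnorm((ix + 0.5 - p[1]) / p[4]) -
      stats::pnorm((ix - 0.5 - p[1]) / p[4])
    wy <- stats::pnorm((iy + 0.5 - p[2]) / p[4]) -
      stats::pnorm((iy - 0.5 - p[2]) / p[4])
    as.numeric(v - (p[5] + p[3] * outer(wy, wx)))
  }
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(par = c(x0, y0, a0, psfSigma, bg0), fn = res,
                       lower = c(cx - 3, cy - 3, 0, 0.3, -Inf),
                       upper = c(cx + 3, cy + 3, Inf, 4, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (p[3] <= 0 || p[4] <= 0.3 + 1e-9 || p[4] >= 4 - 1e-9) return(NULL)
  data.frame(x = p[1], y = p[2], amplitude = p[3], sigma = p[4], bg = p[5])
}

#' Detect single-molecule candidates in one image
#'
#' Local maxima of the sigma = 1 blurred image above an adaptive threshold
#' (`bg + k * noise`, background and noise estimated as median and MAD of
#' the blurred image), refined to sub-pixel positions by least-squares
#' fitting of an integrated 2D Gaussian plus constant background.
#'
#' @param image photon image (matrix).
#' @param k detection threshold in units of local noise sd.
#' @param psfSigma expected spot width (px).
#' @param margin candidates closer than this to the border are skipped (px).
#' @return data.frame with columns `x`, `y` (px, 0-based), `amplitude`
#'   (total photons), `sigma`, `bg`; zero rows when nothing is found.
#' @export
detectSpots <- function(image, k = 4, psfSigma = 1, margin = 3) {
  b <- blurForDetection(image, psfSigma)
  bg <- stats::median(b)
  noise <- stats::mad(b)
  h <- nrow(b); w <- ncol(b)
  core <- b[2:(h - 1), 2:(w - 1)]
  isMax <- core >= b[1:(h - 2), 2:(w - 1)] & core >= b[3:h, 2:(w - 1)] &
    core >= b[2:(h - 1), 1:(w - 2)] & core >= b[2:(h - 1), 3:w] &
    core >= b[1:(h - 2), 1:(w - 2)] & core >= b[1:(h - 2), 3:w] &
    core >= b[3:h, 1:(w - 2)] & core >= b[3:h, 3:w] &
    core > bg + k * noise
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(), y = numeric(),
                                    amplitude = numeric(), sigma = numeric(),
                                    bg = numeric()))
  cy <- idx[, 1]; cx <- idx[, 2]      # already 0-based thanks to the crop
  keep <- cx >= margin & cx <= w - 1 - margin & cy >= margin & cy <= h - 1 - margin
  out <- vector("list", sum(keep))
  n <- 0
  for (i in which(keep)) {
    f <- fitGaussianSpot(image, cx[i], cy[i], psfSigma)
    if (!is.null(f) && abs(f$x - cx[i]) <= 2 && abs(f$y - cy[i]) <= 2) {
      n <- n + 1; out[[n]] <- f
    }
  }
  if (n == 0) return(data.frame(x = numeric(), y = numeric(),
                                amplitude = numeric(), sigma = numeric(),
                                bg = numeric()))
  res <- do.call(rbind, out[seq_len(n)])
  res[order(res$x, res$y), , drop = FALSE]
}

#' Detect candidates across an alternating-excitation movie
#'
#' Green-excitation detections come from the sum image
#' `warp(Im_DD) + Im_DA` (so that both low- and high-FRET molecules are
#' seen), red-excitation detections from `Im_AA`; the two streams are
#' interlaced in recording order (interlaced frame index
#' `2 * pair + {0 green, 1 red}`).
#'
#' @param movie a [FretMovie-class] in photons (see [movieToPhotons()]).
#' @param transform donor-to-acceptor [AffineTransform-class], or NULL when
#'   the channels are already aligned.
#' @param k detection threshold (noise sds).
#' @param psfSigma expected spot width (px).
#' @return data.frame with columns `frame` (interlaced), `pairIndex`,
#'   `excitation` ("green"/"red"), `x`, `y`, `amplitude`, `sigma`.
#' @export
detectCandidates <- function(movie, transform = NULL, k = 4, psfSigma = 1) {
  stopifnot(movie@unit == "photons")
  n <- nFramePairs(movie)
  out <- vector("list", 2L * n)
  for (p in seq_len(n)) {
    ddImg <- movie@dd[, , p]
    if (!is.null(transform)) ddImg <- warpImage(ddImg, transform)
    green <- detectSpots(ddImg + movie@da[, , p], k = k, psfSigma = psfSigma)
    red <- detectSpots(movie@aa[, , p], k = k, psfSigma = psfSigma)
    if (nrow(green))
      out[[2L * p - 1L]] <- cbind(frame = 2L * (p - 1L), pairIndex = p - 1L,
                                  excitation = "green", green)
    if (nrow(red))
      out[[2L * p]] <- cbind(frame = 2L * (p - 1L) + 1L, pairIndex = p - 1L,
                             excitation = "red", red)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(frame = integer(), pairIndex = integer(),
                      excitation = character(), x = numeric(), y = numeric(),
                      amplitude = numeric(), sigma = numeric(), bg = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link localizations into trajectories
#'
#' Nearest-neighbour linking over the interlaced frame sequence with a
#' maximum search radius of 800 nm between consecutive frames and gap
#' closing over up to `memory` missed frame pairs (time points). Missing
#' frame pairs inside a trajectory are filled by linear interpolation of the
#' positions and flagged. Trajectories with fewer than `minLength` observed
#' frame pairs are discarded. Input order does not affect the result
#' (detections are sorted deterministically first).
#'
#' @param locs localization table from [detectCandidates()].
#' @param searchRadius maximum displacement between consecutive frames (nm).
#' @param memory maximum gap length (frame pairs).
#' @param minLength minimum number of observed frame pairs.
#' @param pixelSize pixel size (nm).
#' @return data.frame with columns `molecule`, `frame` (= pair index), `x`,
#'   `y` (px, acceptor-channel geometry), `interpolated`, `nDetections`.
#' @export
linkTrajectories <- function(locs, searchRadius = 800, memory = 3,
                             minLength = 4, pixelSize = 160) {
  if (!nrow(locs))
    return(data.frame(molecule = integer(), frame = integer(), x = numeric(),
                      y = numeric(), interpolated = logical(),
                      nDetections = integer()))
  rPx <- searchRadius / pixelSize
  locs <- locs[order(locs$frame, locs$x, locs$y), , drop = FALSE]
  nLoc <- nrow(locs)
  trackOf <- integer(nLoc)
  lastX <- lastY <- numeric(0); lastF <- integer(0)
  nTracks <- 0L
  maxGap <- 2L * (memory + 1L)   # memory counted in frame pairs
  for (f in sort(unique(locs$frame))) {
    di <- which(locs$frame == f)
    active <- which(f - lastF >= 1L & f - lastF <= maxGap)
    if (length(active) && length(di)) {
      dx <- outer(lastX[active], locs$x[di], "-")
      dy <- outer(lastY[active], locs$y[di], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= rPx, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dist[cand]), , drop = FALSE]
        usedT <- logical(length(active)); usedD <- logical(length(di))
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; dj <- cand[r, 2]
          if (!usedT[ti] && !usedD[dj]) {
            usedT[ti] <- TRUE; usedD[dj] <- TRUE
            tid <- active[ti]
            trackOf[di[dj]] <- tid
            lastX[tid] <- locs$x[di[dj]]; lastY[tid] <- locs$y[di[dj]]
            lastF[tid] <- f
          }
        }
        di <- di[!usedD]
      }
    }
    for (j in di) {  # unmatched detections start new tracks
      nTracks <- nTracks + 1L
      trackOf[j] <- nTracks
      lastX[nTracks] <- locs$x[j]; lastY[nTracks] <- locs$y[j]
      lastF[nTracks] <- f
    }
  }
  locs$molecule <- trackOf
  out <- vector("list", nTracks)
  newId <- 0L
  for (tid in seq_len(nTracks)) {
    tl <- locs[locs$molecule == tid, , drop = FALSE]
    obsPairs <- sort(unique(tl$pairIndex))
    if (length(obsPairs) < minLength) next
    newId <- newId + 1L
    pAll <- obsPairs[1]:obsPairs[length(obsPairs)]
    px <- vapply(obsPairs, function(p) mean(tl$x[tl$pairIndex == p]), 0)
    py <- vapply(obsPairs, function(p) mean(tl$y[tl$pairIndex == p]), 0)
    nd <- vapply(obsPairs, function(p) sum(tl$pairIndex == p), 0L)
    xi <- stats::approx(obsPairs, px, xout = pAll)$y
    yi <- stats::approx(obsPairs, py, xout = pAll)$y
    out[[newId]] <- data.frame(
      molecule = newId, frame = pAll, x = xi, y = yi,
      interpolated = !(pAll %in% obsPairs),
      nDetections = nd[match(pAll, obsPairs)])
  }
  if (newId == 0L)
    return(data.frame(molecule = integer(), frame = integer(), x = numeric(),
                      y = numeric(), interpolated = logical(),
                      nDetections = integer()))
  res <- do.call(rbind, out[seq_len(newId)])
  res$nDetections[is.na(res$nDetections)] <- 0L
  rownames(res) <- NULL
  res
}

# ring/circle pixel offsets around a centre pixel, cached per geometry
circleOffsets <- function(fgRadius, ringOuter) {
  r <- ceiling(ringOuter)
  dx <- rep(-r:r, each = 2 * r + 1)
  dy <- rep(-r:r, times = 2 * r + 1)
  dist <- sqrt(dx^2 + dy^2)
  list(dx = dx, dy = dy, fg = dist <= fgRadius,
       ring = dist > fgRadius & dist <= ringOuter)
}

#' Measure background-corrected brightness at one position
#'
#' Sums the signal in a circular foreground region (default diameter 9 px)
#' around the rounded position after subtracting the mean background of a
#' surrounding ring, excluding ring pixels affected by nearby signals. When
#' the whole ring is excluded, the global image median is used and the
#' record flagged.
#'
#' @param image (blurred) photon image.
#' @param x,y position (px, 0-based).
#' @param others n x 2 matrix of other molecules' positions in the same
#'   frame (px), used for exclusion and overlap flagging; may be NULL.
#' @param fgRadius foreground circle radius (px).
#' @param ringOuter outer radius of the background ring (px).
#' @return list with `f` (photons), `overlap`, `edge`, `bgGlobal` flags and
#'   the background level `bg`.
#' @export
measureBrightness <- function(image, x, y, others = NULL, fgRadius = 4.5,
                              ringOuter = 7.5) {
  h <- nrow(image); w <- ncol(image)
  cx <- round(x); cy <- round(y)
  if (cx < ringOuter || cx > w - 1 - ringOuter ||
      cy < ringOuter || cy > h - 1 - ringOuter)
    return(list(f = NA_real_, overlap = FALSE, edge = TRUE,
                bgGlobal = FALSE, bg = NA_real_))
  off <- circleOffsets(fgRadius, ringOuter)
  px <- cx + off$dx; py <- cy + off$dy
  inField <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  nearOther <- rep(FALSE, length(px))
  if (!is.null(others) && nrow(others)) {
    for (i in seq_len(nrow(others))) {
      d2 <- (px - others[i, 1])^2 + (py - others[i, 2])^2
      nearOther <- nearOther | d2 <= fgRadius^2
    }
  }
  fgIdx <- off$fg & inField
  ringIdx <- off$ring & inField & !nearOther
  vals <- function(sel) image[cbind(py[sel] + 1, px[sel] + 1)]
  bgGlobal <- FALSE
  if (!any(ringIdx)) {
    bg <- stats::median(image)
    bgGlobal <- TRUE
  } else bg <- mean(vals(ringIdx))
  f <- sum(vals(fgIdx)) - bg * sum(fgIdx)
  list(f = f, overlap = any(nearOther[off$fg & inField]), edge = FALSE,
       bgGlobal = bgGlobal, bg = bg)
}

#' Brightness triplets along trajectories
#'
#' For each trajectory record, measures f_DD, f_DA and f_AA on the sigma = 1
#' blurred photon images at the trajectory position (f_DD at the position
#' mapped back to donor-channel geometry via the inverse transform), applies
#' laser-profile correction, and flags records with overlapping foreground
#' circles or too close to the border.
#'
#' @param movie a [FretMovie-class] in photons.
#' @param traj trajectory table from [linkTrajectories()].
#' @param transform donor-to-acceptor [AffineTransform-class] or NULL.
#' @param greenProfile,redProfile laser profile matrices or NULL.
#' @param fgRadius,ringOuter brightness geometry (px).
#' @param psfSigma blur width applied before measuring (px).
#' @return `traj` with added columns `t`, `f_dd`, `f_da`, `f_aa`, `overlap`,
#'   `edge`, `bgGlobal`.
#' @export
measureTrajectoryBrightness <- function(movie, traj, transform = NULL,
                                        greenProfile = NULL,
                                        redProfile = NULL, fgRadius = 4.5,
                                        ringOuter = 7.5, psfSigma = 1) {
  stopifnot(movie@unit == "photons")
  traj$t <- movie@times[traj$frame + 1L]
  traj$f_dd <- traj$f_da <- traj$f_aa <- NA_real_
  traj$overlap <- traj$edge <- traj$bgGlobal <- FALSE
  invT <- if (!is.null(transform)) invertAffine(transform) else NULL
  for (p in sort(unique(traj$frame))) {
    rows <- which(traj$frame == p)
    ddB <- blurForDetection(movie@dd[, , p + 1L], psfSigma)
    daB <- blurForDetection(movie@da[, , p + 1L], psfSigma)
    aaB <- blurForDetection(movie@aa[, , p + 1L], psfSigma)
    pos <- cbind(traj$x[rows], traj$y[rows])
    posD <- if (is.null(invT)) pos else applyAffine(invT, pos)
    for (j in seq_along(rows)) {
      others <- pos[-j, , drop = FALSE]
      othersD <- posD[-j, , drop = FALSE]
      mDD <- measureBrightness(ddB, posD[j, 1], posD[j, 2], othersD,
                               fgRadius, ringOuter)
      mDA <- measureBrightness(daB, pos[j, 1], pos[j, 2], others,
                               fgRadius, ringOuter)
      mAA <- measureBrightness(aaB, pos[j, 1], pos[j, 2], others,
                               fgRadius, ringOuter)
      pg <- if (is.null(greenProfile)) 1 else
        profileAt(greenProfile, pos[j, 1], pos[j, 2])
      pr <- if (is.null(redProfile)) 1 else
        profileAt(redProfile, pos[j, 1], pos[j, 2])
      r <- rows[j]
      traj$f_dd[r] <- mDD$f / pg
      traj$f_da[r] <- mDA$f / pg
      traj$f_aa[r] <- mAA$f / pr
      traj$overlap[r] <- mDD$overlap || mDA$overlap || mAA$overlap
      traj$edge[r] <- mDD$edge || mDA$edge || mAA$edge
      traj$bgGlobal[r] <- mDD$bgGlobal || mDA$bgGlobal || mAA$bgGlobal
    }
  }
  traj
}
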