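# Time-resolved analyses: ergodicity ratio, loading-rate fitting, contact
# time pooling, MSD diffusion fitting, and mobility classification.

#' Ergodicity ratio of single-molecule force trajectories
#'
#' Selects trajectories with at least `minPoints` efficiency values below
#' `lowFretCut` (those unambiguously in the stretched population), computes
#' the force standard deviation of each such trajectory, averages them
#' (std_local) and divides by the standard deviation of all selected force
#' values pooled (std_global). Values near 1 indicate that single molecules
#' sample the full force distribution within one trajectory.
#'
#' @param records record table with columns `molecule`, `e`, `force`.
#' @param frameRate acquisition frame rate (fps), carried through as
#'   metadata.
#' @param lowFretCut efficiency cut selecting stretched-sensor records.
#' @param minPoints minimum qualifying records per trajectory.
#' @return list with `stdLocal`, `stdGlobal`, `ratio`, `nTrajectories`,
#'   `nRecords`, `frameRate`.
#' @export
ergodicityRatio <- function(records, frameRate = NA_real_, lowFretCut = 0.6,
                            minPoints = 5) {
  sel <- records[is.finite(records$e) & records$e < lowFretCut, , drop = FALSE]
  cnt <- table(sel$molecule)
  keep <- names(cnt)[cnt >= minPoints]
  if (!length(keep)) stop("no trajectories qualify for the ergodicity ratio")
  sel <- sel[sel$molecule %in% keep, , drop = FALSE]
  perTraj <- tapply(sel$force, sel$molecule, stats::sd)
  stdLocal <- mean(perTraj)
  stdGlobal <- stats::sd(sel$force)
  list(stdLocal = stdLocal, stdGlobal = stdGlobal,
       ratio = stdLocal / stdGlobal, nTrajectories = length(keep),
       nRecords = nrow(sel), frameRate = frameRate)
}

# peak of a force trace: maximum of the 3-point running-median filtered trace
findForcePeak <- function(force, smooth = 3) {
  m <- stats::runmed(force, smooth)
  which.max(m)
}

#' Pooled loading-rate fit of synchronised force ramps
#'
#' Each trace's peak is identified on a median-filtered version of the
#' force trace; traces are time-shifted so the peaks coincide; the rising
#' phase of each trace — the contiguous stretch ending at the peak that
#' starts where the filtered trace last crosses `startFraction` of the
#' peak-to-baseline height (a noise-robust surrogate for the last minimum
#' before the peak) — is pooled over traces; the pooled points are fitted
#' with a straight line whose slope is the loading rate.
#'
#' @param traces list of data.frames with columns `time` (s), `force` (pN).
#' @param smooth running-median window for peak finding (odd).
#' @param startFraction fractional peak height at which the rising phase
#'   starts.
#' @return list with `loadingRate` (pN/s), `nTraces`, `nPoints`, `pooled`
#'   (aligned rising-phase points), `meanTrace` (per-aligned-time mean
#'   force), and `skipped` (indices of traces without identifiable peak).
#' @export
poolAndFitLoadingRate <- function(traces, smooth = 5, startFraction = 0.05) {
  pooled <- list()
  skipped <- integer(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    n <- length(tr$force)
    w <- min(smooth, if (n %% 2) n else n - 1)
    m <- stats::runmed(tr$force, w)
    pk <- which.max(m)
    if (pk <= 2 || pk >= length(m)) {  # no interior peak -> skip
      skipped <- c(skipped, i)
      next
    }
    base <- min(m[1:pk])
    below <- which(m[1:pk] <= base + startFraction * (m[pk] - base))
    start <- if (length(below)) max(below) else 1L
    if (pk - start < 2) {
      skipped <- c(skipped, i)
      next
    }
    idx <- start:pk
    pooled[[length(pooled) + 1]] <- data.frame(
      trace = i, time = tr$time[idx] - tr$time[pk], force = tr$force[idx])
  }
  if (length(pooled) < 2)
    stop("need at least 2 traces with an identifiable force peak")
  pooled <- do.call(rbind, pooled)
  fit <- stats::lm(force ~ time, data = pooled)
  tBin <- round(pooled$time, 6)
  meanTrace <- stats::aggregate(force ~ time,
                                data = data.frame(time = tBin,
                                                  force = pooled$force),
                                FUN = mean)
  list(loadingRate = unname(stats::coef(fit)[2]),
       nTraces = length(unique(pooled$trace)), nPoints = nrow(pooled),
       pooled = pooled, meanTrace = meanTrace, skipped = skipped)
}

#' Group records by time since first cell contact
#'
#' Records are assigned to consecutive half-open windows
#' `[0, w), [w, 2w), ...` of the annotated contact time; records with
#' missing annotation go to group `"unknown"`.
#'
#' @param records record table with a contact-time column (minutes).
#' @param window window length (minutes).
#' @param timeColumn name of the contact-time column.
#' @return named list of record tables, labels `"0-5"`, `"5-10"`, ...
#' @export
poolByContactTime <- function(records, window = 5,
                              timeColumn = "contactTime") {
  tt <- records[[timeColumn]]
  idx <- floor(tt / window)
  lab <- ifelse(is.na(idx), "unknown",
                paste0(idx * window, "-", (idx + 1) * window))
  split(records, lab)
}

#' Diffusion coefficient from mean squared displacements
#'
#' Squared displacements are pooled over all trajectories for each lag
#' 1..`maxLag` (lag time = lag x `dt`). In each of `nBoot` bootstrap rounds
#' the data are resampled with replacement, the per-lag sets averaged, and
#' MSD = 4 D t_lag + 4 eps^2 is fitted by least squares; reported values are
#' the mean +/- sd (standard error) over the rounds.
#'
#' Two resampling units are available: `"displacements"` resamples each
#' per-lag displacement set independently, which quantifies the marginal
#' dispersion of the MSD points; `"tracks"` resamples whole trajectories,
#' which additionally propagates the correlation between overlapping
#' displacements of one trajectory and therefore gives a standard error
#' calibrated against repeated experiments (see the methods vignette).
#'
#' @param tracks data.frame with columns `molecule`, `frame`, `x_um`,
#'   `y_um`.
#' @param dt frame interval (s), i.e. illumination time plus delay.
#' @param maxLag largest lag (frames).
#' @param nBoot bootstrap rounds.
#' @param resample bootstrap unit, `"displacements"` or `"tracks"`.
#' @param seed integer seed.
#' @return list with `D`, `DSe` (um^2/s), `epsilon`, `epsilonSe` (um),
#'   `msd` (per-lag means of the original data), `lagTimes` (s), `nPerLag`.
#' @export
msdFit <- function(tracks, dt, maxLag = 10, nBoot = 100,
                   resample = c("displacements", "tracks"), seed = NULL) {
  resample <- match.arg(resample)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(tracks$molecule)
  sqByTrack <- vector("list", length(ids))
  for (ti in seq_along(ids)) {
    tr <- tracks[tracks$molecule == ids[ti], , drop = FALSE]
    if (nrow(tr) < 2) next
    tr <- tr[order(tr$frame), ]
    sqByTrack[[ti]] <- lapply(seq_len(maxLag), function(L) {
      j <- match(tr$frame + L, tr$frame)
      ok <- !is.na(j)
      if (!any(ok)) return(numeric(0))
      (tr$x_um[j[ok]] - tr$x_um[ok])^2 + (tr$y_um[j[ok]] - tr$y_um[ok])^2
    })
  }
  sqByTrack <- sqByTrack[!vapply(sqByTrack, is.null, TRUE)]
  sq <- lapply(seq_len(maxLag), function(L)
    unlist(lapply(sqByTrack, `[[`, L)))
  nPerLag <- lengths(sq)
  useLags <- which(nPerLag > 0)
  if (length(useLags) < 2) stop("not enough displacement data for an MSD fit")
  tl <- useLags * dt
  fitOne <- function(msd) {
    cf <- stats::coef(stats::lm(msd ~ tl))
    c(cf[2] / 4, sqrt(max(cf[1], 0) / 4))
  }
  Ds <- eps <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    if (resample == "displacements") {
      msd <- vapply(useLags, function(L)
        mean(sample(sq[[L]], nPerLag[L], replace = TRUE)), 0)
    } else {
      pick <- sample.int(length(sqByTrack), length(sqByTrack), replace = TRUE)
      msd <- vapply(useLags, function(L)
        mean(unlist(lapply(sqByTrack[pick], `[[`, L))), 0)
    }
    de <- fitOne(msd)
    Ds[b] <- de[1]; eps[b] <- de[2]
  }
  msd0 <- vapply(useLags, function(L) mean(sq[[L]]), 0)
  list(D = mean(Ds), DSe = stats::sd(Ds), epsilon = mean(eps),
       epsilonSe = stats::sd(eps), msd = msd0, lagTimes = tl,
       nPerLag = nPerLag[useLags])
}

# ---- smallest enclosing circle (Welzl-type incremental algorithm) --------

secContains <- function(c, p) {
  !is.null(c) &&
    sqrt((p[1] - c$center[1])^2 + (p[2] - c$center[2])^2) <=
      c$radius * (1 + 1e-12) + 1e-14
}

secDiameter <- function(a, b) {
  ctr <- (a + b) / 2
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

secCircum <- function(a, b, c) {
  ox <- (min(a[1], b[1], c[1]) + max(a[1], b[1], c[1])) / 2
  oy <- (min(a[2], b[2], c[2]) + max(a[2], b[2], c[2])) / 2
  ax <- a[1] - ox; ay <- a[2] - oy
  bx <- b[1] - ox; by <- b[2] - oy
  cx <- c[1] - ox; cy <- c[2] - oy
  d <- (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by)) * 2
  if (abs(d) < 1e-14) return(NULL)
  x <- ox + ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
  y <- oy + ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(x, y)
  list(center = ctr,
       radius = max(sqrt(sum((a - ctr)^2)), sqrt(sum((b - ctr)^2)),
                    sqrt(sum((c - ctr)^2))))
}

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
  (a[2] - o[2]) * (b[1] - o[1])

secTwoPoints <- function(pts, p, q) {
  circ <- secDiameter(p, q)
  left <- right <- NULL
  pq <- q - p
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, ]
    if (secContains(circ, r)) next
    cr <- cross2(p, q, r)
    c2 <- secCircum(p, q, r)
    if (is.null(c2)) next
    cc <- cross2(p, q, c2$center)
    if (cr > 0 && (is.null(left) || cc > cross2(p, q, left$center)))
      left <- c2
    else if (cr < 0 && (is.null(right) || cc < cross2(p, q, right$center)))
      right <- c2
  }
  if (is.null(left) && is.null(right)) circ
  else if (is.null(left)) right
  else if (is.null(right)) left
  else if (left$radius <= right$radius) left else right
}

secOnePoint <- function(pts, p) {
  c <- list(center = p, radius = 0)
  for (i in seq_len(nrow(pts))) {
    q <- pts[i, ]
    if (secContains(c, q)) next
    c <- if (c$radius == 0) secDiameter(p, q)
    else secTwoPoints(pts[seq_len(i), , drop = FALSE], p, q)
  }
  c
}

#' Smallest enclosing circle of a point set
#'
#' Exact minimal circle containing all points (Welzl-type incremental
#' construction; deterministic).
#'
#' @param xy n x 2 coordinate matrix.
#' @return list with `center` (length 2) and `radius`.
#' @export
smallestEnclosingCircle <- function(xy) {
  xy <- rbind(as.matrix(xy))
  stopifnot(ncol(xy) == 2, nrow(xy) >= 1)
  c <- NULL
  for (i in seq_len(nrow(xy))) {
    p <- xy[i, ]
    if (!secContains(c, p))
      c <- secOnePoint(xy[seq_len(i), , drop = FALSE], p)
  }
  c
}

#' Classify a trajectory as mobile or immobilized
#'
#' The radius r_c of the smallest circle enclosing the trajectory scales
#' with the square root of the observation time t_d for free diffusion, so
#' r_c / sqrt(t_d) separates immobilized from mobile molecules; the
#' standard threshold is 0.35 um s^-0.5.
#'
#' @param xy n x 2 positions (um), n >= 3.
#' @param duration trajectory duration t_d (s).
#' @param threshold classification boundary (um s^-0.5).
#' @return list with `rc` (um), `td` (s), `statistic` (um s^-0.5), `class`
#'   (`"mobile"` or `"immobilized"`).
#' @export
classifyMobility <- function(xy, duration, threshold = 0.35) {
  xy <- rbind(as.matrix(xy))
  stopifnot(nrow(xy) >= 3, duration > 0)
  sec <- smallestEnclosingCircle(xy)
  stat <- sec$radius / sqrt(duration)
  list(rc = sec$radius, td = duration, statistic = stat,
       class = if (stat >= threshold) "mobile" else "immobilized")
}
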