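# Trajectory quality-control filter chain:
# laser region -> overlap -> first frame -> photobleaching -> truncation ->
# stoichiometry -> cell mask.

#' Remove records outside the bright laser region
#'
#' Drops records located where the donor excitation profile is below
#' `threshold` (default: 50 percent of the maximum intensity).
#'
#' @param records record table with columns `x`, `y`.
#' @param profile donor laser profile matrix (max 1).
#' @param threshold minimum relative intensity.
#' @return filtered record table.
#' @export
filterLaserRegion <- function(records, profile, threshold = 0.5) {
  if (!nrow(records)) return(records)
  keep <- profileAt(profile, records$x, records$y) >= threshold
  records[keep, , drop = FALSE]
}

#' Overlap filter
#'
#' Trajectories in which more than `maxFraction` of the records have
#' overlapping foreground circles are dropped entirely; in the remaining
#' trajectories only the overlapping records are removed. Edge records are
#' treated like overlapping ones (their brightness is not measurable).
#'
#' @param records record table with columns `molecule`, `overlap`, `edge`.
#' @param maxFraction trajectory-level rejection threshold.
#' @return filtered record table.
#' @export
filterOverlap <- function(records, maxFraction = 0.25) {
  if (!nrow(records)) return(records)
  bad <- records$overlap | records$edge
  fracBad <- tapply(bad, records$molecule, mean)
  dropMol <- as.numeric(names(fracBad))[fracBad > maxFraction]
  keep <- !(records$molecule %in% dropMol) & !bad
  records[keep, , drop = FALSE]
}

#' Keep only trajectories present in the first frame
#'
#' Ensures the full photobleaching profile of each retained trajectory is
#' available.
#'
#' @param records record table with columns `molecule`, `frame`.
#' @return filtered record table.
#' @export
filterFirstFrame <- function(records) {
  if (!nrow(records)) return(records)
  first <- tapply(records$frame, records$molecule, min)
  keepMol <- as.numeric(names(first))[first == 0]
  records[records$molecule %in% keepMol, , drop = FALSE]
}

#' Detect intensity steps in a time trace
#'
#' Piecewise-constant changepoint fit by greedy binary segmentation with a
#' BIC stopping rule, followed by merging of steps whose amplitude is below
#' `minAmplitude` noise standard deviations (noise estimated from first
#' differences). Used to find single-step photobleaching events.
#'
#' @param trace numeric vector (photon values), length >= 4.
#' @param minAmplitude amplitude significance threshold (noise sds).
#' @param minSegment minimum plateau length (frames).
#' @return list with `stepFrames` (1-based index of the first frame at the
#'   new level), `amplitudes` (new minus old level), `nSteps`, `levels`
#'   (plateau means) and `noiseSd`.
#' @export
detectSteps <- function(trace, minAmplitude = 3, minSegment = 2) {
  n <- length(trace)
  stopifnot(n >= 4)
  noiseSd <- stats::mad(diff(trace)) / sqrt(2)
  if (noiseSd == 0) noiseSd <- stats::sd(diff(trace)) / sqrt(2)
  if (is.na(noiseSd) || noiseSd == 0) noiseSd <- 1e-12
  # greedy binary segmentation: repeatedly take the split that most reduces
  # the residual sum of squares, accept while BIC improves
  bounds <- c(0L, n)  # segment boundaries (split after these indices)
  css <- function(x) sum(x^2) - sum(x)^2 / length(x)
  repeat {
    segs <- cbind(head(bounds, -1) + 1L, bounds[-1])
    best <- NULL; bestGain <- 0
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, 1]; b <- segs[s, 2]
      if (b - a + 1 < 2 * minSegment) next
      x <- trace[a:b]
      tot <- css(x)
      m <- length(x)
      cl <- cumsum(x); cl2 <- cumsum(x^2)
      i <- minSegment:(m - minSegment)
      left <- cl2[i] - cl[i]^2 / i
      right <- (cl2[m] - cl2[i]) - (cl[m] - cl[i])^2 / (m - i)
      gain <- tot - (left + right)
      gi <- which.max(gain)
      if (gain[gi] > bestGain) {
        bestGain <- gain[gi]
        best <- a - 1L + i[gi]
      }
    }
    if (is.null(best)) break
    rssOld <- sum(vapply(seq_len(nrow(segs)), function(s)
      css(trace[segs[s, 1]:segs[s, 2]]), 0))
    rssNew <- rssOld - bestGain
    # BIC penalty: 2 parameters (mean + changepoint) per split
    if (n * log(max(rssNew, 1e-300) / n) + 2 * log(n) <
        n * log(max(rssOld, 1e-300) / n)) {
      bounds <- sort(c(bounds, best))
    } else break
  }
  # merge insignificant steps; significance is judged against the local
  # plateau noise (shot noise differs strongly between bright and bleached
  # segments, so a global estimate would be misleading)
  localNoise <- function(a, b, cut) {
    s1 <- if (cut - a >= 1) stats::sd(trace[a:cut]) else NA_real_
    s2 <- if (b - cut >= 2) stats::sd(trace[(cut + 1):b]) else NA_real_
    max(c(s1, s2, noiseSd), na.rm = TRUE)
  }
  repeat {
    segs <- cbind(head(bounds, -1) + 1L, bounds[-1])
    lev <- vapply(seq_len(nrow(segs)), function(s)
      mean(trace[segs[s, 1]:segs[s, 2]]), 0)
    if (length(lev) < 2) break
    amp <- abs(diff(lev))
    rel <- vapply(seq_along(amp), function(j)
      amp[j] / localNoise(segs[j, 1], segs[j + 1, 2], segs[j, 2]), 0)
    j <- which.min(rel)
    if (rel[j] < minAmplitude) bounds <- bounds[-(j + 1L)] else break
  }
  segs <- cbind(head(bounds, -1) + 1L, bounds[-1])
  lev <- vapply(seq_len(nrow(segs)), function(s)
    mean(trace[segs[s, 1]:segs[s, 2]]), 0)
  list(stepFrames = if (nrow(segs) > 1) segs[-1, 1] else integer(0),
       amplitudes = diff(lev), nSteps = nrow(segs) - 1L, levels = lev,
       noiseSd = noiseSd)
}

#' Photobleaching filter for one trajectory
#'
#' A trajectory is accepted when its f_AA trace shows exactly one (downward)
#' photobleaching step and the total donor-excited trace f_DD + f_DA shows
#' no partial photobleaching, i.e. no downward step to a plateau
#' significantly above background. A terminal donor bleach to background is
#' allowed and, like the acceptor bleach, defines the truncation point:
#' records from the earliest bleaching step onward are discarded.
#'
#' @param faa f_AA trace (photons).
#' @param fsum f_DD + f_DA trace (photons).
#' @param minAmplitude step significance (noise sds).
#' @param bgLevel photon level considered background (default 0 with
#'   3 x noise tolerance).
#' @return list with `accepted`, `truncateBefore` (1-based frame index of
#'   the earliest bleach; records at or after it are removed), `nStepsAA`.
#' @export
bleachFilter <- function(faa, fsum, minAmplitude = 3, bgLevel = 0) {
  sa <- detectSteps(faa, minAmplitude)
  downA <- which(sa$amplitudes < 0)
  if (length(downA) != 1L || sa$nSteps != 1L)
    return(list(accepted = FALSE, truncateBefore = NA_integer_,
                nStepsAA = sa$nSteps))
  # acceptor plateau after the bleach must be at background
  if (sa$levels[2] > bgLevel + 3 * sa$noiseSd)
    return(list(accepted = FALSE, truncateBefore = NA_integer_,
                nStepsAA = sa$nSteps))
  truncAt <- sa$stepFrames[1]
  ss <- detectSteps(fsum, minAmplitude)
  if (ss$nSteps > 0) {
    down <- which(ss$amplitudes < 0)
    for (j in down) {
      postLevel <- ss$levels[j + 1]
      if (postLevel > bgLevel + 3 * ss$noiseSd) {
        # partial donor bleach (multi-emitter or defective sensor)
        return(list(accepted = FALSE, truncateBefore = NA_integer_,
                    nStepsAA = 1L))
      }
      truncAt <- min(truncAt, ss$stepFrames[j])  # terminal donor bleach
    }
  }
  list(accepted = TRUE, truncateBefore = truncAt, nStepsAA = 1L)
}

#' Apply the photobleaching filter to a record table
#'
#' @param records record table with `molecule`, `frame`, `f_dd`, `f_da`,
#'   `f_aa`, sorted by frame within molecule.
#' @param minAmplitude step significance (noise sds).
#' @return records of accepted trajectories, truncated before the earliest
#'   bleaching step, with a `truncated` marker column. Records that already
#'   carry the marker pass through unchanged, which makes the filter (and
#'   the whole QC chain) idempotent.
#' @export
filterBleaching <- function(records, minAmplitude = 3) {
  if (!nrow(records)) return(records)
  if (!is.null(records$truncated) && all(records$truncated)) return(records)
  keep <- rep(FALSE, nrow(records))
  for (m in unique(records$molecule)) {
    idx <- which(records$molecule == m)
    idx <- idx[order(records$frame[idx])]
    if (length(idx) < 4) next
    bf <- bleachFilter(records$f_aa[idx], records$f_dd[idx] + records$f_da[idx],
                       minAmplitude)
    if (bf$accepted) keep[idx[seq_len(bf$truncateBefore - 1L)]] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  out$truncated <- TRUE
  out
}

#' Stoichiometry filter
#'
#' Removes trajectories in which more than `maxFraction` of the records have
#' S above `sMax` (two or more donors per acceptor) or below `sMin` (two or
#' more acceptors per donor).
#'
#' @param records record table with columns `molecule`, `s`.
#' @param sMin,sMax stoichiometry bounds.
#' @param maxFraction trajectory rejection threshold.
#' @return filtered record table.
#' @export
filterStoichiometry <- function(records, sMin = 0.35, sMax = 0.6,
                                maxFraction = 0.25) {
  if (!nrow(records)) return(records)
  out <- records$s > sMax | records$s < sMin | !is.finite(records$s)
  frac <- tapply(out, records$molecule, mean)
  dropMol <- as.numeric(names(frac))[frac > maxFraction]
  records[!(records$molecule %in% dropMol), , drop = FALSE]
}

#' Adaptive-threshold cell mask
#'
#' Pixels brighter than their local mean (over `blockSize` x `blockSize`
#' blocks) by more than `offset` are classified as cell. Optionally, small
#' connected components are removed.
#'
#' @param image indicator image (e.g. a calcium-dye recording).
#' @param blockSize local-mean block edge (px, odd).
#' @param offset additive threshold above the local mean (image units).
#' @param minArea connected components smaller than this are dropped
#'   (0 disables the cleanup).
#' @return logical mask matrix.
#' @export
makeCellMask <- function(image, blockSize = 51, offset = 0, minArea = 0) {
  blockSize <- min(blockSize, 2 * (min(dim(image)) %/% 2) - 1)
  local <- boxBlur(image, blockSize)
  eps <- 1e-9 * max(1, max(abs(image)))
  mask <- (image - local) > (offset + eps)
  if (minArea > 0 && any(mask)) {
    lab <- labelComponents(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- array(lab > 0 & sizes[pmax(lab, 1)] >= minArea, dim(mask))
  }
  mask
}

# 4-connected component labelling (iterative flood fill)
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (s - 1L) %% h + 1L; j <- (s - 1L) %/% h + 1L
      for (nb in c(if (i > 1) s - 1L, if (i < h) s + 1L,
                   if (j > 1) s - h, if (j < w) s + h)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

#' Select records underneath a cell
#'
#' @param records record table with `x`, `y` (px).
#' @param mask logical cell mask (from [makeCellMask()]).
#' @return records whose nearest pixel lies inside the mask; warns when the
#'   mask is empty.
#' @export
selectInMask <- function(records, mask) {
  if (!any(mask)) {
    warning("cell mask is empty; no records selected")
    return(records[integer(0), , drop = FALSE])
  }
  if (!nrow(records)) return(records)
  i <- pmin(pmax(round(records$y), 0), nrow(mask) - 1L) + 1L
  j <- pmin(pmax(round(records$x), 0), ncol(mask) - 1L) + 1L
  records[mask[cbind(i, j)], , drop = FALSE]
}

#' Run the full quality-control chain
#'
#' Applies, in order: laser-region filter, overlap filter, first-frame
#' filter, photobleaching filter with truncation, stoichiometry computation
#' via [computeES()], stoichiometry filter, and (optionally) cell-mask
#' selection. The chain is idempotent. A per-stage record count is attached
#' as attribute `qcReport`.
#'
#' @param records measured record table (see
#'   [measureTrajectoryBrightness()]).
#' @param factors [CorrectionFactors-class] for the E/S computation.
#' @param greenProfile donor laser profile or NULL to skip the laser filter.
#' @param mask cell mask or NULL to skip mask selection.
#' @param laserThreshold,overlapFraction,sMin,sMax,sFraction thresholds of
#'   the individual filters (defaults follow the standard protocol: 0.5,
#'   25 percent, S in `[0.35, 0.6]`).
#' @return filtered record table with `e` and `s` columns.
#' @export
qcChain <- function(records, factors, greenProfile = NULL, mask = NULL,
                    laserThreshold = 0.5, overlapFraction = 0.25,
                    sMin = 0.35, sMax = 0.6, sFraction = 0.25) {
  report <- c(input = nrow(records))
  if (!is.null(greenProfile))
    records <- filterLaserRegion(records, greenProfile, laserThreshold)
  report["laser"] <- nrow(records)
  records <- filterOverlap(records, overlapFraction)
  report["overlap"] <- nrow(records)
  records <- filterFirstFrame(records)
  report["firstFrame"] <- nrow(records)
  records <- filterBleaching(records)
  report["bleach"] <- nrow(records)
  records <- computeES(records, factors)
  records <- filterStoichiometry(records, sMin, sMax, sFraction)
  report["stoichiometry"] <- nrow(records)
  if (!is.null(mask)) records <- selectInMask(records, mask)
  report["mask"] <- nrow(records)
  attr(records, "qcReport") <- report
  records
}
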