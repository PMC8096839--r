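# Ensemble FRET via donor recovery after acceptor photobleaching (DRAAP).

#' Ensemble FRET efficiency from a DRAAP image pair
#'
#' Pixel-averages the donor signal in the region of interest before
#' (`f_pre`) and after (`f_post`) acceptor photobleaching and computes
#' E_bulk = (f_post - f_pre) / f_post. An optional constant background is
#' subtracted from both averages first.
#'
#' @param pre,post donor-channel images recorded before / after acceptor
#'   photobleaching (matrices of identical shape).
#' @param roi logical mask selecting the region of interest (NULL = whole
#'   image).
#' @param background constant background level subtracted from both means.
#' @param roiId,condition metadata carried into the result.
#' @return one-row data.frame with `fPre`, `fPost`, `eBulk`, `valid`,
#'   `roiId`, `condition`; `valid` is FALSE (and `eBulk` NA) when
#'   `fPost <= 0`.
#' @export
eBulk <- function(pre, post, roi = NULL, background = 0,
                  roiId = NA_character_, condition = NA_character_) {
  stopifnot(identical(dim(pre), dim(post)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pre), ncol(pre))
  stopifnot(identical(dim(roi), dim(pre)))
  fPre <- mean(pre[roi]) - background
  fPost <- mean(post[roi]) - background
  valid <- is.finite(fPost) && fPost > 0
  data.frame(fPre = fPre, fPost = fPost,
             eBulk = if (valid) (fPost - fPre) / fPost else NA_real_,
             valid = valid, roiId = roiId, condition = condition,
             stringsAsFactors = FALSE)
}

#' Cell-minus-control difference of ensemble FRET efficiencies
#'
#' delta E_bulk = E_bulk(cell) - E_bulk(no cell), for region-matched
#' measurements (the control is the same ROI geometry on a bilayer region
#' devoid of cells). Negative values indicate sensor stretching underneath
#' the cell.
#'
#' @param cell,noCell one-row measurements from [eBulk()].
#' @return delta E_bulk (numeric).
#' @export
deltaEBulk <- function(cell, noCell) {
  stopifnot(cell$valid, noCell$valid)
  cell$eBulk - noCell$eBulk
}

#' Two-group comparison by Mann-Whitney U test
#'
#' Two-sample rank test with tie correction; differences with p < 0.01 are
#' reported as significant, following the standard analysis protocol.
#'
#' @param valuesA,valuesB numeric vectors (each n >= 3).
#' @param alpha significance level.
#' @return list with `p`, `statistic` (U), `significant`, `nA`, `nB`.
#' @export
compareGroups <- function(valuesA, valuesB, alpha = 0.01) {
  stopifnot(length(valuesA) >= 3, length(valuesB) >= 3)
  ht <- suppressWarnings(stats::wilcox.test(valuesA, valuesB,
                                            exact = FALSE, correct = TRUE))
  list(p = ht$p.value, statistic = unname(ht$statistic),
       significant = ht$p.value < alpha,
       nA = length(valuesA), nB = length(valuesB))
}
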