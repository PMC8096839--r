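# Correction-factor estimation and corrected FRET efficiency / stoichiometry.
#
#   E = (f_DA - a f_DD - d f_AA) / (g f_DD + f_DA - a f_DD - d f_AA)
#   S = (g f_DD + f_DA - a f_DD - d f_AA) /
#       (g f_DD + f_DA - a f_DD - d f_AA + f_AA / b)
# with a = alpha (bleedthrough), d = delta (direct excitation),
# g = gamma (detection efficiency), b = beta (excitation efficiency).

#' Estimate the donor bleedthrough coefficient alpha
#'
#' Robust location (median) of f_DA / f_DD over donor-only records; the
#' ratio makes the estimate invariant to intensity scaling.
#'
#' @param records record table from a donor-only calibration sample with
#'   columns `f_dd`, `f_da`.
#' @param minRecords minimum number of usable records.
#' @return alpha (unitless).
#' @export
estimateAlpha <- function(records, minRecords = 50) {
  ok <- is.finite(records$f_dd) & is.finite(records$f_da) & records$f_dd > 0
  if (sum(ok) < minRecords)
    stop(sprintf("need at least %d donor-only records, got %d",
                 minRecords, sum(ok)))
  stats::median(records$f_da[ok] / records$f_dd[ok])
}

#' Estimate the direct-excitation coefficient delta
#'
#' Median of f_DA / f_AA over acceptor-only records.
#'
#' @param records acceptor-only record table with columns `f_da`, `f_aa`.
#' @param minRecords minimum number of usable records.
#' @return delta (unitless).
#' @export
estimateDelta <- function(records, minRecords = 50) {
  ok <- is.finite(records$f_aa) & is.finite(records$f_da) & records$f_aa > 0
  if (sum(ok) < minRecords)
    stop(sprintf("need at least %d acceptor-only records, got %d",
                 minRecords, sum(ok)))
  stats::median(records$f_da[ok] / records$f_aa[ok])
}

#' Estimate the detection-efficiency factor gamma
#'
#' From single-step acceptor photobleaching events in a control dataset
#' (high-FRET sensors give the largest intensity contrast): across the
#' bleach step, the crosstalk-corrected FRET signal drops and the donor
#' signal rises by the same number of excitations, so
#' gamma = -delta(f_DA - alpha f_DD - delta f_AA) / delta(f_DD). Plateaus
#' are averaged over at least `minPlateau` points on each side, excluding
#' one frame around the step; the estimator is the median over events.
#'
#' @param records record table of the control dataset (columns `molecule`,
#'   `frame`, `f_dd`, `f_da`, `f_aa`).
#' @param alpha,delta previously estimated crosstalk coefficients.
#' @param minPlateau minimum plateau points on each side of the step.
#' @return gamma with attribute `nEvents`.
#' @export
estimateGamma <- function(records, alpha, delta, minPlateau = 5) {
  gammas <- numeric(0)
  for (m in unique(records$molecule)) {
    idx <- which(records$molecule == m)
    idx <- idx[order(records$frame[idx])]
    if (length(idx) < 2 * minPlateau + 2) next
    faa <- records$f_aa[idx]
    sa <- detectSteps(faa)
    if (sa$nSteps != 1L || sa$amplitudes[1] >= 0) next
    s <- sa$stepFrames[1]
    pre <- seq_len(s - 2L)                       # exclude 1 frame pre-step
    post <- (s + 1L):length(idx)                 # exclude the step frame
    if (length(pre) < minPlateau || length(post) < minPlateau) next
    daCorr <- records$f_da[idx] - alpha * records$f_dd[idx] -
      delta * records$f_aa[idx]
    dDrop <- mean(daCorr[pre]) - mean(daCorr[post])
    dRise <- mean(records$f_dd[idx][post]) - mean(records$f_dd[idx][pre])
    if (dRise > 0) gammas <- c(gammas, dDrop / dRise)
  }
  if (!length(gammas))
    stop("no usable single-step acceptor bleaching events found")
  out <- stats::median(gammas)
  attr(out, "nEvents") <- length(gammas)
  out
}

#' Estimate the excitation-efficiency factor beta
#'
#' beta scales f_AA and is adjusted such that the median stoichiometry of a
#' calibration sample with known 1:1 labelling equals 0.5 (monotone 1D root
#' find).
#'
#' @param records calibration record table (intact 1:1 sensors).
#' @param alpha,delta,gamma fixed crosstalk and detection factors.
#' @param interval search interval for beta.
#' @return beta.
#' @export
estimateBeta <- function(records, alpha, delta, gamma,
                         interval = c(1e-3, 1e3)) {
  num <- gamma * records$f_dd + records$f_da - alpha * records$f_dd -
    delta * records$f_aa
  ok <- is.finite(num) & is.finite(records$f_aa) & num > 0 & records$f_aa > 0
  if (sum(ok) < 10) stop("too few usable calibration records")
  g <- function(b)
    stats::median(num[ok] / (num[ok] + records$f_aa[ok] / b)) - 0.5
  if (g(interval[1]) * g(interval[2]) > 0)
    stop("no beta in the search interval reaches median S = 0.5")
  stats::uniroot(g, interval, tol = 1e-10)$root
}

#' Corrected FRET efficiency and stoichiometry
#'
#' Applies the correction formulas to every record. Records with a
#' non-positive denominator are flagged (`esValid = FALSE`) and carry NaN;
#' they are excluded by the downstream filters.
#'
#' @param records record table with `f_dd`, `f_da`, `f_aa`.
#' @param factors a [CorrectionFactors-class].
#' @return `records` with added columns `e`, `s`, `esValid`.
#' @examples
#' r <- data.frame(f_dd = 100, f_da = 100, f_aa = 200)
#' computeES(r, CorrectionFactors())  # E = 0.5, S = 0.5
#' @export
computeES <- function(records, factors) {
  stopifnot(is(factors, "CorrectionFactors"))
  daCorr <- records$f_da - factors@alpha * records$f_dd -
    factors@delta * records$f_aa
  denomE <- factors@gamma * records$f_dd + daCorr
  denomS <- denomE + records$f_aa / factors@beta
  valid <- is.finite(denomE) & denomE > 0 & is.finite(denomS) & denomS > 0
  records$e <- ifelse(valid, daCorr / denomE, NaN)
  records$s <- ifelse(valid, denomE / denomS, NaN)
  records$esValid <- valid
  records
}

#' Store / load correction factors as JSON with provenance
#'
#' @param factors a [CorrectionFactors-class].
#' @param path file path.
#' @param provenance optional named list (dataset ids, event counts, ...).
#' @export
writeCorrectionFactors <- function(factors, path, provenance = list()) {
  jsonlite::write_json(
    c(list(alpha = factors@alpha, delta = factors@delta,
           gamma = factors@gamma, beta = factors@beta),
      provenance = list(provenance)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCorrectionFactors
#' @export
readCorrectionFactors <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CorrectionFactors(alpha = x$alpha, delta = x$delta, gamma = x$gamma,
                    beta = x$beta)
}
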