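#' Fit the donor-to-acceptor affine channel transform
#'
#' Least-squares affine transform mapping donor-channel fiducial
#' localizations onto their acceptor-channel partners. With
#' `robust = TRUE`, a single re-fit is performed after dropping pairs whose
#' residual exceeds 3x the median residual, which suppresses mispaired
#' beads.
#'
#' @param donor,acceptor n x 2 matrices of matched bead coordinates (px,
#'   0-based pixel centres); at least 3 non-collinear pairs.
#' @param robust drop gross outliers and refit once?
#' @return an [AffineTransform-class] with attributes `rmsResidual` (px) and
#'   `nPairs`.
#' @export
fitAffine <- function(donor, acceptor, robust = FALSE) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  stopifnot(ncol(donor) == 2, ncol(acceptor) == 2,
            nrow(donor) == nrow(acceptor))
  if (nrow(donor) < 3) stop("need at least 3 localization pairs")
  fit1 <- function(d, a) {
    X <- cbind(d, 1)
    if (qr(X)$rank < 3) stop("fiducial positions are collinear")
    beta <- qr.solve(X, a)              # 3 x 2: rows (x coef, y coef, offset)
    tr <- AffineTransform(linear = t(beta[1:2, ]), offset = beta[3, ])
    res <- sqrt(rowSums((applyAffine(tr, d) - a)^2))
    attr(tr, "rmsResidual") <- sqrt(mean(res^2))
    attr(tr, "residuals") <- res
    tr
  }
  tr <- fit1(donor, acceptor)
  if (robust) {
    # iterated trimming: outlier pairs distort the initial fit enough to
    # inflate everyone's residuals, so one pass is not always sufficient
    d <- donor; a <- acceptor
    for (it in 1:5) {
      res <- attr(tr, "residuals")
      keep <- res <= 3 * stats::median(res) + 1e-12
      if (all(keep) || sum(keep) < 3) break
      d <- d[keep, , drop = FALSE]; a <- a[keep, , drop = FALSE]
      tr <- fit1(d, a)
    }
  }
  attr(tr, "nPairs") <- nrow(donor)
  attr(tr, "residuals") <- NULL
  tr
}

#' Apply or invert an affine transform on coordinates
#'
#' @param transform an [AffineTransform-class].
#' @param xy n x 2 coordinate matrix (px).
#' @return transformed n x 2 matrix (`applyAffine`), or the inverse
#'   transform (`invertAffine`).
#' @export
applyAffine <- function(transform, xy) {
  xy <- rbind(as.matrix(xy))
  t(transform@linear %*% t(xy) + transform@offset)
}

#' @rdname applyAffine
#' @export
invertAffine <- function(transform) {
  Ainv <- solve(transform@linear)
  AffineTransform(linear = Ainv, offset = as.numeric(-Ainv %*% transform@offset))
}

#' Warp an image through an affine transform
#'
#' Resamples `image` onto the target geometry with bilinear interpolation:
#' output pixel (x, y) takes the value of the input at
#' `invertAffine(transform)` applied to (x, y). Out-of-field samples are 0.
#'
#' @param image numeric matrix (row = y + 1, col = x + 1, 0-based centres).
#' @param transform an [AffineTransform-class] mapping input coordinates to
#'   output coordinates.
#' @return warped matrix of the same shape.
#' @export
warpImage <- function(image, transform) {
  h <- nrow(image); w <- ncol(image)
  inv <- invertAffine(transform)
  grid <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
  src <- applyAffine(inv, grid)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- image[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, nrow = h, ncol = w)
}

#' Pair fiducial localizations between the two channels
#'
#' Mutual nearest neighbours within `maxDist` px after removing the median
#' translation (coarse alignment).
#'
#' @param donor,acceptor n x 2 localization matrices (px).
#' @param maxDist pairing radius (px).
#' @return list with matched `donor` and `acceptor` matrices.
#' @export
pairFiducials <- function(donor, acceptor, maxDist = 5) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  shift <- apply(acceptor, 2, stats::median) - apply(donor, 2, stats::median)
  ds <- sweep(donor, 2, -shift)          # donor coarsely aligned to acceptor
  d2 <- outer(ds[, 1], acceptor[, 1], "-")^2 + outer(ds[, 2], acceptor[, 2], "-")^2
  nnA <- apply(d2, 1, which.min)         # for each donor, closest acceptor
  nnD <- apply(d2, 2, which.min)         # for each acceptor, closest donor
  i <- seq_len(nrow(donor))
  mutual <- nnD[nnA[i]] == i & sqrt(d2[cbind(i, nnA[i])]) <= maxDist
  list(donor = donor[mutual, , drop = FALSE],
       acceptor = acceptor[nnA[i][mutual], , drop = FALSE])
}

#' Store / load an affine transform as JSON
#'
#' Serialised as a row-major 2 x 3 matrix `[A | t]` in pixel units with
#' 0-based pixel centres.
#'
#' @param transform an [AffineTransform-class].
#' @param path file path.
#' @export
writeAffineTransform <- function(transform, path) {
  m <- cbind(transform@linear, transform@offset)
  jsonlite::write_json(list(matrix = as.numeric(t(m)), order = "row-major",
                            units = "px", origin = "0-based pixel centres"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAffineTransform
#' @export
readAffineTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(x$matrix, nrow = 2, byrow = TRUE)
  AffineTransform(linear = m[, 1:2], offset = m[, 3])
}
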