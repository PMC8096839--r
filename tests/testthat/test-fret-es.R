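test_that("bleedthrough alpha is recovered from donor-only samples", {
  set.seed(151)
  rec <- makeRecords(400, class = "donor_only", alpha = 0.08)
  a <- estimateAlpha(rec)
  expect_lt(abs(a - 0.08) / 0.08, 0.05)
  # zero-crosstalk control
  rec0 <- makeRecords(400, class = "donor_only", alpha = 0)
  expect_lt(estimateAlpha(rec0), 0.005)
  # ratio estimator is invariant to intensity scaling
  recS <- rec
  recS$f_dd <- recS$f_dd * 7; recS$f_da <- recS$f_da * 7
  expect_equal(estimateAlpha(recS), a)
  expect_error(estimateAlpha(rec[1:10, ]), "at least")
})

test_that("direct excitation delta is recovered from acceptor-only samples", {
  set.seed(157)
  rec <- makeRecords(400, class = "acceptor_only", delta = 0.05)
  d <- estimateDelta(rec)
  expect_lt(abs(d - 0.05) / 0.05, 0.05)
  rec0 <- makeRecords(400, class = "acceptor_only", delta = 0)
  expect_lt(estimateDelta(rec0), 0.005)
  recS <- rec
  recS$f_aa <- recS$f_aa * 3; recS$f_da <- recS$f_da * 3
  expect_equal(estimateDelta(recS), d)
})

# acceptor-bleach control trajectories for the gamma estimator
gammaControl <- function(nMol, e, gamma, alpha = 0.05, delta = 0.03,
                         B = 800, len = 60) {
  do.call(rbind, lapply(seq_len(nMol), function(m) {
    s <- sample(20:(len - 20), 1)
    pre <- makeRecords(s - 1, brightness = B, e = e, alpha = alpha,
                       delta = delta, gamma = gamma, molecule = m)
    post <- makeRecords(len - s + 1, brightness = B, e = e, alpha = alpha,
                        delta = delta, gamma = gamma, molecule = m)
    # after acceptor bleach: full donor emission, no FRET, no f_AA
    post$f_dd <- stats::rpois(nrow(post), B)
    post$f_da <- stats::rpois(nrow(post), alpha * B)
    post$f_aa <- stats::rpois(nrow(post), 0)
    out <- rbind(pre, post)
    out$frame <- seq_len(nrow(out)) - 1L
    out
  }))
}

test_that("gamma is recovered from single-step bleaching events", {
  set.seed(163)
  rec <- gammaControl(40, e = 0.87, gamma = 0.9)
  g <- estimateGamma(rec, alpha = 0.05, delta = 0.03)
  expect_lt(abs(g - 0.9) / 0.9, 0.1)
  expect_gte(attr(g, "nEvents"), 30)
  # symmetric channels give gamma of 1
  recSym <- gammaControl(40, e = 0.87, gamma = 1)
  expect_lt(abs(estimateGamma(recSym, 0.05, 0.03) - 1), 0.1)
  expect_error(estimateGamma(rec[1:5, ], 0.05, 0.03), "no usable")
})

test_that("high-FRET controls give a lower-variance gamma than low-FRET ones", {
  set.seed(167)
  spread <- function(e) {
    gs <- vapply(1:12, function(i)
      as.numeric(estimateGamma(gammaControl(25, e = e, gamma = 0.9),
                               0.05, 0.03)), 0)
    sd(gs)
  }
  expect_lt(spread(0.87), spread(0.3))
})

test_that("beta is recovered by centring the calibration sample at S = 0.5", {
  set.seed(173)
  rec <- makeRecords(600, e = 0.7, gamma = 0.9, beta = 1.2)
  b <- estimateBeta(rec, alpha = 0, delta = 0, gamma = 0.9)
  expect_lt(abs(b - 1.2) / 1.2, 0.05)
  # perfectly balanced channels
  recB <- makeRecords(600, e = 0.7, gamma = 1, beta = 1)
  expect_lt(abs(estimateBeta(recB, 0, 0, 1) - 1), 0.05)
  # resulting S distribution is centred at 0.5 by construction
  es <- computeES(rec, CorrectionFactors(gamma = 0.9, beta = b))
  expect_equal(median(es$s), 0.5, tolerance = 0.01)
})

test_that("the E/S formulas reduce correctly in the trivial-factor limit", {
  triv <- CorrectionFactors()
  r <- computeES(data.frame(f_dd = 100, f_da = 100, f_aa = 200), triv)
  expect_equal(r$e, 0.5)
  expect_equal(r$s, 0.5)
  r2 <- computeES(data.frame(f_dd = 0, f_da = 150, f_aa = 150), triv)
  expect_equal(r2$e, 1)
  # with trivial factors E is the proximity ratio and S the ALEX fraction
  set.seed(179)
  rec <- data.frame(f_dd = runif(50, 10, 500), f_da = runif(50, 10, 500),
                    f_aa = runif(50, 10, 500))
  es <- computeES(rec, triv)
  expect_equal(es$e, rec$f_da / (rec$f_dd + rec$f_da), tolerance = 1e-12)
  expect_equal(es$s, (rec$f_dd + rec$f_da) /
                 (rec$f_dd + rec$f_da + rec$f_aa), tolerance = 1e-12)
  # E is invariant under a common intensity scale
  esS <- computeES(rec * 13, CorrectionFactors(alpha = 0.1, delta = 0.05,
                                               gamma = 0.9, beta = 1.1))
  es1 <- computeES(rec, CorrectionFactors(alpha = 0.1, delta = 0.05,
                                          gamma = 0.9, beta = 1.1))
  expect_equal(esS$e, es1$e, tolerance = 1e-12)
  # non-positive denominators are flagged, not propagated
  bad <- computeES(data.frame(f_dd = 10, f_da = 5, f_aa = 500),
                   CorrectionFactors(delta = 0.5))
  expect_false(bad$esValid)
  expect_true(is.nan(bad$e))
})

test_that("estimated factors feed back into an accurate E/S computation", {
  set.seed(181)
  true <- list(alpha = 0.08, delta = 0.05, gamma = 0.9, beta = 1.2)
  a <- estimateAlpha(makeRecords(500, class = "donor_only",
                                 alpha = true$alpha))
  d <- estimateDelta(makeRecords(500, class = "acceptor_only",
                                 delta = true$delta))
  g <- as.numeric(estimateGamma(
    gammaControl(40, e = 0.87, gamma = true$gamma, alpha = true$alpha,
                 delta = true$delta),
    a, d))
  calib <- makeRecords(600, e = 0.87, alpha = true$alpha, delta = true$delta,
                       gamma = true$gamma, beta = true$beta)
  b <- estimateBeta(calib, a, d, g)
  fac <- CorrectionFactors(alpha = a, delta = d, gamma = g, beta = b)
  # two-state population measured with the estimated factors
  recs <- rbind(
    makeRecords(800, e = 0.87, alpha = true$alpha, delta = true$delta,
                gamma = true$gamma, beta = true$beta),
    makeRecords(800, e = 0.42, alpha = true$alpha, delta = true$delta,
                gamma = true$gamma, beta = true$beta))
  es <- computeES(recs, fac)
  expect_lt(abs(mean(es$e[1:800]) - 0.87), 0.02)
  expect_lt(abs(mean(es$e[801:1600]) - 0.42), 0.02)
  expect_lt(abs(mean(es$s) - 0.5), 0.02)
})

test_that("correction factors survive a JSON round trip with provenance", {
  fac <- CorrectionFactors(alpha = 0.08, delta = 0.05, gamma = 0.9,
                           beta = 1.2)
  path <- withr::local_tempfile(fileext = ".json")
  writeCorrectionFactors(fac, path, provenance = list(dataset = "ctrl-1",
                                                      nEvents = 40))
  back <- readCorrectionFactors(path)
  expect_equal(back@alpha, 0.08)
  expect_equal(back@beta, 1.2)
})
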