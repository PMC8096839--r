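test_that("ergodicity ratio separates frozen from fully sampling trajectories", {
  # constant trajectories at distinct force levels: no local variance
  rec <- data.frame(molecule = rep(1:6, each = 10),
                    e = 0.4, force = rep(c(1, 2, 3, 4, 5, 6), each = 10))
  er <- ergodicityRatio(rec)
  expect_lt(er$ratio, 0.05)
  # i.i.d. forces within and across trajectories: ratio near 1
  set.seed(257)
  rec2 <- data.frame(molecule = rep(1:40, each = 30), e = 0.4,
                     force = rnorm(1200, 4, 1.5))
  er2 <- ergodicityRatio(rec2)
  expect_lt(abs(er2$ratio - 1), 0.08)
  # low-FRET selection: trajectories without 5 sub-cut records are excluded
  rec3 <- rbind(rec2, data.frame(molecule = 999, e = 0.9, force = 0))
  expect_equal(ergodicityRatio(rec3)$nTrajectories, 40)
  expect_error(ergodicityRatio(data.frame(molecule = 1, e = 0.9, force = 1)),
               "qualify")
})

test_that("slower sampling moves the ergodicity ratio towards 1", {
  # two-state force switching at about 0.3 per second: fast frame rates see
  # frozen levels, slow frame rates average over transitions
  set.seed(263)
  simulate <- function(dtFrame, nFrames, nTraj) {
    do.call(rbind, lapply(seq_len(nTraj), function(m) {
      state <- numeric(nFrames)
      s <- sample(c(1.5, 5), 1)
      for (k in seq_len(nFrames)) {
        if (runif(1) < 0.3 * dtFrame) s <- if (s > 3) 1.5 else 5
        state[k] <- s
      }
      data.frame(molecule = m, e = 0.4,
                 force = state + rnorm(nFrames, 0, 0.3))
    }))
  }
  r50 <- ergodicityRatio(simulate(0.02, 45, 40), frameRate = 50)
  r1 <- ergodicityRatio(simulate(1, 45, 40), frameRate = 1)
  expect_gt(r1$ratio, r50$ratio)
  expect_gt(r1$ratio, 0.6)
  expect_lt(r50$ratio, 0.6)
})

test_that("noiseless ramps give the exact loading rate, invariant to offsets", {
  p <- defaultCalibration()
  mk <- function(shift) {
    tr <- simulateForceRampTrace(1.5, 3, 10, noiseSdE = 0, params = p,
                                 duration = 4)
    data.frame(time = tr$time + shift, force = fretToForce(tr$e, p))
  }
  out <- poolAndFitLoadingRate(list(mk(0), mk(12.3)))
  expect_equal(out$loadingRate, 1.5, tolerance = 1e-6)
  expect_equal(out$nTraces, 2)
  # mean trace export covers the aligned rising phase
  expect_true(all(out$meanTrace$time <= 0))
  expect_error(poolAndFitLoadingRate(list(mk(0))), "at least 2")
})

test_that("loading-rate recovery is accurate and unbiased at the study scale", {
  p <- defaultCalibration()
  mkSet <- function(seedBase) {
    lapply(1:7, function(i) {
      tr <- simulateForceRampTrace(1.5, 3.75, 10, noiseSdE = 0.05, params = p,
                                   duration = 7, seed = seedBase + i)
      data.frame(time = tr$time,
                 force = fretToForce(pmin(pmax(tr$e, 0.02), 0.98), p))
    })
  }
  # median over five independent seven-ramp experiments
  ests <- vapply(1:5, function(r)
    poolAndFitLoadingRate(mkSet(3000 * r))$loadingRate, 0)
  expect_lt(abs(median(ests) - 1.5) / 1.5, 0.1)
  # bias over many repeats stays below 5 percent
  many <- vapply(1:60, function(r)
    poolAndFitLoadingRate(mkSet(20000 + 97 * r))$loadingRate, 0)
  expect_lt(abs(mean(many) - 1.5) / 1.5, 0.05)
})

test_that("contact-time pooling uses half-open five-minute windows", {
  rec <- data.frame(molecule = 1:4, contactTime = c(7, 5, 0.2, NA))
  g <- poolByContactTime(rec)
  expect_equal(g[["5-10"]]$molecule, c(1, 2))  # 5 min goes to second window
  expect_equal(g[["0-5"]]$molecule, 3)
  expect_equal(g[["unknown"]]$molecule, 4)
})

test_that("MSD fitting recovers fast and slow diffusion with honest errors", {
  tr <- simulateBrownianTracks(150, 0.72, 25, 0.025, locNoise = 0.03,
                               seed = 269)
  m <- msdFit(tr, dt = 0.025, resample = "tracks", seed = 271)
  expect_lt(abs(m$D - 0.72), 2 * m$DSe)
  slow <- simulateBrownianTracks(150, 1e-4, 25, 0.025, locNoise = 0.03,
                                 seed = 277)
  ms <- msdFit(slow, dt = 0.025, resample = "tracks", seed = 281)
  expect_lt(abs(ms$D - 1e-4), max(2 * ms$DSe, 1e-4))
  # immobile molecules: D near zero, intercept gives the localization noise
  ms2 <- msdFit(simulateBrownianTracks(120, 0, 25, 0.025, locNoise = 0.03,
                                       seed = 283),
                dt = 0.025, seed = 293)
  expect_lt(abs(ms2$D), 5e-4)
  expect_equal(ms2$epsilon, 0.03, tolerance = 0.15)
  # halving the frame interval leaves D unchanged
  trH <- simulateBrownianTracks(150, 0.72, 25, 0.0125, locNoise = 0.03,
                                seed = 307)
  mH <- msdFit(trH, dt = 0.0125, resample = "tracks", seed = 311)
  expect_lt(abs(mH$D - 0.72), 2.5 * mH$DSe)
})

test_that("MSD estimation is unbiased across the diffusion range", {
  for (d in c(1e-4, 0.01, 0.7)) {
    tr <- simulateBrownianTracks(120, d, 25, 0.025, locNoise = 0.01,
                                 seed = 313 + round(1e4 * d))
    m <- msdFit(tr, dt = 0.025, resample = "tracks",
                seed = 317 + round(1e4 * d))
    expect_lt(abs(m$D - d), max(3 * m$DSe, 2e-4))
  }
})

test_that("the smallest enclosing circle matches brute force and is minimal", {
  set.seed(331)
  for (i in 1:40) {
    xy <- matrix(runif(2 * sample(3:12, 1)), ncol = 2)
    a <- smallestEnclosingCircle(xy)
    b <- bruteSEC(xy)
    expect_equal(a$radius, b$radius, tolerance = 1e-9)
    dists <- sqrt((xy[, 1] - a$center[1])^2 + (xy[, 2] - a$center[2])^2)
    expect_true(all(dists <= a$radius * (1 + 1e-9) + 1e-12))
  }
  # degenerate inputs
  same <- smallestEnclosingCircle(matrix(c(1, 1, 1, 1, 1, 1), 3, 2))
  expect_equal(same$radius, 0)
  two <- smallestEnclosingCircle(rbind(c(0, 0), c(2, 0)))
  expect_equal(two$radius, 1)
  expect_equal(two$center, c(1, 0))
})

test_that("mobility classification separates bound from diffusing sensors", {
  set.seed(337)
  statIm <- vapply(1:200, function(i) {
    tr <- simulateBrownianTracks(1, 0, 20, 0.05, locNoise = 0.03)
    classifyMobility(cbind(tr$x_um, tr$y_um), max(tr$t))$statistic
  }, 0)
  expect_true(all(statIm < 0.35))
  expect_gt(mean(statIm), 0.03)
  expect_lt(mean(statIm), 0.15)
  statMob <- vapply(1:200, function(i) {
    tr <- simulateBrownianTracks(1, 0.72, 20, 0.05, locNoise = 0.03)
    classifyMobility(cbind(tr$x_um, tr$y_um), max(tr$t))$statistic
  }, 0)
  expect_gte(mean(statMob >= 0.35), 0.95)
})
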