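test_that("blank noise images yield fewer than one detection per frame", {
  cam <- CameraParams()
  set.seed(83)
  nDet <- vapply(1:30, function(i) {
    counts <- matrix(rpois(64 * 64, 2) * cam@emGain / cam@photonsPerCount +
                       cam@offset + rnorm(64 * 64, 0, cam@readNoiseSd), 64, 64)
    nrow(detectSpots(countsToPhotons(counts, cam)))
  }, 0)
  expect_lt(mean(nDet), 1)
})

test_that("bright spots are found with high recall and sub-pixel accuracy", {
  set.seed(89)
  found <- 0; total <- 0; errs <- c()
  for (rep in 1:25) {
    truth <- cbind(x = runif(6, 8, 56) , y = runif(6, 8, 56))
    # enforce 4 px separation
    keep <- rep(TRUE, 6)
    for (i in 2:6) if (min(sqrt((truth[i, 1] - truth[1:(i - 1), 1])^2 +
                                (truth[i, 2] - truth[1:(i - 1), 2])^2)) < 6)
      keep[i] <- FALSE
    truth <- truth[keep, , drop = FALSE]
    img <- matrix(0, 64, 64)
    for (i in seq_len(nrow(truth)))
      img <- forcefret:::addSpot(img, truth[i, 1], truth[i, 2], 400, 1)
    ph <- rpois(length(img), img + 2)             # SNR well above 5
    det <- detectSpots(matrix(ph, 64, 64))
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((det$x - truth[i, 1])^2 + (det$y - truth[i, 2])^2)
      total <- total + 1
      if (length(d) && min(d) < 1) {
        found <- found + 1
        errs <- c(errs, min(d))
      }
    }
  }
  expect_gte(found / total, 0.99)
  expect_lt(mean(errs), 0.15)
})

test_that("detection on the sum image is invariant to the FRET state", {
  img <- matrix(0, 48, 48)
  # high-FRET molecule: photons mostly in DA; low-FRET: mostly in DD
  dd <- forcefret:::addSpot(img, 12.3, 12.8, 600 * (1 - 0.87), 1)
  dd <- forcefret:::addSpot(dd, 33.6, 34.1, 600 * (1 - 0.2), 1)
  da <- forcefret:::addSpot(img, 12.3, 12.8, 600 * 0.87, 1)
  da <- forcefret:::addSpot(da, 33.6, 34.1, 600 * 0.2, 1)
  set.seed(97)
  sumImg <- matrix(rpois(48 * 48, dd + da + 2), 48, 48)
  det <- detectSpots(sumImg)
  expect_equal(nrow(det), 2)
  expect_lt(min(abs(det$x - 12.3)), 0.3)
  expect_lt(min(abs(det$x - 33.6)), 0.3)
})

test_that("linking follows molecules, closes gaps, and interpolates positions", {
  # single immobile molecule observed on every interlaced frame
  mkLocs <- function(pairs, x, y, dropPairs = integer(0)) {
    keep <- setdiff(seq_len(pairs) - 1L, dropPairs)
    do.call(rbind, lapply(keep, function(p)
      data.frame(frame = c(2L * p, 2L * p + 1L), pairIndex = p,
                 excitation = c("green", "red"), x = x, y = y)))
  }
  tr <- linkTrajectories(mkLocs(20, 10, 12))
  expect_equal(length(unique(tr$molecule)), 1)
  expect_equal(nrow(tr), 20)
  expect_false(any(tr$interpolated))
  # molecule dark for 2 frame pairs: positions interpolated and flagged
  locs <- rbind(mkLocs(10, 10, 12, dropPairs = c(4, 5)))
  locs$x <- locs$x + (locs$pairIndex) * 0.2       # slow drift
  tr <- linkTrajectories(locs)
  expect_equal(length(unique(tr$molecule)), 1)
  expect_equal(sum(tr$interpolated), 2)
  drift <- tr$x[order(tr$frame)]
  expect_equal(drift, 10 + 0.2 * (0:9), tolerance = 1e-9)  # linear fill
  # two well-separated mobile molecules never swap identities
  set.seed(101)
  swaps <- 0
  for (rep in 1:30) {
    stepSd <- sqrt(2 * 0.7 * 0.05) * 1000 / 160   # D = 0.7 um2/s at 20 fps
    xa <- cumsum(c(10, rnorm(19, 0, stepSd)))
    ya <- cumsum(c(10, rnorm(19, 0, stepSd)))
    xb <- cumsum(c(10 + 5000 / 160, rnorm(19, 0, stepSd)))
    yb <- cumsum(c(10, rnorm(19, 0, stepSd)))
    locs <- data.frame(frame = rep(2L * (0:19), 2),
                       pairIndex = rep(0:19, 2),
                       excitation = "green",
                       x = c(xa, xb), y = c(ya, yb))
    tr <- linkTrajectories(locs, minLength = 4)
    # a swap is a track mixing detections of both molecules; track splits
    # (a rare too-large Brownian step) are not swaps
    obs <- tr[!tr$interpolated, ]
    whoA <- abs(obs$x - xa[obs$frame + 1]) + abs(obs$y - ya[obs$frame + 1]) <
      1e-6
    mixed <- tapply(whoA, obs$molecule, function(z) any(z) && any(!z))
    swaps <- swaps + sum(mixed)
  }
  expect_equal(swaps, 0)
})

test_that("linking is invariant to the input row order and drops short tracks", {
  set.seed(103)
  locs <- data.frame(frame = rep(2L * (0:9), 2), pairIndex = rep(0:9, 2),
                     excitation = "green",
                     x = c(seq(10, 12, length.out = 10),
                           seq(40, 41, length.out = 10)),
                     y = rep(c(10, 40), each = 10))
  # a two-pair orphan that must be discarded (min length 4)
  locs <- rbind(locs, data.frame(frame = c(0, 2), pairIndex = c(0, 1),
                                 excitation = "green", x = 25, y = 25))
  tr1 <- linkTrajectories(locs)
  tr2 <- linkTrajectories(locs[sample.int(nrow(locs)), ])
  expect_equal(length(unique(tr1$molecule)), 2)
  expect_equal(tr1[order(tr1$molecule, tr1$frame), c("x", "y", "frame")],
               tr2[order(tr2$molecule, tr2$frame), c("x", "y", "frame")])
})

test_that("brightness measurement is background-corrected and profile-scaled", {
  flat <- matrix(7.3, 40, 40)
  m <- measureBrightness(flat, 20, 20)
  expect_equal(m$f, 0, tolerance = 1e-9)          # bg equals signal
  # a rendered spot of N photons is recovered within 2 percent on average
  set.seed(107)
  fs <- vapply(1:100, function(i) {
    img <- forcefret:::addSpot(matrix(0, 40, 40), 20.3, 19.6, 2000, 1)
    noisy <- matrix(rpois(1600, img + 3), 40, 40)
    measureBrightness(blurForDetection(noisy, 1), 20.3, 19.6)$f
  }, 0)
  expect_lt(abs(mean(fs) - 2000) / 2000, 0.02)
  # edge positions are flagged rather than measured
  expect_true(measureBrightness(flat, 2, 20)$edge)
})

test_that("trajectory brightness recovers truth and applies the profile division", {
  mv <- sharedTwoStateMovie()
  ph <- movieToPhotons(mv)
  truth <- mv@truth$records
  m1 <- truth[truth$molecule == 1 & truth$frame < 20, ]
  traj <- data.frame(molecule = 1, frame = m1$frame, x = m1$x, y = m1$y,
                     interpolated = FALSE, nDetections = 2L)
  rec <- measureTrajectoryBrightness(ph, traj)
  expect_lt(abs(mean(rec$f_aa) - mean(m1$f_aa)) / mean(m1$f_aa), 0.05)
  expect_lt(abs(mean(rec$f_dd + rec$f_da) - mean(m1$f_dd + m1$f_da)) /
              mean(m1$f_dd + m1$f_da), 0.05)
  # a profile value of 0.5 at the spot doubles the corrected brightness
  prof <- matrix(1, 80, 80); prof[, 1:40] <- 0.5
  rec2 <- measureTrajectoryBrightness(ph, traj, greenProfile = prof,
                                      redProfile = prof)
  scale <- ifelse(round(traj$x) <= 39, 2, 1)
  expect_equal(rec2$f_aa, rec$f_aa * scale, tolerance = 1e-9)
})

test_that("brightness bias stays below 5 percent across signal-to-noise levels", {
  set.seed(109)
  for (amp in c(120, 600, 2500)) {
    fs <- vapply(1:40, function(i) {
      img <- forcefret:::addSpot(matrix(0, 40, 40), 20.3, 19.6, amp, 1)
      noisy <- matrix(rpois(1600, img + 2), 40, 40)
      measureBrightness(blurForDetection(noisy, 1), 20.3, 19.6)$f
    }, 0)
    expect_lt(abs(mean(fs) - amp) / amp, 0.05)
  }
})
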