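test_that("step detection finds single steps reliably and rejects flat traces", {
  set.seed(113)
  # constant trace plus noise: no steps
  zeros <- vapply(1:50, function(i)
    detectSteps(rnorm(80, 10, 1))$nSteps, 0L)
  expect_lte(mean(zeros > 0), 0.05)
  # single 5-sigma step at frame 50 of 100: found at +-1 frame >= 99 percent
  hits <- 0
  for (i in 1:300) {
    y <- c(rep(10, 50), rep(5, 50)) + rnorm(100)
    s <- detectSteps(y)
    if (s$nSteps == 1 && abs(s$stepFrames[1] - 51) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 300, 0.99)
  # two-step staircase
  y2 <- c(rep(20, 30), rep(12, 30), rep(4, 30)) + rnorm(90, 0, 0.8)
  expect_equal(detectSteps(y2)$nSteps, 2L)
})

test_that("bleach filter accepts clean single-step traces and truncates them", {
  set.seed(127)
  faa <- c(rep(500, 60), rep(0, 40)) + rnorm(100, 0, 15)
  fsum <- rep(480, 100) + rnorm(100, 0, 15)
  bf <- bleachFilter(faa, fsum)
  expect_true(bf$accepted)
  expect_lt(abs(bf$truncateBefore - 61), 2)
  # two acceptor steps: rejected as multi-emitter
  faa2 <- c(rep(900, 35), rep(450, 35), rep(0, 30)) + rnorm(100, 0, 15)
  expect_false(bleachFilter(faa2, fsum)$accepted)
  # partial donor bleach (mid-trace drop not reaching background): rejected
  fsum3 <- c(rep(900, 40), rep(500, 60)) + rnorm(100, 0, 15)
  expect_false(bleachFilter(faa, fsum3)$accepted)
  # terminal donor bleach to background before the acceptor step: truncates
  fsum4 <- c(rep(500, 40), rep(0, 60)) + rnorm(100, 0, 15)
  bf4 <- bleachFilter(faa, fsum4)
  expect_true(bf4$accepted)
  expect_lt(abs(bf4$truncateBefore - 41), 2)
})

test_that("truncation lands on the true bleach frame for a simulated ensemble", {
  set.seed(131)
  ok <- 0
  for (i in 1:100) {
    s <- sample(20:80, 1)
    faa <- c(rep(600, s - 1), rep(0, 100 - s + 1)) + rnorm(100, 0, 20)
    fsum <- rep(580, 100) + rnorm(100, 0, 20)
    bf <- bleachFilter(faa, fsum)
    if (bf$accepted && abs(bf$truncateBefore - s) <= 1) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.95)
})

test_that("laser-region filter removes dim-illumination records", {
  prof <- matrix(1, 40, 40)
  rec <- data.frame(molecule = 1, x = c(5, 30), y = c(5, 30))
  expect_equal(nrow(filterLaserRegion(rec, prof)), 2)  # uniform: keep all
  prof[, 1:20] <- 0.4
  expect_equal(filterLaserRegion(rec, prof)$x, 30)
  # retained fraction matches the area above half-maximum within 2 percent
  xs <- matrix(rep(0:199, each = 200), 200, 200)
  ys <- matrix(rep(0:199, times = 200), 200, 200)
  gauss <- exp(-((xs - 100)^2 + (ys - 100)^2) / (2 * 50^2))
  set.seed(137)
  rec2 <- data.frame(molecule = 1, x = runif(6000, 0, 199),
                     y = runif(6000, 0, 199))
  kept <- nrow(filterLaserRegion(rec2, gauss)) / 6000
  expect_lt(abs(kept - mean(gauss >= 0.5)), 0.02)
})

test_that("overlap rule drops trajectories or records as specified", {
  rec <- data.frame(molecule = rep(1:3, each = 10),
                    frame = rep(0:9, 3),
                    overlap = c(rep(FALSE, 10),                 # isolated
                                rep(c(TRUE, FALSE), c(3, 7)),   # 30 percent
                                rep(c(TRUE, FALSE), c(1, 9))),  # 10 percent
                    edge = FALSE)
  out <- filterOverlap(rec)
  expect_equal(sort(unique(out$molecule)), c(1, 3))
  expect_equal(sum(out$molecule == 3), 9)   # only the overlapping record lost
  expect_equal(sum(out$molecule == 1), 10)
})

test_that("first-frame filter keeps only full-profile trajectories", {
  rec <- data.frame(molecule = rep(1:2, each = 5),
                    frame = c(0:4, 3:7))
  out <- filterFirstFrame(rec)
  expect_equal(unique(out$molecule), 1)
})

test_that("stoichiometry rule removes multi-donor and multi-acceptor species", {
  rec <- data.frame(molecule = rep(1:3, each = 20),
                    s = c(rep(0.5, 20),
                          c(rep(0.7, 6), rep(0.5, 14)),   # 30 percent high S
                          c(rep(0.7, 4), rep(0.5, 16))))  # 20 percent high S
  out <- filterStoichiometry(rec)
  expect_equal(sort(unique(out$molecule)), c(1, 3))
  # simulated double-donor molecules (true S about 0.67) are removed
  set.seed(139)
  dd <- do.call(rbind, lapply(1:20, function(m) {
    r <- makeRecords(15, class = "double_donor", e = 0.6, molecule = m)
    computeES(r, CorrectionFactors())
  }))
  out2 <- filterStoichiometry(dd)
  expect_gte(1 - length(unique(out2$molecule)) / 20, 0.9)
})

test_that("adaptive cell masks match the ground truth discs", {
  expect_false(any(makeCellMask(matrix(5, 40, 40), 21, offset = 0)))
  cell <- renderCellImage(data.frame(x = 45, y = 45, radius = 31,
                                     intensity = 40),
                          imgSize = c(96, 96), background = 10, seed = 149)
  # one 10 um disc (about 31 px at 160 nm/px) at about 5x background
  ph <- countsToPhotons(cell$image, CameraParams())
  mask <- makeCellMask(ph, blockSize = 91, offset = 2, minArea = 50)
  inter <- sum(mask & cell$mask)
  expect_gte(inter / sum(cell$mask), 0.95)   # recovers >= 95 percent of disc
  expect_gte(inter / sum(mask | cell$mask), 0.9)  # IoU
  # record selection follows the mask
  rec <- data.frame(molecule = 1:2, x = c(45, 5), y = c(45, 5))
  expect_equal(selectInMask(rec, mask)$x, 45)
  expect_warning(out <- selectInMask(rec, matrix(FALSE, 96, 96)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("the full QC chain is idempotent and keeps intact sensors", {
  mv <- sharedTwoStateMovie()
  ph <- movieToPhotons(mv)
  locs <- detectCandidates(ph)
  traj <- linkTrajectories(locs)
  rec <- measureTrajectoryBrightness(ph, traj)
  q1 <- qcChain(rec, CorrectionFactors())
  # drop helper columns added by the chain before re-running
  q2 <- qcChain(q1[, setdiff(names(q1), c("e", "s", "esValid"))],
                CorrectionFactors())
  expect_equal(q2$e, q1$e)
  expect_equal(nrow(q2), nrow(q1))
  # intact pairs that bleach within the movie survive the chain
  dt <- frameInterval(mv@timing)
  bleachFrame <- mv@truth$molecules$bleachA / dt
  intact <- which(bleachFrame > 8 & bleachFrame < 95 &
                    mv@truth$molecules$bleachD / dt > bleachFrame + 5)
  survivors <- unique(q1$molecule)
  # map back: trajectory ids correspond to molecules via position
  startPos <- do.call(rbind, lapply(survivors, function(m) {
    r <- q1[q1$molecule == m, ][1, c("x", "y")]
  }))
  matched <- vapply(intact, function(i) {
    any(sqrt((startPos$x - mv@truth$molecules$x[i])^2 +
               (startPos$y - mv@truth$molecules$y[i])^2) < 2)
  }, TRUE)
  expect_gte(mean(matched), 0.95)
})
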