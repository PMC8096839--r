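# Shared fixtures and independent oracles for the test suite.

# brute-force smallest enclosing circle over all point pairs and triples
bruteSEC <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  contains <- function(c) {
    all(sqrt((xy[, 1] - c$center[1])^2 + (xy[, 2] - c$center[2])^2) <=
          c$radius * (1 + 1e-10) + 1e-12)
  }
  best <- NULL
  for (i in 1:n) for (j in i:n) {
    c <- forcefret:::secDiameter(xy[i, ], xy[j, ])
    if (contains(c) && (is.null(best) || c$radius < best$radius)) best <- c
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    c <- forcefret:::secCircum(xy[i, ], xy[j, ], xy[k, ])
    if (!is.null(c) && contains(c) &&
        (is.null(best) || c$radius < best$radius)) best <- c
  }
  best
}

# brightness record table following the ALEX emission model, with Poisson
# photon noise, for the correction-factor estimators
makeRecords <- function(n, brightness = 500, e = 0.87, alpha = 0, delta = 0,
                        gamma = 1, beta = 1,
                        class = c("pair", "donor_only", "acceptor_only",
                                  "double_donor"),
                        molecule = seq_len(n)) {
  class <- match.arg(class)
  nD <- if (class == "double_donor") 2 else 1
  fdd0 <- switch(class, donor_only = brightness, acceptor_only = 0,
                 brightness * (nD - e))
  ffret0 <- switch(class, donor_only = 0, acceptor_only = 0,
                   gamma * brightness * e)
  faa0 <- switch(class, donor_only = 0, beta * gamma * brightness)
  data.frame(
    molecule = molecule, frame = seq_len(n) - 1L,
    f_dd = stats::rpois(n, fdd0),
    f_da = stats::rpois(n, ffret0 + alpha * fdd0 + delta * faa0),
    f_aa = stats::rpois(n, faa0))
}

# one small cached two-state movie shared across test files; all molecules
# bleach within the movie so the QC chain can act on complete profiles
sharedMovieEnv <- new.env(parent = emptyenv())
sharedTwoStateMovie <- function() {
  if (is.null(sharedMovieEnv$movie)) {
    scene <- sceneTwoState(10, width = 80, height = 80, brightness = 700,
                           meanBleachA = 3, meanBleachD = 20, seed = 101)
    sharedMovieEnv$scene <- scene
    sharedMovieEnv$movie <- renderMovie(
      scene, timing = TimingParams(nFramePairs = 100), seed = 102)
  }
  sharedMovieEnv$movie
}
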