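# End-to-end orchestration: simulate -> analyze -> report, from a single
# configuration with reproducible seeding.

#' Two-state scene generator
#'
#' Builds a scene of well-separated sensor molecules whose FRET states are
#' drawn from a two-state population (collapsed high-FRET and stretched
#' low-FRET), with exponential acceptor and donor photobleaching times —
#' the study conditions of a gel-phase recording with cells.
#'
#' @param nMolecules number of molecules.
#' @param width,height field size (px).
#' @param eStates c(high, low) FRET states.
#' @param weights population weights of `eStates` (sum to 1).
#' @param brightness photon budget per frame.
#' @param d diffusion coefficient (um^2/s); 0 for gel-phase anchors.
#' @param meanBleachA,meanBleachD mean acceptor / donor bleach times (s).
#' @param margin placement margin from the border (px).
#' @param minSep minimum inter-molecule distance (px).
#' @param seed integer seed.
#' @return a [movieScene()].
#' @export
sceneTwoState <- function(nMolecules, width = 96, height = 96,
                          eStates = c(0.87, 0.42), weights = c(0.79, 0.21),
                          brightness = 600, d = 0, meanBleachA = 4,
                          meanBleachD = 12, margin = 9, minSep = 12,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pos) < nMolecules && tries < 50000) {
    cand <- c(stats::runif(1, margin, width - 1 - margin),
              stats::runif(1, margin, height - 1 - margin))
    if (!nrow(pos) || min(sqrt((pos[, 1] - cand[1])^2 +
                               (pos[, 2] - cand[2])^2)) >= minSep)
      pos <- rbind(pos, cand)
    tries <- tries + 1
  }
  if (nrow(pos) < nMolecules)
    stop("could not place the requested molecules with this separation")
  state <- sample.int(length(eStates), nMolecules, replace = TRUE,
                      prob = weights)
  mols <- do.call(rbind, lapply(seq_len(nMolecules), function(i)
    moleculeSpec(x = pos[i, 1], y = pos[i, 2], d = d,
                 brightness = brightness, e = eStates[state[i]],
                 bleachA = stats::rexp(1, 1 / meanBleachA),
                 bleachD = stats::rexp(1, 1 / meanBleachD))))
  movieScene(width, height, mols)
}

#' Default pipeline configuration
#'
#' All standard analysis constants appear here as named defaults: the
#' camera conversion (15.7 photons/count, EM gain 300, 160 nm pixels), the
#' tracking parameters (800 nm search radius, 3-frame memory, 4-observation
#' minimum), the QC thresholds (50 percent laser cut, 25 percent overlap and
#' stoichiometry fractions, S in `[0.35, 0.6]`), the mixture fallback rule
#' and the calibration constants.
#'
#' @return nested configuration list; override entries as needed.
#' @export
pipelineConfig <- function() {
  list(
    camera = list(photonsPerCount = 15.7, emGain = 300, pixelSize = 160,
                  readNoiseSd = 1, offset = 100),
    timing = list(tIll = 5, tGr = 5, tDelay = 85, nFramePairs = 150),
    scene = list(nMolecules = 24, width = 96, height = 96,
                 eStates = c(0.87, 0.42), weights = c(0.79, 0.21),
                 brightness = 600, d = 0, meanBleachA = 4, meanBleachD = 12),
    factors = list(alpha = 0.05, delta = 0.05, gamma = 1, beta = 1),
    detection = list(k = 4, psfSigma = 1),
    tracking = list(searchRadius = 800, memory = 3, minLength = 4),
    qc = list(laserThreshold = 0.5, overlapFraction = 0.25,
              sMin = 0.35, sMax = 0.6, sFraction = 0.25),
    mixture = list(maxComponents = 2, eMax = 0.8, minWeight = 0.1),
    calibration = list(e0 = 0.87, fLinearLimit = 10),
    background = 2,
    nMovies = 1)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

configObjects <- function(config) {
  list(camera = do.call(CameraParams, config$camera),
       timing = do.call(TimingParams, config$timing),
       factors = do.call(CorrectionFactors, config$factors))
}

#' Simulate a dataset from a configuration
#'
#' Renders `config$nMovies` two-state movies; optionally writes the TIFF
#' stacks, ground truth CSV and scene YAML to `outDir`.
#'
#' @param config configuration list (see [pipelineConfig()]); entries
#'   override the defaults.
#' @param seed integer seed governing every source of randomness.
#' @param outDir output directory or NULL to keep everything in memory.
#' @return list of [FretMovie-class] objects.
#' @export
runSimulation <- function(config = list(), seed = 1, outDir = NULL) {
  config <- mergeConfig(pipelineConfig(), config)
  obj <- configObjects(config)
  movies <- vector("list", config$nMovies)
  for (i in seq_len(config$nMovies)) {
    scene <- do.call(sceneTwoState,
                     c(config$scene, list(seed = seed + 7919L * (i - 1L))))
    movies[[i]] <- renderMovie(scene, camera = obj$camera,
                               timing = obj$timing,
                               psfSigma = config$detection$psfSigma,
                               factors = obj$factors,
                               background = config$background,
                               seed = seed + 7919L * (i - 1L) + 1L)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      prefix <- file.path(outDir, sprintf("movie%03d", i))
      writeChannelStacks(movies[[i]], prefix)
      utils::write.csv(movies[[i]]@truth$records,
                       paste0(prefix, "_truth.csv"), row.names = FALSE)
      writeScene(scene, paste0(prefix, "_scene.yaml"))
    }
  }
  movies
}

#' Analyze one movie: detection, tracking, brightness, QC
#'
#' @param movie a [FretMovie-class] (counts or photons).
#' @param config configuration list.
#' @param factors [CorrectionFactors-class] used for the E/S computation.
#' @param greenProfile,redProfile laser profiles or NULL.
#' @param mask cell mask or NULL.
#' @return QC-filtered record table with `e` and `s` columns.
#' @export
analyzeMovie <- function(movie, config = pipelineConfig(), factors,
                         greenProfile = NULL, redProfile = NULL,
                         mask = NULL) {
  ph <- movieToPhotons(movie)
  locs <- detectCandidates(ph, k = config$detection$k,
                           psfSigma = config$detection$psfSigma)
  traj <- linkTrajectories(locs,
                           searchRadius = config$tracking$searchRadius,
                           memory = config$tracking$memory,
                           minLength = config$tracking$minLength,
                           pixelSize = movie@camera@pixelSize)
  rec <- measureTrajectoryBrightness(ph, traj, greenProfile = greenProfile,
                                     redProfile = redProfile,
                                     psfSigma = config$detection$psfSigma)
  qcChain(rec, factors, greenProfile = greenProfile, mask = mask,
          laserThreshold = config$qc$laserThreshold,
          overlapFraction = config$qc$overlapFraction,
          sMin = config$qc$sMin, sMax = config$qc$sMax,
          sFraction = config$qc$sFraction)
}

#' Run the full pipeline on simulated (or supplied) movies
#'
#' Orchestrates simulate -> photon conversion -> detection -> tracking ->
#' brightness -> quality control -> E/S -> mixture fit -> force summary, and
#' returns every intermediate product plus a run log. All numeric output is
#' reproducible from configuration and seed alone.
#'
#' @param config configuration overrides (see [pipelineConfig()]).
#' @param seed integer seed.
#' @param movies list of [FretMovie-class] objects; NULL simulates them from
#'   the configuration.
#' @return list with `records` (pooled QC-passed records), `fit`
#'   ([MixtureFit-class]), `forces` (force-peak summary), `params`, `range`,
#'   `qcReports`, `config`, `seed`.
#' @export
runPipeline <- function(config = list(), seed = 1, movies = NULL) {
  config <- mergeConfig(pipelineConfig(), config)
  obj <- configObjects(config)
  if (is.null(movies)) movies <- runSimulation(config, seed = seed)
  recs <- vector("list", length(movies))
  qcReports <- vector("list", length(movies))
  for (i in seq_along(movies)) {
    r <- analyzeMovie(movies[[i]], config, obj$factors)
    qcReports[[i]] <- attr(r, "qcReport")
    if (nrow(r)) {
      r$movie <- i
      r$molecule <- r$molecule + i * 1e6  # unique ids across movies
    }
    recs[[i]] <- r
  }
  records <- do.call(rbind, recs)
  params <- calibrateLinker(config$calibration$e0, CalibrationParams())
  range <- assembleDynamicRange(params, config$calibration$fLinearLimit,
                                config$mixture$eMax)
  fit <- fitESMixture(records[records$esValid, , drop = FALSE],
                      maxComponents = config$mixture$maxComponents,
                      eMax = config$mixture$eMax,
                      minWeight = config$mixture$minWeight)
  forces <- summarizeForcePeaks(fit, params, range)
  list(records = records, fit = fit, forces = forces, params = params,
       range = range, qcReports = qcReports, config = config, seed = seed,
       log = list(package = as.character(utils::packageVersion("forcefret")),
                  rVersion = R.version.string, seed = seed,
                  nMovies = length(movies), timestamp = NA_character_))
}
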