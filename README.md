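# forcefret

Single-molecule FRET analysis of molecular tension sensors, from raw
alternating-excitation image stacks to piconewton force distributions.

T cells probe antigen-presenting surfaces by pulling on ligand-engaged
T-cell receptors. A molecular force sensor (MFS) built around a
flagelliform spider-silk spring, flanked by a FRET donor/acceptor pair and
anchored to a supported lipid bilayer, reads those forces out as a drop in
FRET efficiency: pulling stretches the spring, separates the dyes, and
lowers the energy transfer. `forcefret` implements the complete
quantitative analysis for such experiments at the single-molecule level,
plus a synthetic-movie generator with full ground truth so that every
stage can be validated without experimental recordings.

## The model

The spring follows a linear force-extension law,

    F = (r − b·n − c) / (a·n)

with compliance per amino acid `a = 0.0122 nm/pN`, collapsed length per
amino acid `b = 0.044 nm`, `n = 29` amino acids between the dyes, and a
constant linker length `c` determined from zero-force measurements. The
dye separation `r` comes from the Förster relation

    E = 1 / (1 + (r/R0)^6),   R0 = 5.1 nm,

so FRET efficiency maps monotonically to tensile force. Corrected
efficiencies and stoichiometries are computed from the alternating-laser
excitation (ALEX) brightness triplet (f_DD, f_DA, f_AA):

    E = (f_DA − α f_DD − δ f_AA) / (γ f_DD + f_DA − α f_DD − δ f_AA)
    S = (γ f_DD + f_DA − α f_DD − δ f_AA) /
        (γ f_DD + f_DA − α f_DD − δ f_AA + f_AA/β)

with bleedthrough α, direct excitation δ, detection efficiency γ and
excitation efficiency β, each estimated from calibration samples.

## What the package covers

* **calibration** — efficiency ↔ distance ↔ force conversions, linker
  inference, dynamic range, truncated-Gaussian propagation of fitted FRET
  peaks to force means (`fretToForce`, `calibrateLinker`,
  `propagatePeakToForce`).
* **synthetic data** — three-channel EMCCD movies with Gaussian PSFs,
  Poisson shot noise, Brownian motion, state schedules and single-step
  photobleaching, with frame-resolved ground truth (`renderMovie`,
  `sceneTwoState`); fiducial, cell-indicator and DRAAP image generators;
  (E, S) mixture and force-ramp samplers.
* **image preparation** — count→photon conversion, laser-profile
  estimation, mass-conserving Gaussian blur.
* **registration** — affine channel mapping from fiducial beads with
  robust refit, bilinear image warping (`fitAffine`, `warpImage`).
* **detection & tracking** — sum-image spot detection with sub-pixel
  Gaussian fits, nearest-neighbour linking with gap closing,
  ring-background brightness triplets (`detectCandidates`,
  `linkTrajectories`, `measureTrajectoryBrightness`).
* **quality control** — laser-region, overlap, first-frame,
  photobleaching-step (changepoint), stoichiometry and cell-mask filters
  (`qcChain`, `detectSteps`, `bleachFilter`, `makeCellMask`).
* **populations & forces** — Gaussian-mixture fits of the (S, E) cloud
  with the single-component fallback rule, bootstrap errors, force-peak
  summaries (`fitESMixture`, `bootstrapFit`, `summarizeForcePeaks`).
* **kinetics & mobility** — ergodicity ratio, pooled loading-rate fits,
  contact-time windows, MSD diffusion fitting with bootstrap errors,
  smallest-enclosing-circle mobility classification (`ergodicityRatio`,
  `poolAndFitLoadingRate`, `msdFit`, `classifyMobility`).
* **ensemble FRET** — donor recovery after acceptor photobleaching
  (DRAAP), ΔE_bulk, Mann–Whitney group comparison (`eBulk`,
  `compareGroups`).
* **dynamic range** — Kolmogorov–Smirnov detectability simulation for the
  largest measurable low-FRET efficiency (`eMaxThreshold`,
  `assembleDynamicRange`).
* **orchestration** — `runSimulation()` / `runPipeline()` drive the whole
  chain from a single seeded configuration (`pipelineConfig()`).

## Worked example

```r
library(forcefret)

params <- calibrateLinker(0.87, CalibrationParams())
params
#> CalibrationParams
#>   a  = 0.0122 nm/pN (compliance per amino acid)
#>   b  = 0.0440 nm (collapsed length per amino acid)
#>   n  = 29 amino acids
#>   c  = 2.4 nm (linker)
#>   R0 = 5.10 nm

assembleDynamicRange(params)
#> DynamicRange: E in [0.11, 0.80]  <->  F in [0.9, 10.0] pN

pk <- propagatePeakToForce(0.42, 0.22, params, assembleDynamicRange(params))
sprintf("mean force %.2f pN, sd %.2f pN", pk$mean, pk$sd)
#> "mean force 4.79 pN, sd 1.96 pN"
```

The linker constant of 2.4 nm reproduces the collapsed sensor at zero
force; the dynamic range spans 0.9–10 pN; a fitted low-FRET peak at
E = 0.42 (sd 0.22) corresponds to an average pulling force of about
4.8 pN with a 2 pN spread.

A fully synthetic end-to-end run (two small movies, ~10 s):

```r
out <- runPipeline(list(nMovies = 2, scene = list(nMolecules = 12)), seed = 7)
out$fit
#> MixtureFit: 2 component(s), n = 557
#>   comp 1: weight 0.625, E = 0.869 (sd 0.022), S = 0.500
#>   comp 2: weight 0.375, E = 0.419 (sd 0.026), S = 0.498
out$forces[, c("role", "weight", "meanE", "meanForce", "sdForce")]
#>         role weight meanE meanForce sdForce
#> e  collapsed  0.625 0.869      0.00      NA
#> e1 stretched  0.375 0.419      4.72   0.273
```

The simulator planted molecules at E = 0.87 (collapsed) and E = 0.42
(stretched); after detection, tracking, quality filtering and mixture
fitting, both state means are recovered to better than 0.01 and the
stretched component converts to 4.7 pN. (Record-count weights at this
small scale reflect per-molecule photobleaching times; the full-scale
recovery is exercised in the test suite.)

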