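---
title: "Methods: single-molecule FRET force-sensor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule FRET force-sensor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(forcefret)
```

# The measurement and its model

A molecular force sensor (MFS) anchors a TCR ligand to a supported lipid
bilayer through an elastic peptide derived from the spider-silk protein
flagelliform, flanked by a FRET donor (AF555) and acceptor (AF647). A
T cell pulling on the ligand stretches the spring and lowers the FRET
efficiency. Two readouts are supported:

* **Ensemble (DRAAP)**: donor recovery after acceptor photobleaching gives
  a bulk efficiency `E_bulk = (f_post − f_pre)/f_post` per region of
  interest; cell-minus-control differences ΔE_bulk report stretching under
  the synapse.
* **Single molecule (ALEX)**: alternating green/red excitation yields per
  molecule and frame the brightness triplet (f_DD, f_DA, f_AA), from which
  crosstalk-corrected efficiency E and stoichiometry S are computed; a
  mixture fit of the (S, E) cloud separates collapsed from stretched
  sensors, and the calibration converts the stretched peak to force.

## Force calibration

The spring is modelled as linear, `F = (r − b·n − c)/(a·n)`, with defaults
`a = 0.0122` nm/pN, `b = 0.044` nm, `n = 29` residues, and the dye
separation follows `E = 1/(1 + (r/R0)^6)` with `R0 = 5.1` nm. The linker
constant `c` is not a free dial: it is inferred at run time from the
collapsed-state efficiency measured without cells (`calibrateLinker`),
`c = r(E0) − b·n`, and carried **unrounded** (`E0 = 0.87` gives
`c ≈ 2.439` nm, displayed as 2.4). Rounding `c` would shift the force
working points by several percent; reproducing `F = 10` pN at `E = 0.11`
and `F = 0.9` pN at `E = 0.8` requires the unrounded value.

Forces below the collapsed length (`r < b·n + c`) come out negative and
are reported as such, with clamping left to the caller (`pointForces`
flags clamped records). Keeping zero-force noise symmetric avoids biasing
peak fits.

`propagatePeakToForce` transforms a Gaussian efficiency peak, truncated to
the sensor's dynamic range, through the nonlinear map by deterministic
trapezoidal quadrature on 2001 nodes concentrated on the ±10 sd support of
the peak. Monte-Carlo sampling appears only as an independent oracle in
the test suite. The expectation of the transformed distribution is
reported as the mean pulling force; because the map is convex over most of
the range, it sits slightly above the point transform of the peak mean —
both are exposed, as either convention is defensible.

## Dynamic range

`E_min` is set by restricting the spring to its linear regime up to 10 pN
(`assembleDynamicRange`, giving `E_min ≈ 0.11`). `E_max` is limited by
overlap with the collapsed-state peak at `E = 0.87` (sd 0.12): mixture
samples of n = 2300 with a low-FRET peak of weight 0.15 are compared to
pure collapsed-state samples by a two-sample Kolmogorov–Smirnov test
(`ksDetectability`). `E_max` is the largest low-peak mean still detected.
The significance cut on the median p-value defaults to α = 0.05 and the
median is taken over 50 replicate draws per grid point — the replicate
median is a stability choice; single draws give the same threshold up to
one grid step. Detectability is monotone in the low-peak weight, so the
weight-0.15 threshold is the conservative bound.

# The synthetic-data generator

The generator defines the study conditions under which every downstream
module is validated; its defaults are not tuned per test.

* **Camera**: EMCCD conversion with 15.7 photons/count, EM gain 300,
  160 nm pixels, Gaussian read noise (1 count sd) and offset (100 counts).
  The EM conversion is a deterministic scale — gain excess noise is *not*
  modelled, matching the plain count→photon conversion used in the
  analysis. Counts are therefore slightly less dispersed than a real
  EMCCD's; shot noise still dominates at the photon budgets used.
* **PSF**: integrated 2D Gaussian per pixel (error-function mass), sigma
  defaulting to 1 pixel. Point sampling would bias sub-pixel brightness
  and localization checks.
* **Emission model**: a pair with donor-excitation budget B emits
  `f_DD = B(1−E)`, sensitised acceptor emission `γBE`, and
  `f_AA = βγB` under red excitation, so an intact pair has corrected
  E equal to its scheduled state and S = 0.5 exactly; double-donor and
  double-acceptor species land at S = 2/3 and 1/3 and must be removed by
  the stoichiometry filter. The DA image additionally receives
  `α f_DD + δ f_AA` (bleedthrough, direct excitation), all scaled by the
  *green* laser profile — direct acceptor excitation is green-laser
  physics — which makes the four factor estimators exactly identifiable.
* **Dynamics**: Brownian steps per frame pair (`sqrt(2 D dt)` per axis),
  E-state schedules, and single-step photobleaching at exponential times.
  Blinking kinetics, triplet states and vesicle/microcluster morphology
  are *not* modelled; real data will violate the single-step assumption
  more often, so the photobleaching filter's acceptance rate on real data
  will be lower than on clean simulations.
* **Photon budgets** are not published for this kind of recording; the
  default of 600 photons/frame/molecule gives spots of SNR ≈ 10–15 at the
  default background of 2 photons/pixel, a realistic TIRF working point.
  It is configuration-exposed.

Because the generator and the estimators share the emission *formulas* but
nothing else (detection, tracking, background estimation and filtering all
operate on the rendered images), passing tests demonstrate internal
consistency of the full chain and correct parameter recovery under the
stated noise model — not robustness to the artefacts the generator does
not emulate (uneven background, rolling-shutter timing, gain fluctuation).

# Image processing choices

* **Blur**: separable Gaussian convolution with reflective (whole-sample
  symmetric) boundaries, which conserves total intensity exactly for
  interior spots — the brightness estimator sums blurred pixels, so mass
  conservation is load-bearing. Kernels are truncated at 4 sd.
* **Counts→photons**: `(counts − offset) · photonsPerCount / emGain`.
  Whether an offset is subtracted before conversion is unstated in common
  protocols; it is configurable (`subtractOffset`, default on) and the
  default camera carries an explicit 100-count offset.
* **Laser profile**: Gaussian blur (sigma 10 px) of a stained-sample
  image, scaled to max 1; brightness values are divided by the profile at
  the molecule position; records below 50% of the profile maximum are
  discarded.

# Detection, tracking, brightness

Candidates are local maxima of the sigma-1 blurred image above
`median + k·MAD` (k = 4), refined by Levenberg–Marquardt least squares of
an integrated Gaussian plus constant background on a 9×9 patch; fits are
rejected when the width leaves (0.3, 4) px or the centre moves more than
2 px. Detection runs on the sum image `T(Im_DD) + Im_DA` for green frames
(so low- and high-FRET molecules are detected with the same sensitivity)
and on `Im_AA` for red frames, interlaced in recording order.

Linking is greedy nearest-neighbour with an 800 nm search radius between
consecutive interlaced frames. Gap memory is counted in frame pairs
(time points): a molecule dark for up to 3 pairs is re-linked and its
positions filled by linear interpolation (flagged). Trajectories with
fewer than 4 observed pairs are discarded. Ties are broken by ascending
distance after a deterministic sort, so the result is invariant to input
row order.

Brightness is measured on the blurred photon images: foreground = pixels
within 4.5 px of the rounded position (9 px diameter), background = mean
over a 4.5–7.5 px annulus excluding pixels within 4.5 px of any other
molecule. The 3 px annulus width is a compromise between locality and a
stable mean (~110 pixels). If the whole ring is excluded, the global image
median substitutes and the record is flagged. f_DD is measured at the
position mapped back to donor-channel geometry via the inverse channel
transform.

# Quality-control chain

Order: laser region → overlap → first frame → photobleaching → truncation
→ stoichiometry → cell mask. The chain is idempotent (truncated records
are marked and pass through unchanged on a second run).

* **Step detection** (`detectSteps`): greedy binary segmentation of the
  trace with a BIC stopping rule (penalty 2·log n per changepoint),
  followed by merging of steps whose amplitude falls below 3× the local
  plateau noise. The local noise is `max(sd(left), sd(right), global
  floor)` — a global estimate would be dominated by the quiet post-bleach
  background and keep spurious plateau wiggles, since shot noise scales
  with brightness. Minimum plateau length is 2 frames.
* **Bleach filter**: accept only trajectories whose f_AA trace has exactly
  one downward step ending at background; any mid-trace downward step of
  f_DD + f_DA that does *not* reach background is treated as partial donor
  photobleaching (multi-emitter or defective sensor) and rejects the
  trajectory; a terminal donor bleach to background is allowed and, like
  the acceptor step, defines the truncation point. Records from the
  earliest bleach onward are dropped.
* **Stoichiometry**: trajectories with more than 25% of records outside
  S ∈ [0.35, 0.6] are removed (multi-donor above, multi-acceptor below).
* **Cell mask**: adaptive threshold = local mean over 51 px blocks plus an
  offset, optional small-component cleanup; the block size and offset are
  exposed because no standard parameterisation exists for this step.

# Correction factors and populations

α and δ are medians of the ratios f_DA/f_DD (donor-only) and f_DA/f_AA
(acceptor-only); the median is used throughout as the robust location for
ratio estimators. γ comes from acceptor-bleach events in high-FRET control
data — the crosstalk-corrected FRET drop divided by the donor rise across
the step, plateaus averaged over ≥5 points excluding one frame around the
step, median over events; high-FRET controls give the larger intensity
contrast and hence the lower-variance estimate. β solves
`median S = 0.5` on a known 1:1 calibration sample by a monotone
root-find on (1e-3, 1e3).

The (S, E) cloud is fitted by a full-covariance Gaussian mixture
(maximum likelihood EM with deterministic model-based hierarchical
initialisation; for more than 5000 points the initialisation uses a
deterministic evenly spaced subset of 2000). Up to two components are
fitted; when the low-FRET component's mean exceeds `E_max` or its weight
falls below 0.1, a single-component fit is reported and flagged
(fallback). Degenerate covariances trigger a conjugate-prior-regularised
refit. Bootstrap standard errors (100 resamples of the original size)
restart EM from the full-data solution so every resample stays in the
same likelihood basin; components are matched to the original by nearest
mean efficiency, which resolves label switching. The fallback rule is not
re-applied inside the bootstrap, since model selection was already made on
the full data.

# Kinetics and mobility

* **Ergodicity**: trajectories with ≥5 efficiency records below 0.6 are
  selected; the ratio of the mean per-trajectory force sd to the pooled sd
  approaches 1 when single molecules sample the full force distribution
  within one trajectory, and falls toward 0 when force levels are frozen
  over the observation window.
* **Loading rate**: each ramp's peak is the maximum of a 5-point
  median-filtered force trace; the rising phase is the contiguous stretch
  ending at the peak that starts where the filtered trace last crosses 5%
  of the peak-to-baseline height. This fractional-height delimiter
  replaces a literal "last local minimum before the peak", which at the
  working noise level (efficiency sd 0.05 at 10 frames/s) selects 2–5
  points conditioned on the peak and inflates the slope by tens of
  percent; the fractional rule is unbiased to within ~3% in simulation.
  Rising phases are pooled after aligning peaks in time and fitted by
  ordinary least squares.
* **MSD**: squared displacements pooled per lag 1–10; in each of 100
  bootstrap rounds the data are resampled, per-lag means computed, and
  `MSD = 4 D t_lag + 4 ε²` fitted; the reported D and ε are means ± sd
  over rounds (negative intercepts are truncated at ε = 0). Two resampling
  units exist: per-lag displacement sets (the conventional procedure,
  default) and whole trajectories. Overlapping displacements of one
  trajectory are strongly correlated, so the displacement-set bootstrap
  understates the experiment-to-experiment error severalfold for fast
  diffusion; the trajectory bootstrap is calibrated against repeated
  simulations and is what the package's own recovery tests use.
* **Mobility**: the smallest enclosing circle of a trajectory (exact
  Welzl-type incremental algorithm, deterministic point order) gives
  `r_c/√t_d`; molecules below 0.35 µm·s^−0.5 are classified immobilized.
  The brute-force oracle over point pairs and triples lives in the test
  suite.

# Statistical conventions

Group differences use the two-sample Mann–Whitney U test with tie
correction; p < 0.01 counts as significant. All simulations accept a seed
and are bit-reproducible from configuration plus seed; the pipeline's
reproducibility is asserted as a test.

# Problem sizes in the test suite

The validation suite runs at desk scale: the end-to-end recovery uses six
simulated movies of 24 molecules each (96×96 px, 150 frame pairs,
600 photons/frame, mean acceptor bleach 4 s, donor 12 s), which yields
roughly 4000 quality-controlled records — enough that the fitted state
means carry standard errors well below the 0.03 tolerance being asserted.
Step-detection and mobility rates use 300–400 replicates; the KS
detectability grid uses 50 replicates per point. These sizes are the
package's validation design, chosen for statistical adequacy.

# Known limitations

* The spring model is linear by construction; worm-like-chain or other
  nonlinear elasticity, and temperature dependence of `R0`, are out of
  scope (the calibration object accepts any `R0`).
* The simulator omits fluorophore blinking kinetics, EM-gain excess noise
  and structured backgrounds; quality-filter acceptance rates on real data
  will be lower than on simulations.
* Registration supports affine distortion only; field-dependent
  (polynomial) chromatic distortion is not modelled.
* The mixture model assumes Gaussian components in (S, E); strongly
  non-Gaussian stretched-state distributions would bias the force peak.
* Whether published peak forces are the force at the mean efficiency or
  the mean of the transformed force distribution is convention-dependent;
  both are computed (`fretToForce(meanE)` vs `propagatePeakToForce`), and
  the summaries report the latter.
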