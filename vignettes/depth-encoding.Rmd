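---
title: "Modeling horizontal and depth position codes with inverted encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling horizontal and depth position codes with inverted encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthIEM)
```

## The problem

A stereoscopic stimulus rendered in a 3-D scene has a position along the
horizontal (x) axis, signalled directly by its retinal location, and a
position along the depth (z) axis, signalled indirectly by the binocular
disparity between the two eyes' images. fMRI voxels in retinotopic visual
cortex carry graded information about both. This package implements, end to
end, the analysis needed to ask how well a voxel population encodes each
axis: a forward model of voxels as mixtures of position-tuned channels, its
inversion on held-out data to obtain a *model-based representation* of the
viewed stimulus, quantification of those representations by constrained
curve fitting, a complementary pairwise decoding analysis scored by d', and
group-level bootstrap statistics. Because real BOLD data are not required
for any of the machinery to be exercised, the package also contains a
first-class synthetic-data generator whose ground truth is known exactly.

## Stereo viewing geometry

The scene is rendered with two cameras at x = −0.4 and +0.4 scene units
(interpupillary distance 0.8) fixating straight ahead at distance D = 10.
For a point at horizontal offset x and depth z (positive z toward the
viewer, so the point sits at viewing distance d = D − z), the relative
disparity with respect to fixation is

$$\delta(x, z) = 2\,\mathrm{atan}\frac{e}{D} -
 \left[\mathrm{atan}\frac{x+e}{d} - \mathrm{atan}\frac{x-e}{d}\right],$$

converted to arcminutes; crossed (near) disparities are negative. On the
fixation plane $\delta = 0$ exactly, and at the nearest on-axis depth row
(z = 1.5) the model gives −48.4 arcmin.

The stimulus grid places six depth rows (z = −1.5 to 1.5, step 0.6) by six
columns. Column positions are defined in eccentricity: within each row the
unsigned eccentricities fill 0.9°–9.8° evenly (three columns per side), and
alternate rows are staggered by a quarter of the column spacing, making the
grid triangular. Scene-unit x coordinates follow as x = d · tan(θ), i.e.
every row spans the same eccentricity range. We chose this layout over a
single shared scene-unit spacing because it is the only simple layout
consistent with all the design quantities at once: the grid disparities
span +42.7 to −48.4 arcmin, and the per-row disparity averages agree with
the package's reference table (`depthRowDisparities()`: 38.6, 25.6, 11.1,
−5.2, −23.6, −44.6 arcmin) to within ~0.2 arcmin. Mirrored grids (x
negated, used on alternate runs) make a run pair sample 72 distinct
locations, 12 columns per row. The grid code is fully configurable
(`gridSpacing()`), so other layouts remain available.

Sphere radius is interpolated linearly in viewing distance between the
rendered anchors (0.73 scene units at d = 11.5, 0.55 at d = 8.5), which
holds the apparent size constant. We deliberately anchor on the two printed
scene-unit sizes rather than derive the radius from a single angular size,
because no single angular radius reproduces both anchors under tangent
scaling.

## The synthetic experiment

`simulateExperiment()` emulates the study design: 9 subjects, 13 run pairs
(26 runs) by default, 36 stimulus trials per run (one per grid location,
shuffled) plus 9 null trials, with the mirrored grid on even-numbered runs.
Each subject gets an independent voxel population (`makeVoxels()`, 60
voxels by default): a voxel's tuning along each axis is a nonnegative
(half-normal) mixture of six generative exponentiated-cosine channels, and
its trial response is the tuned response plus iid Gaussian noise. Tuning
along x and z is additive, so the same dataset supports both axis models;
when one axis's model is analysed, the other axis's tuning acts as
structured trial-to-trial variability, as in real data.

Noise can be given in absolute response units or relative to the mean
per-voxel peak response. The default (relative SD 2.5) was calibrated once
so that six-way depth decoding of the default dataset lands mid-range in
0–0.6, the d' regime reported for real BOLD data; it is a reporting choice,
not an estimate of true cortical SNR.

Two features of real data the generator does *not* emulate: spatially
correlated (voxel-to-voxel) noise, and any tolerance/interaction structure
between x and z tuning beyond additivity. Passing tests therefore show the
pipeline's correctness and statistical behaviour under a known population
code, not that real cortex matches this generative family.

A time-series mode is included for testing the trial-estimate extraction
step: `simulateTimeseries()` convolves each trial's noiseless response with
a canonical two-gamma HRF (peak 5 s, undershoot peak 15 s, ratio 6,
dispersions 1 s) at TR 2 s, 150 volumes per 300-s run, with optional white
noise and linear drift; trial onsets are jittered and not locked to volume
times, and the drawn inter-trial intervals are rescaled by a common factor
so the schedule exactly fills the run. `extractTrialEstimates()` z-scores
each voxel within the run and averages the volumes at offsets +3 and +4
from the last volume at or before onset (about 6–8 s post-onset). The
reference-volume convention (floor rather than round) was chosen because it
is deterministic under unlocked onsets.

## The inverted encoding model

The forward model is linear: $B_1 = W X_1$, with $B_1$ the voxels × trials
training responses, $X_1$ the channels × trials design matrix, and $W$ the
voxels × channels weights. Channels are exponentiated cosines,

$$f(r) = \left(0.5\cos\frac{r\pi}{s} + 0.5\right)^7 \quad (r < s;\ 0
\text{ elsewhere}),$$

six of them tiling the modeled axis. Their centers and size are not
design-determined, so we default to the six stimulus row coordinates
(−1.5 … 1.5, spacing 0.6) with size s = 1.8, giving adjacent-channel
overlap $0.75^7 \approx 0.13$; both are arguments of `buildBasis()`. The
design matrix is $X_1 = F S$ where F samples the basis on a 111-pixel grid
over [−2.75, 2.75] (spacing 0.05, matching the fitting domain) and S is
the pixel representation of each trial's stimulus — a delta at the nearest
pixel by default, with a normalized boxcar (e.g. of the sphere radius)
available. The delta default is the simplest faithful pixel encoding; with
six channels the two choices give nearly identical design matrices.

Weights are the least-squares solution $\hat W = B_1 X_1^\top (X_1
X_1^\top)^{-1}$, i.e. $B_1\,\mathrm{pinv}(X_1)$. (Written with the
trials × trials Gram matrix instead, the normal equations would be singular
whenever trials exceed channels; the row-space form is the Moore–Penrose
solution in the full-row-rank case.) Inversion on held-out runs is the left
pseudoinverse, $\hat X_2 = (\hat W^\top \hat W)^{-1} \hat W^\top B_2$, and
$\hat X_2^\top F$ gives the trials × pixels model-based representations.
Training/testing follows leave-one-run-out cross-validation so each run is
tested exactly once. Rank-deficiency in either solve is an error (naming
the unidentified channels), not a silent regularization.

For position averages, curves from mirrored runs are reflected about the
(symmetric) pixel-domain midpoint and pooled within column index for x, and
pooled within row for z, yielding six mean representations per axis. The
mirrored-run bookkeeping is carried per trial (a `mirrored` flag set by the
generator), so whether even or odd runs are mirrored is a simulation
setting (`mirrorRuns`), not an analysis-time convention. Because of the
stagger, the trials pooled into one x column sit up to ±0.16 scene units
around the column center; the reported true coordinate is their mean.

## Curve fitting

Each representation is fitted with the channel profile plus amplitude and
baseline, $f(x) = b + a(0.5\cos(|x-c|\pi/s)+0.5)^7$, in two stages
(`fitRepresentation()`):

1. exhaustive grid over centers −2.75 … 2.75 (step 0.1) × sizes 1.5 … 15
   (step 0.1); at each node the bounded (a, b) regression is solved exactly
   — unconstrained least squares, clamp a into [0, max − min], re-solve b —
   and the lowest-RMSE node wins, with ties broken toward the smaller
   center then smaller size for determinism;
2. bounded local refinement (`L-BFGS-B`) of all four parameters with c and
   s confined to ±0.1 of the grid optimum, b to [−5, 5], a to
   [0, max − min]; if refinement fails or increases the RMSE the grid fit
   stands.

On noiseless curves this recovers centers to better than 0.01 scene units
*provided the curve is identifiable within the window*: the peak must lie
inside the domain and the curve's baseline must be visible (support not
extending past both edges), because the amplitude bound is taken from the
windowed curve's own range. Broad curves truncated by the window
(size beyond roughly 2.75 + |center|) cannot reach their true amplitude
under that bound, and their best feasible fit shifts the center — an
inherent property of the bounded procedure, not a numerical failure. With
5% amplitude noise the median center error over identifiable curves stays
below 0.1. The unit-amplitude grid curves are
precomputed once (`precomputeFitGrid()`) and shared across fits, so a full
study (108 averaged representations) fits in seconds.

## Decoding

`pairwiseDecode()` discriminates two depth rows (collapsing x within row)
with a linear maximum-margin classifier (libSVM via e1071, cost 1) under
leave-one-run-out cross-validation, pooling held-out predictions.
Performance is reported as $d' = \Phi^{-1}(\mathrm{HR}) -
\Phi^{-1}(\mathrm{FAR})$ with rates clipped to $[1/(2N), 1 - 1/(2N)]$, the
standard correction for perfect rates. Two solver settings differ from
libSVM's defaults, both exposed as arguments: features are standardized on
the training fold (real trial estimates are z-scored; this keeps the
decision invariant to simulation scale), and the stopping tolerance is 0.01
rather than 0.001 (on example data the looser tolerance changed 2 of 576
held-out predictions and no downstream statistic, while avoiding the
solver's iteration cap on low-SNR data).

The 15 row pairs (`pairwiseScheme()`) carry the published row-average
disparity differences; their mean d' is the six-way decoding score.
Significance uses a permutation null (`permutationNull()`: labels shuffled
across all trials of the restricted dataset, full cross-validated decode
repeated, 1000 iterations in the reference design), compared at the
subject-averaged level by the minimum of the two tail proportions — exactly
as specified, not doubled; a `smooth` option gives the add-one variant so p
is never exactly zero. Families of p-values are corrected with
Benjamini–Hochberg step-up (`fdrBh()`, a thin wrapper over
`stats::p.adjust`). The d'-versus-disparity slope is estimated by OLS on
subject-resampled pair means (`dprimeDisparitySlope()`), reported with a
percentile CI, a t test of the slope distribution against zero (kept for
fidelity to the reference analysis despite being statistically
unconventional on a bootstrap distribution), and the tail-proportion
p-value as the principled alternative.

A note on what scales with disparity. With the default generative tuning
(the analysis basis: size 1.8, exponent 7) the six depth rows evoke nearly
orthogonal response patterns — adjacent-row channel overlap is 0.13 — so
pattern separation, and hence d', is essentially flat across pairs. Graded
growth of d' with disparity difference, the signature seen in real cortex,
requires generative tuning broad enough that pattern similarity decays over
the whole depth range; the generator provides this as a raised-cosine mode
(`size = 3.6, exponent = 1`), which the discriminability-scaling checks
use. The slope-recovery checks keep generative = analysis tuning.

## Group statistics

`bootstrapSubjects()` resamples subjects with replacement (1000 iterations
in the reference design) and applies the statistic per draw; intervals are
percentile 2.5/97.5 (the resampling variant was not further specified, and
percentile is the simplest estimator consistent with the procedure; BCa was
deliberately left out rather than silently substituted).
`bootstrapCenterSlope()` fits the fitted-centers-versus-true-positions line
on every iteration; slope 1 means perfect position recovery, slope 0 no
positional information. Distribution-versus-zero and paired-distribution
p-values use the same minimum-tail-proportion rule as the permutation test.
Per-subject (non-bootstrapped) representation errors are tabulated
separately for any downstream regression-style modeling; hierarchical
mixed-model comparisons themselves are out of scope.

## Orchestration and reproducibility

`runPipeline()` chains simulate → IEM → fit → decode → stats from a nested
configuration list (`defaultPipelineConfig()`, YAML-loadable via
`readPipelineConfig()`), validates every block before any computation, and
optionally writes all tables as CSV together with the configuration and a
manifest (config MD5, seed, file list). Stages compose: running them
separately over a carried bundle is numerically identical to a single-shot
run. Every stochastic operation is a pure function of its inputs and an
explicit seed (internally, fixed-stream child seeds derived from the master
seed), so identical configurations give byte-identical tables.
`pipelineReport()` summarizes a bundle as text and, optionally, writes
diagnostic figures. The package's functions are the interface; the
pipeline runner plays the role of a command-line front end for scripted
use.

## Problem sizes used in the checks

The packaged checks run the reference design at reduced scale chosen to
exercise every code path with comfortable statistical margins: exactness
checks use 1 subject, 2–4 noiseless runs and 12–20 voxels; parameter
recovery uses 9 subjects × 12 runs × 60 voxels at trial noise 0.5 × mean
peak response; curve-fit recovery uses 100 random curves; permutation
nulls use 60–200 iterations except where the 1000-iteration reference
design is itself under test. These sizes are the package's choices for its
own verification and are stated here so they can be scaled up freely.

## Known limitations

- The generative voxel model is additive across axes and noise is iid
  across voxels and trials; claims about real cortical depth codes cannot
  be read off the simulations.
- The x-axis column positions inherit a ±quarter-spacing stagger, so x
  position averages pool slightly heterogeneous coordinates (faithful to
  the triangular design, but a source of apparent width in x
  representations).
- The 2-D joint (x, z) encoding model is out of scope; the two axes are
  modeled separately, so depth results rely on voxels whose depth tuning
  tolerates horizontal displacement.
- Disparity-domain fitting is not provided: representations are fitted in
  scene units, where the stimulus rows are evenly spaced.
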