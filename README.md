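# depthIEM

Population codes in visual cortex carry information about where a stimulus
is — not only across the visual field (horizontal position, *x*) but also
in depth (*z*), which must be inferred from the binocular disparity between
the two eyes' images. `depthIEM` is an R package for building and
validating the full analysis chain used to recover such position codes from
trial-wise fMRI voxel responses:

- **Stereo geometry** — eyes at ±*e* fixating at distance *D*; a point at
  horizontal offset *x* and viewing distance *d = D − z* has relative
  disparity `2 atan(e/D) − [atan((x+e)/d) − atan((x−e)/d)]` (arcmin,
  crossed/near negative). A staggered triangular 6 × 6 stimulus grid spans
  0.9°–9.8° of eccentricity per depth row and +42.7 to −48.4 arcmin of
  disparity; a run pair (grid + horizontal mirror) samples 72 distinct
  locations.
- **Inverted encoding model (IEM)** — voxels are modeled as linear
  mixtures of six exponentiated-cosine channels,
  `f(r) = (0.5 cos(rπ/s) + 0.5)^7` for `r < s`, tiling the axis of
  interest. Weights are the pseudoinverse solution of `B₁ = W X₁` on
  training runs; inversion of held-out runs,
  `X̂₂ = (ŴᵀŴ)⁻¹Ŵᵀ B₂`, followed by projection through the basis yields
  pixel-space *model-based representations* of each viewed stimulus, under
  leave-one-run-out cross-validation.
- **Curve fitting** — each representation is fitted with
  `b + a (0.5 cos(|x−c|π/s) + 0.5)^7` by an exhaustive (center × size)
  grid with exact bounded amplitude/baseline regression, then a
  box-constrained local refinement.
- **Decoding** — pairwise linear-SVM classification of the 15 depth-row
  pairs scored by d′ (`Φ⁻¹(HR) − Φ⁻¹(FAR)` with extreme-rate clipping),
  permutation nulls, Benjamini–Hochberg FDR, and the d′-versus-disparity
  slope.
- **Group statistics** — bootstrap resampling across subjects for CIs and
  the center-versus-true-position slope (1 = perfect recovery, 0 = no
  positional information).
- **Synthetic data** — a first-class generator with known ground-truth
  voxel tuning (and an optional HRF-convolved time-series mode at TR 2 s),
  so every stage is testable without any scanner data.

The methods vignette (`vignettes/depth-encoding.Rmd`) explains the model,
parameter choices and limitations in detail.

## Worked example

A small synthetic study, end to end (3 subjects, 8 runs, 40 voxels, trial
noise 0.5 × mean peak response):

```r
library(depthIEM)

cfg <- defaultPipelineConfig()
cfg$simulation$n_subjects <- 3L
cfg$simulation$n_runs    <- 8L
cfg$simulation$n_voxels  <- 40L
cfg$simulation$seed      <- 42L
cfg$simulation$noise     <- list(type = "relative", sd = 0.5)

bundle <- runPipeline(cfg)
pipelineReport(bundle)
```

```
depthIEM pipeline report
========================
Simulation: 3 subjects, 8 runs, 40 voxels, seed 42
Six-way decoding: mean d' = 2.139
d'/disparity slope: 0.0127 per arcmin [0.0017, 0.0242], p(t) = 0
x axis: center-vs-true slope 0.910 [0.898, 0.922] (p = 0), mean |center error| 0.098
z axis: center-vs-true slope 0.965 [0.952, 0.972] (p = 0), mean |center error| 0.039
```

Reading the output: the mean of the 15 pairwise d′ values ("six-way"
decoding) says how discriminable the six depth rows are overall; the
d′/disparity slope says how discriminability grows per arcminute of depth
separation. The center-vs-true slopes near 1 with small mean |center
error| (scene units) show that the inverted encoding model places the
reconstructed stimulus representations at the correct positions along both
axes. At the package's default noise level — calibrated to emulate
realistic BOLD signal-to-noise, where six-way d′ sits in the 0–0.6 range —
the same pipeline yields much shallower slopes, as expected.

Individual stages are ordinary functions on ordinary objects:

```r
sim   <- simulateExperiment(nSubjects = 1, nRuns = 4, nVoxels = 20, seed = 1)
basis <- buildBasis()
rec   <- crossvalReconstruct(subjectData(sim, 1), basis, axis = "z")
avg   <- averageByPosition(rec)
fitReconstruction(avg)          # center/size/amplitude/baseline per position
sixWayDecode(subjectData(sim, 1))
```

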