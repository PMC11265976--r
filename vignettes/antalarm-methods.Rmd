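---
title: "Methods: antennal-lobe response quantification and alarm-curve comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antennal-lobe response quantification and alarm-curve comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antalarm)
```

This vignette documents the models, conventions and numerical choices
behind `antalarm`, in the spirit of a statistics-package methods section.
Nothing here asserts an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The imaging quantification chain

A trial is a 4D fluorescence movie `[frame, z, y, x]`
(`volume_series`), one volume every 0.83 s by default — the cadence of
the volumetric two-photon acquisitions this package targets, which scan
512 × 512 × 33 voxel volumes. All frame and plane indices are **1-based**
throughout the package, so the conventional analysis windows read exactly
as they are usually quoted: baseline frames 1–5, peak frames 9–14, AUC
frames 6–40. (The on-disk ROI JSON format is the one exception: it stores
0-based, half-open rectangles, a file-format convention.)

The chain implemented by `build_response_map()` is, in fixed order:

1. **Baseline** `B` = per-pixel mean of frames 1–5, before odor-evoked
   responses begin (the default stimulus timing — trigger at frame 3,
   3 s valve delay, 5 s delivery — puts odor arrival after frame 6).
2. **Fold change** `ΔF/F = (F_t − B)/B`. Pixels with `B ≤ ε` are
   undefined: they are masked, set to 0 and counted
   (`attr(fc, "n_undefined")`). The default
   `ε = 10⁻⁶ × max(movie)` scales with the data because fluorescence
   units are arbitrary. Since intensities are non-negative, every defined
   value is ≥ −1.
3. **Peak** = per-pixel mean ΔF/F over frames 9–14.
4. **Minimum filter**, radius 2, per plane: each pixel becomes the
   minimum over the disc `dy² + dx² ≤ r²` (13 pixels at r = 2), with
   nearest-value edge padding. A disc was chosen because that is the
   neighborhood the common rank-filter implementations use for a
   "2-pixel" radius; a square window is available via
   `shape = "square"`. The filter is deliberately applied per plane
   *before* projection (the printed order of the workflow it reproduces);
   `filter_before_projection = FALSE` swaps the order for sensitivity
   analysis only.
5. **Max-Z projection** across planes.
6. **Clip** to `[−1, 4]`: −1 is the hard lower bound of fold change,
   4 the saturation ceiling used for display and comparison
   standardization. Clipping is last.

The baseline window is validated to precede the peak window. Every map
carries a `provenance` attribute with all parameters.

**Why a minimum filter matters for interpretation.** The filter erodes
the rim of a responding region by its radius, so the flat top of a
glomerulus-scale response survives but single-pixel noise is removed.
ROI means should therefore be taken a couple of pixels inside anatomical
boundaries (the simulator's `ground_truth_rois()` shrinks its discs by
3 px for exactly this reason).

### ROI-level statistics

* `classify_responding_rois()`: per ROI × odorant, the mean map value is
  averaged across that odorant's trials; **responds ⇔ mean ≥ 0.2**, an
  inclusive threshold stored with every call. Trials flagged by
  `flag_motion_artifact()` are dropped *before* averaging; an odorant
  whose trials are all excluded yields `responds = NA` (undetermined),
  never `FALSE`. When a whole-AL ROI is supplied, a `broad_response`
  flag marks odorant panels where more than 25% (configurable) of AL
  pixels exceed the threshold — such panels activate the AL too broadly
  for discrete ROI counting to mean much, and the flag makes that caveat
  machine-readable instead of discarding the data.
* `glomerular_trace()`: max-Z over the center plane ±1 (edge planes use
  the available neighbors, with a message), *then* ΔF/F of the projected
  series against its own frames 1–5 baseline, then the ROI mean — the
  projection-before-ΔF/F order matters and is tested. `AUC` is the plain
  sum over frames 6–40 (35 frames); movies shorter than the window
  return a trace without an AUC and a warning rather than a truncated
  sum.
* `compare_cohorts()`: Welch's t (unequal variances,
  Welch–Satterthwaite df) or Wilcoxon rank-sum (normal approximation
  with continuity correction where applicable), both two-sided, via the
  vetted `stats` implementations. Two constant, equal groups return
  p = 1 by convention with a message.

### Stabilization

Acquisition-ordered stacks (z fastest) are split per plane by
`deinterleave()`; `interleave()` inverts it exactly. Registration is
rigid, in-plane and per z-plane: `estimate_translation()` takes the
integer argmax of the FFT cross-correlation (images mean-subtracted),
then refines it on a ±1 px window at 1/`upsample` pixel steps by direct
matrix DFT of the cross-power spectrum. Plain cross-correlation is the
default; phase correlation (`normalize = "phase"`) gives a sharper peak
on structure-rich images. Registration on a constant image is undefined
and errors.

Two numerical choices deserve explanation:

* **Reference refinement.** The natural reference — the mean of baseline
  frames 1–5, which ties registration to the ΔF/F baseline — is blurred
  when those frames themselves carry motion, and a blurred reference
  biases subpixel peaks by several tenths of a pixel. `stabilize_series()`
  therefore re-estimates in passes (default `refine_iterations = 2`):
  after each pass the reference is rebuilt from the *aligned* baseline
  frames and all shifts are re-estimated from the original frames, so
  frames are only interpolated once. Residuals against simulated
  ground-truth drift drop from ~0.4 px to below 0.1 px with refinement
  (measured in the test suite and acceptance script). Because the
  reference's absolute position is unidentifiable, residuals are always
  assessed after removing the per-movie constant offset.
* **Median edge fill.** Shifted frames are resampled bilinearly and
  exposed edges are filled with the frame median, not zeros — zero fill
  would bias the frames 1–5 baseline and hence every downstream fold
  change.

`flag_motion_artifact()` flags a trial when any frame-to-frame jump of
the plane-averaged shift strictly exceeds `threshold_px` (default 5 px).
The criterion is artifact-defined — the workflow it automates excluded
such trials by eye — so the threshold and the flag are recorded with
every run.

## 2. Alarm-behavior curve comparison

`nest_from_tracks()` takes the coordinate-wise median of all ant
positions in the first 5 min as the nest center, radius 0.25 cm.
`proportion_outside()` counts, every 10 s from −60 s to +60 s around
stimulus placement (t = 0), the ants whose centroid distance from the
center strictly exceeds `radius + body_radius`. The 0.15 cm body margin
approximates the stricter requirement that no part of the ant's body
touch the nest circle, which centroid tracks cannot express exactly; it
is an explicit, configurable approximation. Ants lacking a sample within ±5 s of a
gridpoint are dropped from that gridpoint's denominator (and reported).

The fitted model over the −10…+60 s analysis window is the logistic
growth curve

\[ Y(t) = \frac{Y_0 Y_M}{(Y_M - Y_0) e^{-kt} + Y_0}, \]

with `Y0` the proportion outside at t = 0, `YM` the plateau, `k` (1/s)
the rate. The curve-fitting tool originally used for this analysis does
not print its equation; this parameterization is its documented
"logistic growth" family, pinned here so fits are reproducible. Fitting
is bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`,
`Y0, YM ∈ [0, 1]`, `k ≥ 0`), equal weights. Initialization is
deterministic: `Y0` from the earliest observation (floored at 0.01),
`YM` from the maximum, `k = ln(81)/(t₉₀ − t₁₀)` from the 10→90% rise
time, fanned into five fixed starts over the rate; the converged fit
with the lowest residual sum of squares wins, so there is no hidden RNG
in the fitter. Constant data short-circuit to the degenerate constant
curve (`Y0 = YM`, `k = 0`, SS = 0). Observed proportions may stray
slightly outside `[0, 1]` under measurement noise; only parameters are
bounded. The quadratic family (`fit_quadratic()`, ordinary least
squares) serves non-sigmoidal vehicle responses.

`extra_ss_f_test()` — the analysis core, implemented by hand — fits one
pooled curve (null) and per-group curves (alternative) and computes

\[ F = \frac{(SS_{null} - SS_{alt})/(df_{null} - df_{alt})}{SS_{alt}/df_{alt}},
\qquad df_{null} = N - p,\; df_{alt} = N - Gp,\; p = 3, \]

with the p-value from `F(df_num, df_den)` and "separate" preferred at
p < 0.05. Nesting guarantees `SS_alt ≤ SS_null` at the optimum; if an
optimizer leaves a group fit above the pooled one, the group is refit
from the pooled estimates and the SS difference floored at zero. The
grouping variable is generic: age cohorts and stimulus identities go
through the same interface.

**Known property: finite-sample conservativeness.** The F test is exact
for linear models only; for this bounded nonlinear family at 8
timepoints per group the acceptance script measures a null rejection
rate of about 0.03–0.05 at α = 0.05 (seed-dependent at 1000
replicates), i.e. the test errs slightly on the conservative side while
retaining essentially full power against a 3-fold rate difference at
realistic noise. An independent reimplementation reproduces the same
size, so this is a property of the procedure, not of this
implementation.

## 3. The synthetic-data generator

The generator exists to make every stage falsifiable against known
ground truth; its defaults mirror the acquisition and assay designs.

**Imaging scenes.** Glomeruli are constant-intensity spheroids
(in-plane radius 6 px, ±2 planes) at `baseline_intensity` 1000 over a
background of 100 carrying a static blocky texture (relative amplitude
0.2) — without the texture, planes containing no glomerulus would be
featureless and unregisterable, which real tissue never is. During a
response the blob is multiplied by `1 + a·g(t)` where `a` is the
programmed peak fold change and

\[ g(s) = (1 - e^{-s/\tau_r})\, e^{-s/\tau_d} \]

(renormalized to peak 1; `s` = time since odor arrival) is the simplest
two-constant GCaMP-like kinetic shape. The defaults τ_r = 1 s,
τ_d = 5 s are placeholders — the source recordings report no kinetic
constants — and `decay_tau_s = Inf` gives a sustained plateau, the
configuration used by the recovery tests so that the mean over the peak
window equals `a` exactly. Motion is an integer 2D random walk applied
rigidly to all planes of a frame (what rigid translation registration
can invert; the background texture rolls with it); noise is additive
Gaussian (floored at 0), with Poisson shot noise available; intensities
are quantized to integer counts by default, like a detector, which also
makes 16-bit TIFF round-trips exact. The default desk-scale scene is
45 frames × 8 planes × 64 × 64 px with 4 glomeruli — small enough for
seconds-level tests while preserving every frame-window convention
(45 ≥ 40 frames for the AUC window). The study-design manifest is 7
odorants × 3 repeats = 21 trials, order randomized within repeat blocks.

**Colony tracks.** Each ant is a point centroid; at every sample it is
outside the nest with probability `Y0` before the stimulus and
`Y(t − t_stim)` after, drawn independently per sample. Outside ants are
placed uniformly beyond `nest_radius + body_radius` (so centroid
counting recovers the generated labels exactly), inside ants uniformly
within the nest circle. Defaults: 12 young + 12 old ants, 570 s
recordings with the stimulus at 270 s, 1 s tracking cadence. The leave
parameters (young: Y0 0.05, YM 0.8, k 0.08; old: Y0 0.05, YM 0.5,
k 0.04) are plausible inventions — no fitted constants are reported for
the real assay — chosen once to give distinguishable cohorts.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: neuropil background and bleaching, axial
(z) motion, non-rigid deformation, olfactometer airflow dynamics,
occlusion or identity switches in tracking, and any within-ant
behavioral persistence (outside/inside draws are independent across
samples, so the tracks have no dwell-time structure). Results on real
recordings depend on ROI curation and glomerulus matching, which remain
manual.

**Determinism.** Every stochastic function takes an explicit seed
(mandatory in `run_pipeline()` configs), uses it in a local RNG scope,
and restores the caller's RNG state; identical seeds and configs give
byte-identical movies, tracks and pipeline outputs.

## 4. File formats

Movies travel as multi-page 16-bit TIFF (acquisition page order: z
fastest) with a YAML sidecar for period, stimulus timing and trial
metadata; integer-valued movies round-trip bit-identically. Response
maps are stored as 32-bit TIFF affinely scaled into `[0, 1]` with
offset/scale in the sidecar (round-trip precision ~10⁻⁹ of the value
range). ROI sets are JSON (0-based pixels or half-open rectangles).
Tracking tables are plain CSV (`time_s, ant_id, age_class, x_cm, y_cm`).
NWB ingestion (`load_nwb_series()`) is an optional extra behind the
`hdf5r` package with a user-supplied dataset mapping, because archive
layouts vary; nothing else depends on it.

## 5. Verification problem sizes

The test suite and `scripts/acceptance.R` use: 20 random 16×16 movies
(3 planes, 20 frames) for pipeline-versus-oracle equality; noiseless
plateau-kinetics trials with amplitudes {0, 0.1, 0.5, 1, 6} for
amplitude recovery, clipping and classification; 50 simulated movies
(45 frames, 4 planes, 64×64, integer walk of step SD 1 px) for
registration recovery at a 0.25 px residual criterion; 1000 null and
200 alternative replicates (8 timepoints per group) for F-test size and
power; and 200 replicates at noise SD 0.02 for logistic
parameter-recovery bias. These sizes keep the full verification run in
the low minutes on one CPU while leaving Monte Carlo error well inside
the asserted tolerances (the binomial SE of a rate at n = 1000 is
~0.007).
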