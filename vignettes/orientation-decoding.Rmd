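---
title: "Simulating and decoding orientation representations in V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding orientation representations in V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1decode)
```

## The scientific question

Multivoxel pattern analysis can decode the orientation of a visual grating
from V1 fMRI patterns even though orientation columns are an order of
magnitude finer than the voxels.  Two mechanisms could carry that
information: *columnar sampling* — each voxel's idiosyncratic, biased sample
of the fine-scale orientation-preference map — and *global preference maps* —
smooth, cortex-wide overrepresentation of radial (pointing at fixation) or
cardinal (vertical/horizontal) orientations.  A further possibility is that
apparent global maps are not purely feed-forward but depend on the stimulus
having a coherent global form, through attention spreading or feedback from
higher areas.

`v1decode` implements an analysis chain designed to separate those
mechanisms, together with a synthetic V1 cohort generator in which each
mechanism is an explicit, independently switchable model component.  Because
the generator's ground truth is known, every analysis in the chain can be
validated as a *method*: does it detect a mechanism when it is present, and
stay silent when it is absent?

## Stimuli

Four stimulus families live on a common annulus (inner radius 1.5°, outer
7.04°, diameter 14.08°) divided into 36 log-polar tiles: 3 exponentially
spaced rings (boundaries 1.50°, 2.51°, 4.20°, 7.04°) crossed by 12 wedges of
30°, with wedge boundaries on the cardinal meridians.  Thin mid-gray "grout"
lines mark the tile boundaries in *all* stimuli, so the tiling itself never
distinguishes conditions.

* **Gratings**: square-wave gratings at 1.25 cycles/degree, oriented ±45°
  from vertical.  The pair is *cardinally balanced*: a vertical- or
  horizontal-preference map responds identically to both.
* **Spirals**: logarithmic spirals with 22 contrast cycles around the
  perimeter whose edges keep a constant ±45° angle to the local radius.  The
  pair is *radially balanced*: a radial-preference map cannot tell them
  apart.
* **Patch-swapped gratings / spirals**: half the tiles (one parity class of
  the log-polar checkerboard) are exchanged between the two parent
  exemplars.  Local orientation disparity remains exactly 90° everywhere,
  but the two exemplars have nearly identical global form.

Orientations are measured anticlockwise from the rightward horizontal in
`[0, 180)`, so "45° clockwise from vertical" is 45 and the radial direction
at a point equals its polar angle.  All four families satisfy the same
invariant, enforced by tests: the two exemplars differ by 90° at every
in-annulus, non-grout point.

```{r stimuli}
spec <- stim_spec("spiral", "A")
orientation_at(spec, 3, 1)
ras <- render_stimulus(spec, pixels_per_degree = 12, seed = 1)
dim(ras$image)
```

Two choices here were genuinely open.  The grout-line width is not a
published quantity; we use 0.06°, thin enough that the smallest tile retains
more than one contrast cycle.  Phase randomization is applied per
presentation with a *single* phase shared by all tiles of a render, which
preserves the exact tile-wise correspondence between patch-swapped stimuli
and their parents; per-tile independent phases would break that
correspondence without changing any analysis downstream.

## The synthetic V1 cohort

The simulator is a hypothesis machine, not a biophysical model.  A subject's
V1 is a complex-log conformal map of the annulus (`w = k log z`, `k` ≈ 21.5
mm per log-degree when solved for an ~1126-voxel ROI), with voxels on a 2-mm
grid on the cortical sheet.  For spatial-filtering analyses the sheet is
embedded on a cylinder of radius `k`, giving a folded-cortex-like ~45-mm
maximal extent rather than an implausible 135-mm flat strip.

Each voxel `v` carries a tuning vector in double-angle space,
`t_v = t_col,v + g · t_glob,v`, with:

* `t_col,v`: the average of a unit-RMS smoothed complex Gaussian random
  field (correlation length 0.8 mm — the columnar scale) over the voxel's
  2×2-mm footprint, rescaled so the voxel-level RMS modulus is 0.45;
* `t_glob,v = w_r e^{2iθ_v} + w_vert e^{2i·90°}`: radial plus vertical
  preference maps (`θ_v` the voxel's receptive-field polar angle);
* `g`: 1 for globally coherent stimuli, `coherence_gain` (default 0.1) for
  patch-swapped ones.  This single switch encodes the hypothesis that global
  preference maps depend on coherent global form; setting it to 1 simulates
  the purely feed-forward alternative, and 0 the fully form-dependent one.

The response of a voxel to a stimulus is
`r_v = B_v m_v + A · Re( conj(t_v) s_v )` (% signal change), where `m_v` and
`s_v` are receptive-field-weighted averages of the stimulus contrast energy
and of `e^{2i·orientation}`.  Receptive fields are Gaussians of width
`0.2° + 0.1·eccentricity`, integrated by a fixed 48-point equal-weight
quadrature.  Defaults: baseline `B = 2.5` (mean overall responses just above
2% signal change), tuned amplitude `A = 0.3`, `w_r = 1/12` and
`w_vert = 0.07` — so the global patch-level modulations are ±0.025 and
±0.021 % signal change, an order of magnitude smaller than the overall
response, on top of voxel-level columnar modulations of a few hundredths of
a percent.

Time series follow the block design: 8-min runs of 4 subruns, each with six
14-s blocks (three per exemplar, alternating, with the leading exemplar
alternating across subruns), 2-s inter-block and 24-s inter-subrun fixation,
TR 2 s, 252 volumes, 28 phase-randomized 250-ms presentations per block at
2 Hz.  Noise is i.i.d. Gaussian per volume (default SD 1.1% signal change,
i.e. a temporal SNR near 90 — the upper range of 3T protocols; temporal
autocorrelation is deliberately out of scope).  Head motion is a seeded
random walk of 3 translations and 3 rotations whose volume-to-volume
magnitude multiplies a spatially white artifact field (gain 60 % signal
change per unit motion step).  A spatially *smooth* artifact variant is
available, because whether motion artifacts are band-selective is exactly
the kind of question the band-resolved motion analysis asks.  Cohorts
default to 18 subjects with log-normal subject-level spreads of noise
(×e^0.2) and motion (×e^0.5); those spreads were chosen once so that motion,
not thermal noise, dominates the between-subject accuracy range, the regime
the head-motion analysis addresses.

The noise and amplitude defaults were calibrated once, jointly, so that the
simulated full-scale cohort reproduces the qualitative operating point the
analyses assume: coherent stimuli decode well above chance, patch-swapped
stimuli decode above chance but distinctly worse, and both effects survive
fine-scale-only analysis.  They were not tuned to reproduce any particular
published accuracy value, and the package's checks deliberately assert only
the qualitative pattern.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: physiological (cardiac/respiratory) noise and its
temporal autocorrelation, eye movements, susceptibility distortion, the
irregular folded geometry of real cortex, retinotopic-mapping error in patch
definitions, and any V2/V3 structure.  The pipeline runs unchanged on any
ROI with voxel coordinates and patterns, but its validation here is entirely
within-model.

## Estimation and decoding

Subrun-wise t-patterns come from an ordinary-least-squares GLM per run: one
regressor per exemplar and subrun (block boxcars convolved with a gamma HRF,
`n = 3`, `τ = 1.25` s, `δ = 2.5` s, peak-normalized), six motion confounds
and an intercept; the first two volumes are discarded, mirroring the usual
handling of T1 saturation so volume bookkeeping stays conventional.  The
simulator injects no slow drift, so no drift regressors are included by
default; `hrf_args` and the design builder accept additions.  Betas over the
intercept give % signal change; the 2×4 subruns of the two runs per family
yield 8 t-patterns per exemplar.

Decoding is a linear SVM (cost 1, no feature scaling — t-values as-is) under
leave-one-subrun-out cross-validation: 8 folds, train on 14 patterns, test
on 2.  A decision value of exactly 0 goes deterministically to exemplar A.
Group inference subtracts chance (50%) and applies the Wilcoxon signed-rank
test; the exact null distribution of the rank sum is computed by dynamic
programming for n ≤ 25 (correct under ties, zeros dropped), with a
tie-corrected normal approximation above.  Decoding-versus-chance is tested
one-sided; paired comparisons and all preference-map tests are two-sided,
since tangential or horizontal preferences are meaningful negatives.

A methodological caveat inherited from the filtering literature and
reproduced in code: Gaussian smoothing is invertible, so a Fisher linear
discriminant with sample covariance is *provably unaffected* by it
(`fisher_loso_accuracy()` asserts this to 1e-6 in tests), whereas the SVM is
not.  Filter-resolved SVM accuracies therefore measure the amplitude of
pattern components per band, not information in the Shannon sense.

## Spatial scale analyses

`masked_smooth()` implements ROI-masked Gaussian smoothing: each voxel
becomes a Gaussian-weighted average (σ = FWHM/√(8 ln 2)) of in-ROI voxels
only, with weights renormalized — out-of-ROI voxels are missing values, not
zeros.  Distances are Euclidean over voxel-center mm coordinates.  High-pass
maps are original minus smoothed; band-pass maps are differences of
smoothings 1 mm apart, a band being named by its larger FWHM (the 5-mm band
is 4-mm smoothed minus 5-mm smoothed; FWHM 0 is the identity, so the 1-mm
band is original minus 1-mm smoothed).  With 2-mm voxels the 1-mm kernel is
nearly an identity; the grid is implemented literally anyway and the
near-identity is simply visible in the curves.  `sweep_decode()` filters
train and test patterns identically and re-decodes per FWHM.

Patch-level analyses use the ground-truth receptive-field tile assignment as
the parcellation (the simulator's analogue of "equally sized patches", which
are approximately equal in cortical area under log-polar magnification):
36 patches, merged to 12 wedges, 4 meridian-bounded quadrants, 2 hemifields,
or 1 region.  `remove_patch_means()` isolates the fine scale,
`patch_means()` the coarse scale.

## Preference-map inference

`build_patch_table()` tabulates each patch's mean % signal change per
exemplar.  The cosine tuning model
`response = β0 + β1 cos(2(θ_stim − θ_opt))` is fit per subject, with
`θ_opt` the patch's polar angle (radial hypothesis, grating families) or 90°
(vertical hypothesis, spiral families).  The complementary pairings are
structurally unidentifiable — the spirals' ±45° radial offset makes the
radial predictor constant — and the fit refuses them rather than returning a
spurious zero.

The rank-order test correlates (Spearman) measured patch responses with the
predicted scores `cos(2Δ)` over all 72 (patch, exemplar) observations and
tests per-subject correlations against zero by the two-sided signed-rank
test.  One design choice deserves note: raw patch responses mix
between-patch baseline differences (e.g. the eccentricity gradient) with the
preference modulation of interest.  By default each patch's two responses
are therefore centered before ranking, which makes the test sensitive to the
exemplar *contrast* only — the same quantity the low-contrast-patch
exclusion control (`contrast_exclusion()`) operates on.  `center = FALSE`
reproduces the literal ranking of raw responses.

## Head-motion analysis

`motion_index()` averages absolute volume-to-volume translation changes (mm)
and rotation changes (deg) and then averages the two — intentionally
unit-inconsistent, frame-difference-based, and offset-invariant.  Subjects
more than 3 SD above the group mean (one pass, one-sided) are excluded;
Pearson correlation with per-subject accuracy uses the t-transform for its
p-value, and `band_resolved_corr()` repeats the correlation per spatial
band.

## Numerical choices and degenerate inputs

* Tile intervals are half-open with the outer ring closed; eccentricities
  and angles within 1e-9 of a boundary are snapped onto it, so conformal
  round trips cannot leak voxels out of the annulus.
* The cosine predictor is rounded at 1e-12 so observations at
  mathematically equal angles are exact ties under ranking.
* FFT convolution ringing in regressors is clipped at zero (the true
  convolution is nonnegative); task regressors are peak-normalized, which
  affects β scale only, never t.
* All-zero signed-rank differences give p = 1 with a degenerate flag;
  constant measured vectors make Spearman r undefined and the subject is
  flagged missing rather than imputed.
* Exclusion sweeps retaining fewer than 3 patches are reported as undefined.
* Every stochastic component (stimulus phases, columnar fields, noise,
  motion) is seeded; models, schedules and event tables are bit-reproducible
  given the seed.

## Problem sizes used in the checks

The package's own test-suite cohorts are deliberately smaller than the
default 18-subject, ~1126-voxel conditions: property checks use 60–400-voxel
models and 5–8 subjects, sizes at which every qualitative contrast the
analyses are built to detect (fine-scale decodability at all patch-removal
scales, coherent-versus-patch-swapped coarse-scale differences, the
coherence dependence of preference maps, the low-pass accuracy decline, the
amplitude recovery of the cosine fit) is already stable across seeds.  The
full-scale defaults remain the package's description of the study
conditions and are exercised directly by the model-construction tests.

## Known limitations

The simulator's two decodability mechanisms are additive and stationary;
real V1 likely mixes scales continuously.  The cylinder embedding gives
realistic distances but not realistic *curvature* of distances, so absolute
FWHM values should be compared within the model, not to published cortical
scales.  The exact signed-rank DP is quadratic in n and switches to a
normal approximation beyond n = 25.  And the SVM's filter-resolved curves
inherit the interpretational caveat above: they quantify band amplitude,
not recoverable information.
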