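# v1decode

Simulation and multivoxel decoding of orientation representations in human
primary visual cortex (V1).

## The problem

fMRI can decode which of two orthogonal orientations a subject is viewing
from V1 voxel patterns, even though orientation columns are far finer than
the voxels.  Whether that decodability reflects **columnar sampling** (each
voxel's biased sample of the fine-scale orientation-preference map),
**global preference maps** (smooth cortex-wide biases toward radial or
cardinal orientations), or top-down effects tied to the stimulus's
**coherent global form**, is a long-running methodological debate.
`v1decode` is for researchers who want to prototype, validate or teach the
analysis chain used in that debate, on synthetic cohorts whose ground truth
is known and whose mechanisms can be switched on and off independently.

The package provides, end to end:

* **Log-polar stimuli** — uniform gratings (orientations 45°/135°,
  1.25 cycles/deg), logarithmic spirals (edges at a constant ±45° to the
  radius, 22 cycles around the perimeter), and patch-swapped variants that
  exchange half the tiles of a 36-tile log-polar checkerboard between the
  two parents, destroying global form while preserving the exact 90° local
  orientation disparity.
* **A synthetic V1 cohort generator** — complex-log retinotopy with ~1126
  voxels on a 2-mm grid, a smoothed-random columnar preference field
  sampled into per-voxel tuning vectors (double-angle space), additive
  radial/vertical global maps with a coherence-dependent gain, a Boynton
  HRF block design (8-min runs, 4 subruns, 14-s blocks at 2 Hz), white
  temporal noise and motion-locked spatially white artifacts.
* **The analysis chain** — subrun-wise GLM t-patterns with motion
  confounds; leave-one-subrun-out linear-SVM decoding with exact
  signed-rank group inference; ROI-masked Gaussian low/high/band-pass
  filtering (`band n = (n−1)-mm smoothed − n-mm smoothed`); patch-mean
  removal and patch-mean-only decoding at 36/12/4/2/1 scales; cosine
  tuning-model fits of radial and vertical preference (`response =
  β0 + β1 cos 2(θ_stim − θ_opt)`); rank-order preference tests with a
  low-contrast-patch exclusion control; univariate and
  eccentricity-resolved summaries; and head-motion indices, outlier
  exclusion and (band-resolved) motion–accuracy correlations.

## Worked example

```r
library(v1decode)

# annulus geometry: exponentially spaced rings
ring_radii(1.5, 7.04, 3)
#> [1] 1.500000 2.511414 4.204802 7.040000

# a small cohort: 6 subjects, gratings and their patch-swapped variants
co <- simulate_cohort(n_subjects = 6,
                      families = c("grating", "patchswap_grating"),
                      seed = 42, motion_scale = 0,
                      model_args = list(target_voxels = 400))

acc <- decode_cohort(co, "grating")
round(mean(acc), 3)
#> [1] 1
group_signedrank(acc)$p.value
#> [1] 0.015625

round(mean(decode_cohort(co, "patchswap_grating")), 3)
#> [1] 0.854

# global radial preference: cosine tuning model on the 36 patch responses
tab <- build_patch_table(co)
fit <- cosine_fit(tab[tab$family == "grating", ])
round(c(beta0 = mean(fit$beta0), beta1 = mean(fit$beta1)), 4)
#>  beta0  beta1
#> 2.1421 0.0267

rank_preference_test(tab[tab$family == "grating", ])
#> radial preference (grating): median r = 0.430, n = 6, p = 0.03125
rank_preference_test(tab[tab$family == "patchswap_grating", ])
#> radial preference (patchswap_grating): median r = 0.069, n = 6, p = 0.5625
```

Reading the output: both families decode above chance (grating at 100%,
patch-swapped at 85% here), so local orientation information survives the
loss of global form.  Patch responses sit just above 2% signal change
(`beta0`) with a subtle ±0.027%-amplitude radial modulation (`beta1`) —
and the rank-order test finds that radial preference map for the coherent
gratings (p = 0.03) but not for the patch-swapped ones, whose global-map
gain is an order of magnitude lower in the default generator.

Spatial-scale analyses follow the same pattern:

```r
parc <- parcellate(co[[1]]$model$rf, co[[1]]$model$tiling, scale = 36)
fine <- remove_patch_means(co[[1]]$patterns$grating$t, parc)   # fine scale only
sw <- sweep_decode(co, "grating", kind = "low", grid = c(2, 6, 12, 20, 30))
sw$group      # accuracy declines as low-pass FWHM grows
```

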