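# tpmtorsion

Quantification of left-ventricular (LV) torsion from **tissue phase mapping
(TPM)** cardiovascular magnetic resonance.

TPM is a phase-contrast cine technique that measures the velocity of the
myocardium itself — three directions per pixel per frame — on short-axis
slices. During systole the LV base and apex rotate in opposite directions;
the normalized angle difference between two slices,

```
T(t) = (theta_upper(t) - theta_lower(t)) / h        [deg/mm]
```

with `h` the inter-slice distance, is the torsion curve, and its signed peak
`T_max` is a compact biomarker of systolic function. Because the endocardium
rotates further than the epicardium, the transmural peak difference

```
dT_max = T_max(endo) - T_max(epi)                   [deg/mm]
```

(and its relative form `dT_max / T_max(endo) * 100`) probes the transmural
contraction gradient, which degrades early in ischemic disease.

The package implements the full measurement chain:

| Step | Functions |
|---|---|
| velocity I/O (NIfTI/container, phase→velocity, venc checks) | `read_tpm()`, `write_tpm()`, `phase_to_velocity()` |
| eddy-current baseline correction from stationary soft tissue | `classify_soft_tissue()`, `detect_stationary()`, `fit_eddy_plane()`, `correct_eddy()` |
| velocity noise filtering (3×3 mean/median) | `smooth_velocity()` |
| contour refinement, velocity-field propagation (RK4), layer split by topology-preserving thinning | `refine_contours()`, `propagate_contours()`, `segment_series()`, `extract_centerline()`, `label_layers()` |
| rotation, torsion and transmural summaries | `slice_rotation()`, `torsion_curve()`, `transmural_summary()`, `resample_and_average()` |
| cohort statistics | `assign_subgroups()`, `compare_groups()`, `pearson_corr()`, `bland_altman()` |
| analytic ground-truth phantom | `phantom_spec()`, `generate_phantom()`, `analytic_torsion()`, `measure_phantom_torsion()` |
| orchestration | `run_pipeline()`, `inst/cli/tpm.R` |

See the methods vignette (`vignettes/tpm-torsion-methods.Rmd`) for the model,
conventions, parameter rationale and limitations.

## Worked example

The package ships a synthetic rotating-annulus phantom with closed-form
ground truth, so the whole pipeline can be exercised without patient data:

```r
library(tpmtorsion)

spec <- phantom_spec(noise_sd_mm_s = 2, seed = 7)
phantom <- generate_phantom(spec)
phantom
#> <tpm_phantom> base/mid/apex; 64 x 64 px @ 2.20 mm, 40 frames @ 20.8 ms, noise SD 2.0 mm/s, seed 7

series <- phantom$slices$series$base
series
#> <tpm_series> base slice: 64 x 64 px, 40 frames
#>   pixel 2.20 x 2.20 mm, dt 20.8 ms, venc 250 mm/s, position 0.0 mm

# eddy-current plane fit from stationary soft tissue (phantom is clean, so
# the fitted coefficients are ~0) + 3x3 low-pass filtering
pp <- preprocess_series(series, phantom$roi)
round(unclass(pp$plane), 4)
#>         a      b      c
#> x -0.0075 -1e-04  1e-04
#> y  0.0167  0e+00 -9e-04
#> z -0.0224  2e-04  7e-04

# segmentation: one contour pair propagated through the velocity field
seg <- segment_series(pp$series, analytic_contours(spec, "base", 8))
seg
#> <myo_segmentation> 40 frames, mask 64 x 64, mean area 338 px

# full chain on the base-apex pair, per layer
curves <- measure_phantom_torsion(phantom, pair = c("base", "apex"),
                                  layers = c("full", "endo", "epi"))
glance(curves$full)
#> # A tibble: 1 × 5
#>   slice_pair layer  h_mm T_max t_peak_ms
#>   <chr>      <chr> <dbl> <dbl>     <dbl>
#> 1 base-apex  full     50 0.402       312

transmural_summary(curves$endo, curves$epi)
#> # A tibble: 1 × 5
#>   slice_pair T_max_endo T_max_epi dT_max dPctT_max
#>   <chr>           <dbl>     <dbl>  <dbl>     <dbl>
#> 1 base-apex       0.490     0.371  0.119      24.4

# analytic (ground-truth) peak torsion of the same phantom
analytic_torsion(spec, c("base", "apex"), "full", spec$t_sys_ms)
#> [1] 0.4063231
```

The measured full-wall peak (0.402 deg/mm) recovers the analytic truth
(0.406 deg/mm) to about 1%. `autoplot(curves$full)` plots the torsion curve
with the peak marked; `autoplot(bland_altman(x, y))` draws agreement plots.

## Command line

A thin CLI wraps the package:

```sh
Rscript inst/cli/tpm.R simulate --out /tmp/phantom --seed 1
Rscript inst/cli/tpm.R preprocess --in /tmp/phantom/base --out /tmp/base-pp --roi 16,16,47,47
Rscript inst/cli/tpm.R run-all --config config.yaml
```

Exit codes: `0` success, `2` input error, `3` numerical failure.

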