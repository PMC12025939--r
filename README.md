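# tendonT2

Quantitative T2 mapping and length-normalized T2 profiling of the
supraspinatus tendon, in R.

## What it is for

T2 relaxation time rises where tendon tissue holds more free water —
degeneration, matrix disorganization, inflammation — so voxelwise T2 maps
computed from multi-echo spin-echo MRI can track tendon state
quantitatively. A single whole-tendon mean hides *where* change happens.
This package analyzes the tendon as a one-dimensional structure: every
masked voxel gets a normalized position `x` along the tendon (0 % at the
lateral footprint, 100 % at the musculotendinous junction), T2 is
summarized as a **distribution profile** (mean T2 per 1 % of length), the
profile is split into three equal segments (lateral, middle, medial), and
paired visits are compared statistically.

The pipeline, intended for researchers analyzing multi-echo shoulder MRI
or validating T2-profiling methodology:

1. **Relaxometry** — per-voxel mono-exponential fit
   `S(TE) = S0 · exp(−TE/T2)` by log-linear least squares (signal-domain
   NLS available), over an echo train of 8 TEs from 11.4 to 91.2 ms.
2. **Filtering** — removes partial-volume voxels: keep valid fits with
   `T2 ∈ [5, 120]` ms and `r² ≥ 0.7`, rejecting bone (short T2) and
   bursal fluid (long T2).
3. **Length parameterization** — within-mask geodesic coordinate
   `x = 100·(d_lat − d_med + L)/(2L)` from the two end seeds; reduces to
   the axis coordinate on straight bands and needs no inter-visit image
   registration.
4. **Profiling** — mean T2 per length bin; per-segment means ± SD.
5. **Statistics** — per-segment OLS lines on the profile (global-x
   intercepts), the **Chow test**
   `F = [(RSS_p − RSS_a − RSS_b)/2] / [(RSS_a + RSS_b)/(n_a+n_b−4)]`
   for pre/post structural change, an exact Wilcoxon signed-rank test on
   paired segment means, paired t-tests for clinical scores.
6. **Digital phantom** — curved tendon band with a known piecewise-linear
   `T2(x)`, fluid/bone rims, Rician noise; every stage is testable against
   exact ground truth.

## Worked example

```r
library(tendonT2)

# a noisy phantom of a degenerated (tendinosis-like) tendon
ph  <- generate_phantom(phantom_config(noise_sigma = 20, seed = 8L))
rep <- run_subject(ph$image, ph$truth$mask)
rep
#> <subject_report> subject: 524/524 voxels kept, tendon length 46.5 mm
#>   segment  mean_t2    sd_t2 n_voxels
#> 1 lateral 35.84696 3.794136      176
#> 2  middle 36.44167 3.749946      171
#> 3  medial 40.66186 4.621262      177

rep$regressions$lateral
#> <regression_fit> slope -0.23 ms/%, intercept 39.29 ms, n = 33, RSS = 47.61
```

The lateral segment mean (≈ 35.8 ms) and its descending profile slope
(≈ −0.23 ms per % length) recover the generating preset (−0.268, 39.5)
up to noise and voxel discretization. A paired synthetic cohort:

```r
co   <- simulate_cohort(9, pre_preset = "tendinosis_before",
                        post_preset = "tendinosis_after",
                        seed = 99L, grid_shape = c(64L, 64L))
crep <- run_cohort(co)
crep
#> <cohort_report> 9 paired subjects
#>
#> Per-segment regression (group profiles):
#>  segment slope_before intercept_before slope_after intercept_after chow_f    chow_p
#>  lateral      -0.2473            39.70     -0.1900          35.027 369.96 1.791e-34
#>   middle       0.2201            25.50      0.5859           6.178  50.36 6.985e-12
#>   medial      -0.3335            68.82     -0.3653          72.904  40.13 6.573e-12
#>
#> Wilcoxon signed-rank on paired segment means:
#>  segment statistic  p_value n
#>  lateral         0 0.003906 9
#>   middle         0 0.003906 9
#>   medial         0 0.003906 9
```

The group profiles show the biphasic pattern (descending lateral,
ascending middle, descending medial segment); the Chow test flags the
slope/intercept changes between visits per segment, and the exact
Wilcoxon p-values compare the 9 paired segment means.

A command-line wrapper ships in `inst/cli/tendont2.R` with subcommands
`simulate`, `fit`, `profile`, `compare` (NIfTI in, CSV/JSON out); see the
header of that file for usage.

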