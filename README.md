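# laa3d

Surface-based 3D assessment of the **left atrial appendage (LAA)** from
multi-phase cardiac CT: simultaneous measurement of the appendage's
morphology (ostium area, volume) and function (volume–time curve, ejection
fraction) from triangle surface models, together with the classical 2D
slice-stack (Simpson) reference and the agreement statistics used to
validate one method against the other.

## Who this is for

Cardiac imaging researchers and biomedical engineers who need reproducible
LAA measurements from gated CT (or any modality that yields a binary
blood-pool mask or an STL surface): thrombo-embolic risk studies, closure
device sizing, and method-comparison work.

## What it computes

For each cardiac phase the pipeline runs

> threshold segmentation → connected-component selection → watertight
> isosurface → plane crop of the appendage → ostium cutting plane from
> landmarks → mesh–plane intersection contour → surface capping →
> voxelization volumetry at the CT spacing

and aggregates the per-phase results into the ejection fraction

```
EF_LAA = (max V_LAA(t) − min V_LAA(t)) / max V_LAA(t)
```

with the diastolic/systolic phases detected as the curve's extremes. The
ostium area is the planar shoelace area of the intersection contour; the
volume is the count of voxel centres inside the capped model times the
voxel size, with the divergence-theorem mesh volume as a built-in
cross-check. Measurements can be normalized by body surface area
(Mosteller: `sqrt(height_cm · weight_kg / 3600)`).

For method comparison the package provides the within-subject two-rater
coefficient of variation `100 · sqrt(mean(d²/2)) / grand mean`, Bland–Altman
bias with 95% limits of agreement `bias ± 1.96·SD(d)`, and the paired
t-test.

Because clinical CT datasets of this kind are confidential, a dynamic
digital phantom (atrial sphere + neck + lobed ellipsoid appendage, scaled
per phase with analytic ground truth) makes every stage testable; see the
methods vignette `vignettes/laa-3d-morphometry.Rmd`.

## Worked example

```r
library(laa3d)

spec   <- phantom_spec(spacing = c(1, 1, 1.5), truth_oversample = 4)
ser    <- make_dynamic_series(spec)          # 10-phase CT-like series + truth
report <- run_case(case_config(ser$stack, ser$truth$landmarks))
report
#> <laa_case_report> 10 phase(s)
#> # A tibble: 10 × 5
#>    phase_percent ostium_area_cm2 volume_cm3 mesh_volume_cm3 threshold
#>            <dbl>           <dbl>      <dbl>           <dbl>     <dbl>
#>  1             0            3.84      12.1            12.1       68.3
#>  2            10            3.66      11.4            11.4       68.3
#>  3            20            3.21       9.75            9.73      68.3
#>  4            30            3.06       8.61            8.59      68.3
#>  5            40            2.88       8.00            7.98      68.3
#>  6            50            3.06       8.61            8.59      68.3
#>  7            60            3.21       9.75            9.73      68.3
#>  8            70            3.51      10.8            10.8       68.3
#>  9            80            3.78      11.8            11.8       68.3
#> 10            90            3.84      12.1            12.1       68.3
#> <laa_function> EF 34.1% (V 12.13 -> 7.998 cm^3; diastole at 0% RR, systole at 40% RR)
```

The appendage fills to 12.1 cm³ at 0% RR (diastole), empties to 8.0 cm³ at
40% RR (systole), and the measured ejection fraction of 34.1% recovers the
phantom's prescribed truth of `1 − 0.87³ = 34.15%`; the ostium area
breathes between 2.9 and 3.8 cm² in step with the contraction. `glance()`
and `tidy()` return these results as tibbles, and `autoplot()` draws the
volume–time curve with the detected phases marked.

Comparing two measurement series (here, diastolic/systolic areas and
volumes measured by two methods):

```r
tb <- agreement_table(m1 = c(4.54, 3.58, 10.26, 7.39),
                      m2 = c(4.77, 3.79, 10.55, 7.46))
coefficient_of_variation(tb)
#> # A tibble: 1 × 3
#>   cov_percent     n definition
#>         <dbl> <int> <chr>
#> 1        2.33     4 within-subject RMS, two raters
bland_altman(tb)$interval
#> [1] "]-0.38; -0.02["
paired_t_test(tb)$p_value
#> [1] 0.02318403
```

A thin command-line front end over the same functions ships at
`inst/cli/laa3d` (subcommands `phantom`, `segment`, `surface`, `crop`,
`ostium`, `simpson`, `function`, `agree`, `run`).

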