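# anklemorph

Simulation framework for quantifying how ankle positioning errors corrupt
morphometric measurements made on planar radiographs.

Pre-surgical planning for total ankle arthroplasty — implant sizing, bone
resection levels — relies on morphological parameters of the distal tibia,
fibula and talus that are usually read off plain lateral and frontal
radiographs. A radiograph is a perspective projection: a structure at depth
*d* from the detector, imaged at source-to-image distance SID, is magnified
by SID/(SID − d), and any rotation of the limb away from the standard
imaging pose changes projected distances and axis-referenced angles.
`anklemorph` reproduces this whole measurement chain in simulation so the
errors can be quantified and corrected:

1. **Synthetic specimens** (`generate_phantom()`, `generate_cohort()`):
   constructive-solid-geometry ankle bones whose fourteen morphological
   parameters (TiAL, TiSR, APG, APA, MTiTh, MDA, MDV, TiW, MalW, MLATi,
   TaAL, TaR, TaW, MLATa) are closed-form functions of the specification —
   exact ground truth, with cohort-level variation drawn from truncated
   normal distributions around study-population means.
2. **3D gold standard** (`measure_phantom_3d()`): automatic landmark
   extraction (trimmed circle fits for the articular arcs, deterministic
   extremal-point rules) and measurement in the anatomical frame.
3. **Virtual radiography** (`cast_drr()`, `make_standard_geometry()`):
   perspective digitally reconstructed radiographs (DRRs) by ray casting
   with trilinear interpolation (compiled integrator), standard M/L and
   A/P positioning with SID = 1 m.
4. **2D measurement** (`measure_2d()`, `measure_pose_2d()`): the same
   parameter definitions applied in image coordinates, in detector mm,
   magnification deliberately uncorrected — that bias is the object of
   study.
5. **Experiments** (`sensitivity_sweep()`, `repeatability_experiment()`,
   `residual_error_table()`, `run_study()`): ±6° systematic pose sweeps
   (37 poses per view), ICC(3,k) repeatability under random pose error,
   and linear-regression correction of perturbed 2D measurements
   (3D = a·2D + b, fitted in the standard pose).

Results flow as tibbles through dplyr verbs, with broom-style `tidy()` /
`glance()` methods for fitted objects and `autoplot()` methods for DRRs,
sensitivity tables and comparison tables.

## Worked example

Generate the reference specimen, image it laterally in the standard pose,
and compare 2D against 3D:

```r
library(anklemorph)
library(dplyr)

ph    <- generate_phantom(phantom_spec(voxel_spacing = 1.25))  # fast profile
prof3 <- measure_phantom_3d(ph)                  # 3D gold standard
lm3   <- attr(prof3, "landmarks")

geom  <- make_standard_geometry("ML", ph$meshes, ph$frame, lm3,
                                image_size = 192, pixel_spacing = 0.7)
prof2 <- measure_pose_2d(ph, rigid_pose(), geom, lm3)  # renders the DRR

inner_join(prof3 |> select(parameter, value3d = value),
           prof2 |> select(parameter, value2d = value),
           by = "parameter") |>
  mutate(pct_error = round(100 * (value2d - value3d) / value3d, 2))
#>   parameter value3d value2d pct_error
#> 1      TiAL  28.410  29.328      3.23
#> 2      TiSR  29.070  29.853      2.69
#> 3       APG   3.885   4.011      3.23
#> 4       APA   7.860   7.860      0.00
#> 5     MTiTh  42.440  43.081      1.51
#> 6       MDA  10.210  10.364      1.51
#> 7       MDV   3.150   3.299      4.73
#> 8      TaAL  33.550  34.634      3.23
#> 9       TaR  20.570  21.134      2.74
```

The numbers show the two systematic effects the package exists to study.
The tibial arc chord (TiAL) sits about 31 mm from the detector in the
lateral view, so it is magnified by 1000/969 ≈ 1.032 — a +3.2% error with
no mal-positioning at all. The inclination angle APA is error-free to
machine precision because its two defining landmarks share projection
depth, so the projection scales both image components equally. A
mal-positioned specimen breaks these patterns; for example, a 6° in-plane
rotation changes the vertical gap MDA from 10.36 to 11.03 mm (+6.4%):

```r
measure_pose_2d(ph, rigid_pose(theta_z = 6), geom, lm3)
```

The full study — cohort, comparison table with calibration regressions,
sensitivity sweep, ICC table, correction residuals — runs from one
configuration:

```r
res <- run_study(study_config(n = 6, seed = 1))   # fast profile, minutes
res$comparison      # per parameter: means, % error, paired t, R, a, b
res$icc             # ICC(3,k) per parameter per view, reliability bands
res$residuals       # % error before/after regression correction, 3 and 6 deg
autoplot(res$sensitivity)
```

or from the shell:
`Rscript inst/scripts/run_study.R --config inst/extdata/fast_study.yaml --out results/`.

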