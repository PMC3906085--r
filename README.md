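# vesselcsa

Coronary lumen reconstruction and shape-free cross-sectional-area (CSA)
measurement from contrast CT volumes, with the validation statistics used
to compare CT-derived profiles against intravascular ultrasound (IVUS)
pullbacks.

## The problem and who this is for

Patient-specific coronary models need the lumen area *A(s)* along the
vessel, measured without assuming a circular cross-section — diseased
lumens are elliptical or crescent-shaped, and it is exactly at a stenosis
that a diameter-based area goes wrong. This package is for image-analysis
and cardiovascular-modelling work that starts from CCTA volumes (DICOM
series or NIfTI, in Hounsfield Units) and needs reproducible lumen
morphometry: areas, inscribed-circle and equivalent diameters, and a
sub-voxel centerline.

The pipeline:

1. **Restoration** — Wiener deconvolution against a Gaussian PSF model
   (counters blooming/point-diffusion), then bilateral edge-preserving
   smoothing: `wiener_deconvolve()`, `selective_deblur()`,
   `bilateral_filter()`.
2. **Segmentation** — automatic seeds, local-spherical-histogram region
   growing, densitometric (partial-volume) threshold calibration, calcium
   classification above 700 HU with max-gradient boundary refinement:
   `detect_seeds()`, `region_grow()`, `calibrate_mask_pv()`,
   `classify_calcific()`, `apply_manual_edits()`.
3. **Surface** — watertight isosurface plus Taubin (non-shrinking)
   curvature smoothing: `marching_cubes()`, `curvature_smooth()`.
4. **Centerline** — topology-preserving 3D thinning, main-path pruning,
   moving-average smoothing and blended local cubic Bezier refinement to
   sub-voxel accuracy: `thin_skeleton()`, `extract_main_path()`,
   `smooth_points()`, `bezier_refine()`, `resample_centerline()`.
5. **Measurement** — cutting planes normal to the centerline tangent;
   plane–mesh intersection polygons; shoelace area (no shape assumption),
   maximal inscribed circle, equivalent diameter
   `2 sqrt(A / pi)`; deviated-plane detection and repair:
   `slice_mesh()`, `polygon_area()`, `inscribed_diameter()`,
   `build_profile()`.
6. **Validation** — signed percent error
   `(A_ref − A_CT) / A_ref × 100`, RMSE normalized to the reference mean,
   and ordinary least-squares identity fits (`y = a·x + b` against the
   `y = x` line): `read_pullback()`, `align_series()`, `percent_error()`,
   `rmse_normalized()`, `identity_fit()`.

A synthetic phantom generator (`phantom_spec()` / `generate_phantom()`)
renders CT-like vessels — line/arc/helix axes; circular, elliptical or
crescent lumens; Gaussian stenoses; calcific inserts; PSF blur and noise —
with analytic ground-truth centerline and CSA, so the whole chain is
testable without patient data.

## Worked example

A 30 mm straight vessel of radius 2 mm (nominal area 12.57 mm²) with a 50%
Gaussian area stenosis at mid-vessel, rendered at 0.4 mm voxels with
0.6 mm PSF blur and 20 HU noise, then reconstructed end to end:

```r
library(vesselcsa)

spec <- phantom_spec(stenosis = list(depth = 0.5, center_s = 15, width = 3))
res <- run_pipeline(pipeline_config(list(
  input = list(phantom = spec),
  csa   = list(step_mm = 0.5),
  seed  = 42
)))

res$profile
#> <csa_profile> 47 sections (47 ok), s in [0.00, 22.56] mm
#>   area 6.19-12.72 mm^2

sec <- subset(res$profile$sections, flag == "ok")
sprintf("minimum lumen area: %.2f mm^2 at s = %.1f mm",
        min(sec$area), sec$s[which.min(sec$area)])
#> "minimum lumen area: 6.19 mm^2 at s = 11.0 mm"

str(res$report$validation)   # profile vs analytic phantom truth
#> List of 6
#>  $ slope                : num 1.03
#>  $ intercept            : num -0.328
#>  $ rmse_pct             : num 1.06
#>  $ mean_abs_pct_error   : num 0.951
#>  $ mean_signed_pct_error: num 0.375
#>  $ n                    : int 47
```

The minimum area (6.19 mm²) recovers the programmed 50% stenosis of the
12.57 mm² nominal lumen; the identity fit of measured against true area has
slope 1.03 and normalized RMSE ≈ 1%, i.e. each cross-section is measured to
about one percent under these imaging conditions.

Real volumes enter the same way via
`pipeline_config(list(input = list(volume = "scan.nii.gz"), ...))`, and
IVUS pullback tables (CSV: `frame, position, max_d, min_d, avg_d, area`)
via the `validate` block or `compare_to_reference()`. A command-line front
end is installed at `exec/vessel-csa` with subcommands `phantom`,
`preprocess`, `segment`, `mesh`, `centerline`, `profile`, `validate`,
`run`.

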