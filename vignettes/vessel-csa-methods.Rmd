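---
title: "Measuring coronary lumen cross-sectional area from CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coronary lumen cross-sectional area from CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselcsa)
```

## The problem

Contrast-enhanced coronary CT angiography shows the arterial lumen as a
bright (roughly 400–500 HU) tube in a darker soft-tissue background
(about 50 HU), sampled on a voxel grid of roughly 0.3–0.5 mm and blurred
by the scanner point-spread function (PSF). Patient-specific hemodynamic
models need the lumen **cross-sectional area (CSA)** along the vessel, and
they need it without a circularity assumption: diseased lumens are
elliptical or crescent-shaped, and a diameter-based area can be badly wrong
exactly where it matters, at a stenosis.

`vesselcsa` reconstructs the lumen in five stages and then measures CSA as
the area of the **plane–mesh intersection polygon** at planes normal to a
sub-voxel centerline:

1. *restoration* — Wiener deconvolution against a Gaussian PSF model, then
   bilateral (edge-preserving) smoothing;
2. *segmentation* — seeded region growing driven by local spherical
   histograms, followed by a partial-volume (densitometric) threshold
   calibration, with optional calcium classification above 700 HU;
3. *surface* — a watertight isosurface of the mask with non-shrinking
   curvature smoothing;
4. *centerline* — topology-preserving 3D thinning, branch pruning to the
   main path, moving-average smoothing and blended local cubic Bezier
   interpolation, giving a curve accurate to a fraction of a voxel;
5. *measurement* — one cutting plane per arc-length step, oriented by the
   local tangent; polygon area, maximal-inscribed-circle diameter and
   equivalent (equal-area) diameter per station; deviated planes repaired by
   resampling between neighbours.

Validation statistics — signed per-point percent error
$(A_\mathrm{ref}-A_\mathrm{CT})/A_\mathrm{ref}\times 100$, RMSE normalized
to the reference mean, and an ordinary least-squares identity fit — compare
a profile against either an intravascular-ultrasound (IVUS) pullback table
or the analytic truth of a synthetic phantom.

## The phantom: what it emulates, and what it does not

Every stage is testable without patient data through `generate_phantom()`:
a tubular lumen swept along a parametric line, arc or helix, with circular,
elliptical or crescent cross-sections, an optional Gaussian-profile
stenosis (area scale $1-d\,e^{-(s-s_0)^2/2w^2}$), and an optional spherical
calcific insert. The indicator is rendered with $3\times3\times3$ sub-voxel
supersampling (realistic partial-volume edges), convolved with a Gaussian
PSF and corrupted with additive Gaussian noise under a fixed seed. The
ground truth — centerline, tangents, CSA and inscribed diameter as
functions of arc length — is analytic and noise-free.

Defaults are a typical CCTA regime: 0.4 mm isotropic voxels, 450 HU lumen,
50 HU background, 900 HU calcium, PSF sigma 0.6 mm, noise sigma 20 HU.
Two generator choices deserve comment:

* **Generic grid offset.** The grid origin is shifted by a fixed sub-voxel
  amount (0.37/0.21/0.44 voxels). An axis that passes exactly through voxel
  centres with a radius equal to an integer number of voxels is a
  measure-zero alignment that no scanner produces, and it biases every
  discrete boundary estimate coherently; the offset puts the phantom in the
  generic position that real data occupies.
* **What passing does not show.** The phantom has no beam hardening, no
  helical reconstruction artifacts, no motion, no neighbouring bright
  structures (veins, myocardium) and a single straight or smoothly curved
  vessel without bifurcations. Tests passing here demonstrate the geometry
  and measurement chain under ideal CT-like statistics; they do not certify
  performance on clinical images, where manual include/exclude edits
  (`apply_manual_edits()`) are expected to play the role they play in
  practice.

## Why restoration and calibration are load-bearing

Gaussian blur moves a convex boundary inward: the half-height level set of
a blurred disk of radius $R$ sits at roughly $R-\sigma^2/2R$. At
$R = 2$ mm and $\sigma = 0.6$ mm that is a 5% radius deficit — a 10% CSA
error — and it afflicts *any* level-set or maximum-gradient criterion, no
matter how the threshold is chosen. Two mechanisms fix it:

* **Wiener deconvolution** (`wiener_deconvolve()`, default noise-to-signal
  ratio 0.01) shrinks the effective blur; the restored volume is also kept
  aside as the *linear* reference for calibration, because linear filters
  conserve integrated intensity while the bilateral filter, which follows
  it for segmentation stability, does not (its range kernel strips mass
  from convex edges).
* **Partial-volume calibration** (`calibrate_mask_pv()`): blurring
  conserves mass, so the fraction field $(HU-c_{bg})/(c_{lum}-c_{bg})$
  integrates to the true lumen volume no matter the residual blur. After
  region growing, the threshold is re-picked on a lightly smoothed copy of
  the restored volume so that the thresholded voxel count inside an
  envelope of the mask equals that integral. Tissue levels are medians of
  the eroded interior and of a background ring beyond the blur tail; the
  envelope must cover the blur tail, which is why the threshold is taken on
  the restored volume, while the mass integral itself is evaluated on the
  raw acquisition (its noise is uncorrelated, so the integral is an order
  of magnitude tighter). This is the densitometric idea applied as a
  one-parameter correction to an otherwise geometric pipeline, and it is
  what brings per-section CSA errors from ~5% to under 3% on the default
  phantom.

Three refinements make the calibration robust at realistic noise:

* the lumen level is sampled in a thin tube around a provisional
  centerline, not at the deepest mask voxels (those sit preferentially
  where boundary noise bulges outward, biasing the level);
* even on the axis of a 2 mm vessel the blurred intensity never reaches the
  true plateau; the analytic near-axis deficit of a blurred disk
  (`blurred_disk_mean()`, a Rice-integral quadrature using the declared
  PSF) rescales the sampled contrast;
* the final surface is extracted from the smooth restored field — not from
  the re-binarized mask, whose staircase would have to be anti-aliased
  again — and its iso value is refined by a secant iteration until the
  smoothed mesh encloses exactly the mass-target volume
  (`mesh$volume_match`).

## Segmentation choices

Seeds are connected components of a high threshold (default 350 HU), one
seed per component at the interior maximum of the distance transform. The
local spherical histogram (radius 2 mm, 10 HU bins) is split by Otsu's
criterion into background and lumen feature-centers; a frontier voxel is
accepted when its HU is nearer the lumen center. Two practical guards:

* a split only counts as bimodal when the feature-centers are at least
  100 HU apart — Otsu happily "splits" pure noise around one tissue;
* the histogram sphere is centered on the initial seed (widening until
  bimodal), and is *not* refreshed at the frontier centroid by default
  (`refresh_every = Inf`): on a long vessel the frontier centroid drifts
  deep into the lumen where the sphere sees one tissue, and refreshed
  centers become erratic. The refresh machinery exists and is configurable
  for locally varying contrast.

Calcium is classified above 700 HU among voxels in or adjacent to the
lumen, then the boundary is refined to the surface of locally maximal
radial gradient — thresholding alone under-segments blurred calcium
(blooming pushes the 700 HU crossing inside the true edge). Calcific
voxels are excluded from the lumen surface and reported separately; whether
calcium should count as lumen is a modelling decision the caller can make
by relabelling.

## Surface and centerline numerics

The isosurface tessellates each cell into six tetrahedra around a fixed
diagonal. The decomposition is translation-invariant, so neighbouring cells
agree on shared faces and the mesh is watertight by construction — there
are no ambiguous configurations to resolve, which the plane-slicing stage
depends on (open intersection chains are hard errors). Binary masks are
anti-aliased with a 0.6-voxel Gaussian before extraction so edge vertices
interpolate partial-volume values rather than snapping to edge midpoints;
without it the staircase inflates surface area by ~25%. Smoothing is
Taubin's $\lambda/\mu$ scheme (0.5 / −0.53, 20 iterations): a low-pass
filter on geometry that removes jag without the systematic shrinkage of
plain Laplacian smoothing (volume change is well under 1%).

Thinning deletes simple points (removal preserves both foreground
26-topology and background 6-topology) in six directional subiterations,
split into eight parity subfields so that deletions cannot cascade along a
thin rod within one pass, and ordered by distance-to-background so erosion
proceeds layer by layer and the surviving curve sits on the medial ridge
rather than drifting with scan order. Voxels whose neighbourhood foreground
splits in two — curve isthmuses — are preserved permanently, which anchors
the emerging curve and its endpoints without spur-prone endpoint
heuristics; a final cleanup removes voxels that ended up redundant
(triangle corners of doubled diagonal runs). On test cylinders the skeleton
stays within half a voxel of the true axis, and a solid torus thins to a
single clean cycle.

The voxel path is then smoothed by a moving average (window 5, endpoints
pinned) and refined by overlapping local cubic Bezier curves (windows of
four points, 50% overlap, linear blending across the shared span). Bezier
control points need not lie on the curve, which is exactly what filters the
residual half-voxel jag; keeping the windows local avoids the
over-smoothing a single global curve would cause at tight bends. On a
jagged helix discretization the refined curve sits at ~0.2 voxels RMS from
the true axis, about half the raw thinned path's error.

## Measurement conventions

Profiles are built at a fixed arc-length step (default 0.25 mm) with plane
normals from the centerline tangent, so oblique sections do not incur the
$1/\cos\theta$ inflation of fixed-axis slicing. When a plane intersects the
mesh in several loops, the loop containing the plane point (smallest such
loop) wins. A plane is *deviated* when its intersection line with a
neighbouring plane passes within the local equivalent radius, or when its
area jumps more than 30% against both neighbours; deviated planes are
repaired by interpolating center and normal between valid neighbours
(up to 3 rounds) and otherwise excluded with a flag. The centerline is
trimmed 1.5 mm at each end by default: the outermost skeleton voxels sit on
the end caps, where a cross-section is not meaningful.

The inscribed-circle diameter maximizes distance-to-boundary over the
polygon interior: a coarse grid at 1/20 of the equivalent radius followed
by two nested fine grids. It is the stenosis-robust "minimum caliber"
measure; on exact circles it equals the equivalent diameter to well under
1%, while on voxelized tubes the residual lattice scallop costs a few
percent — the isoperimetric bound (inscribed ≤ equivalent) holds always.

## Problem sizes and tolerances used by the test suite

The packaged checks run the full pipeline on a 30 mm tube at 0.4 mm voxels
(~0.5 M voxels), a stenotic variant, a one-turn helix (82³ grid), and
analytic meshes of spheres and cylinders at 5–10 voxel radii. Frozen
expectations come from closed forms (areas of disks, ellipses, circular
lenses, oblique sections), brute-force oracles (10⁶-point Monte-Carlo areas,
2000² distance-transform grids for the inscribed circle), and
determinism contracts (byte-identical profile CSVs for identical
configuration and seed). Key numeric tolerances: per-section CSA within 3%
of truth on the default tube; profile normalized RMSE ≤ 10%; refined
centerline RMS ≤ 0.5 voxel; inscribed-circle diameter within 1% of the
grid oracle; mesh volume within 2% and area within 3% of analytic spheres.

## Known limitations

* Single vessel, no bifurcations: branches must be removed upstream
  (masks or main-path pruning), matching the measurement model.
* The PSF is user-declared, not estimated; a badly wrong sigma degrades
  both restoration and (indirectly) calibration.
* Partial-volume calibration assumes two dominant tissues around the
  vessel; a third bright structure inside the calibration envelope would
  bias the mass target (use exclusion masks there).
* The DICOM reader is deliberately minimal: uncompressed single-frame CT
  series, explicit-VR little endian. NIfTI is the recommended interchange
  format.
* Validation against IVUS assumes the pullback table arrives pre-traced
  with positions on a comparable arc-length axis; landmark offsets are
  user inputs.
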