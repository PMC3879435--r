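---
title: "Simulated radiographic morphometry of the ankle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated radiographic morphometry of the ankle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anklemorph)
```

## The problem

Total ankle arthroplasty planning and prosthesis sizing rely on
morphological parameters of the distal tibia, fibula and talus — arc
lengths and radii of the articular surfaces, widths, thicknesses and
frontal tilts. In clinical practice these are usually measured on planar
radiographs, where two systematic error sources operate:

* **perspective magnification** — a structure at depth $d$ from the
  detector, imaged with source-to-image distance $\mathrm{SID}$, is
  enlarged by $\mathrm{SID}/(\mathrm{SID}-d)$;
* **mal-positioning** — if the limb is rotated away from the standard
  imaging pose, structures project obliquely and axis-referenced angles
  and distances change.

`anklemorph` reproduces this measurement chain end to end in simulation:
synthetic ankle specimens with *exactly known* morphology are imaged by a
virtual radiography system, the same fourteen parameters are measured in
3D (gold standard) and on the 2D projections, and the package quantifies
(i) the standard-pose 2D-vs-3D bias and its linear calibration,
(ii) the sensitivity of each 2D parameter to rotational pose error,
(iii) repeatability under random pose error via ICC(3,k), and
(iv) how much of the 2D error a standard-pose linear regression can
remove.

## The anatomical frame and the fourteen parameters

All geometry lives in an anatomical frame with origin at the geometric
centre of the talus (implemented as the area-weighted surface centroid),
X anteroposterior (positive anterior), Y superoinferior (positive
proximal) and Z mediolateral (positive medial). The parameters are:

| symbol | unit | definition |
|---|---|---|
| TiAL | mm | chord between the anterior (A) and posterior (B) ends of the tibial mortise arc |
| TiSR | mm | radius of that arc (least-squares circle fit) |
| APG | mm | Y-component of A−B |
| APA | deg | inclination of AB against the X axis |
| MTiTh | mm | X-distance between the most anterior (C) and posterior (D) profile points |
| MDA | mm | Y-distance between A and C |
| MDV | mm | Y-distance between the mortise vertex V and D |
| TiW | mm | mortise width: mean of the anterior and posterior edge endpoint segments |
| MalW | mm | Z-distance between the most lateral fibula and most medial tibia points |
| MLATi | deg | frontal tilt of the line joining the most distal fibula and tibia points |
| TaAL | mm | circular arc length through the trochlea landmarks F (anterior), H (proximal), G (posterior) |
| TaR | mm | trochlea sagittal radius (circle fit per slab) |
| TaW | mm | trochlea width: segment between the medial and lateral crest landmarks |
| MLATa | deg | frontal tilt of the trochlea crest vertex line |

Two conventions deserve comment, because the width and angle definitions
are not all equivalent once the bone is rotated:

* **Widths defined by an endpoint pair** (TiW, TaW) are measured as the
  Euclidean length of the endpoint segment, in 3D and in the image alike.
  In 3D the two endpoints share their other coordinates, so this equals
  the axis-component reading exactly; in 2D it is the choice that makes an
  in-plane rotation a pure isometry of the measurement, which is the
  behaviour the sensitivity experiment exhibits for equal-depth endpoints.
  MalW, APG, MDA, MDV and MTiTh remain axis components.
* **Angles are measured against the fixed image axes** and reported as
  magnitudes. A consequence is that an in-plane rotation of the specimen
  changes every image-axis-referenced angle by exactly the rotation angle;
  there is no hidden co-rotating reference. This is the clinically
  realistic convention (a radiograph has no access to the specimen's
  internal axes).

## The synthetic specimen (phantom)

The phantom is a constructive-solid-geometry idealisation, not a
statistical shape model; the package's claims concern projection geometry,
which CSG bones exercise exactly while keeping every parameter
closed-form:

* **talus** — a cylinder-segment trochlea (axis along Z, central radius
  `tar`, arc half-angle `taal / (2 tar)`) on a prismatic body, with raised
  medial and lateral crest bands whose gentle roof makes the crest apex
  vertices unique; the medial crest is raised an extra
  `taw * tan(mlata)` to produce the talar frontal tilt;
* **distal tibia** — a block whose distal face carries a concave
  cylindrical mortise cut (radius `tisr`, chord `tial`, chord inclination
  `apa`), anterior/posterior profile creases placed to realise MTiTh, MDA
  and MDV (slightly bevelled faces keep the extremal points unique), and a
  medial malleolus column with a pyramidal tip;
* **fibula** — a lateral malleolus column whose tip is dropped by
  `(tiw/2 + malw/2) * tan(mlati)` relative to the tibial tip, producing
  the inter-malleolar frontal tilt.

Every Table-style parameter is therefore an *input* to the construction,
and `generate_phantom()` emits the exact ground-truth profile and the
landmark set (placed on actual mesh vertices) alongside the meshes. The
attenuation volume is rasterised from the same implicit solids (binary
bone/background by default, with an optional soft-tissue shell level to
make edge detection harder); the analytic solid volume provides an
independent check of the rasteriser (voxel count within 2%).

Cohort generation draws the thirteen free parameters from truncated
normal distributions (±3 SD) around the study-population means stored in
`ankle_cohort_defaults()`; APG is excluded because it is geometrically
determined by TiAL and APA (APG = TiAL·sin APA; the defaults verify this
to 1%). Draws violating a geometric feasibility invariant (for example a
sagittal radius too small for the arc chord, or a trochlea wider than the
mortise) are rejected and redrawn, with an error if the means themselves
are infeasible. Angles are reported as magnitudes, so a negative tilt draw
has a positive ground truth.

What the phantom does **not** emulate: cortical/trabecular attenuation
structure, cartilage, neighbouring bones (calcaneus, navicular), soft
tissue scatter, detector noise, and the shape variability of real tali
beyond the fourteen parameters. Passing tests therefore demonstrate the
correctness of the projection geometry and of the measurement and
statistics pipeline — not the anatomical fidelity of any silhouette-level
effect (for instance, real trochlea width measurements suffer overlap
effects this phantom cannot reproduce).

## The virtual radiography system

DRRs are rendered by perspective ray casting: for every detector pixel the
attenuation is integrated along the source-to-pixel ray (midpoint rule at
a fixed nominal step, default half the smallest voxel dimension) with
trilinear interpolation; samples outside the volume contribute zero, and
rays missing the volume give exactly zero. Pixel intensities are raw line
integrals — no Beer–Lambert conversion or detector response — because all
measurements depend on geometry alone. The rigid pose is applied to the
*ray sample positions* through the inverse rotation, never by resampling
the volume, so no interpolation loss accumulates across poses. The
integrator is compiled (Rcpp); a pure-R fine-step integrator serves as an
independent oracle in the tests (agreement within 0.5% on random rays).

Standard-pose geometries follow radiographic positioning practice with
SID = 1000 mm:

* **M/L (lateral)**: detector normal to Z, touching the most lateral
  fibula point; principal ray through the most medial tibia point; image
  axes (u, v) ≡ (X, Y).
* **A/P (frontal)**: detector normal to X, offset from the most posterior
  bone point by a configurable heel stand-in thickness (default 40 mm,
  emulating the calcaneus and soft tissue that separate the ankle from
  the plate); principal ray through the inter-malleolar midpoint; image
  axes (u, v) ≡ (Z, Y).

The detector defaults to 512 × 512 pixels at 0.35 mm pitch (the pitch is
not a physically pinned value and is recorded in the geometry so its
influence can be audited); the fast profile uses 192 px at 0.7 mm.

2D landmarks are labeled by projecting the 3D landmarks (provenance
`"projected"`); `label_landmarks_2d()` can snap them to detected contour
points within a capture radius, but the default radius is 0 — the human
landmark-identification step of a reading-room workflow is out of scope,
and projected labels make the geometric effects exact. Image contours
(gradient-magnitude edges linked into connected components) are still used
for the 2D circle-fit parameters TiSR and TaR, which are refined on edge
points near the projected arc and fall back to the three-point circle when
too few edge points support the fit.

## The perturbation experiments

**Rotation pivot.** Positioning error arises while the limb rests on the
detector assembly, so perturbations rotate the specimen about the
anatomical axes through the *detector contact point* (the most distal of
the bone points touching the plane, projected onto it): the lateral
malleolus for the M/L view and the posterior heel stand-in for the A/P
view. This choice matters only for out-of-plane rotations, where the
magnification change of a structure is proportional to its lever arm about
the pivot: with a pivot at malleolar level the mortise chord's lateral
magnification is nearly unchanged by a ±6° tilt (|ΔTiAL| ≤ 0.1%), which is
the observed clinical-imaging behaviour this package reproduces; a pivot
at the talus centre, ~20 mm distal to the mortise, would instead produce a
systematic ~0.2% change. `pivot = "origin"` restores talus-centre
rotations for users who want them. In-plane sensitivities (the large MDA,
MDV, MLATi, MLATa effects) are independent of the pivot.

**Systematic sweep.** From the standard pose, ±6° in 1° steps about each
anatomical axis: 12 perturbed poses per axis plus the shared standard pose
= 37 distinct poses per view. Percent error is
$100\,(v(\theta)-v(0))/v(0)$ against the standard-pose 2D value, exactly 0
at θ = 0 by definition. A parameter whose landmark leaves the imaging
frustum is recorded as missing, never extrapolated. Trends are classified
by fitting $b_1\theta + b_2\theta^2$ (zero intercept forced by the 0-at-0
invariant): quadratic if $b_2$ is significant at α = 0.05, else linear if
$b_1$ is, else none; coefficients whose contribution over the sweep is
below numerical noise never count, so exact zeros classify as "none".

**Repeatability.** Each specimen receives 10 random poses with each
rotational component drawn independently and uniformly in [−bound, +bound]
(the bound defaults to 6°; the uniform law is the least-informative choice
for an error "within a maximum range"). ICC(3,k) — two-way mixed effects,
average measures, consistency — is computed directly from the ANOVA mean
squares, $(\mathrm{BMS}-\mathrm{EMS})/\mathrm{BMS}$, with reliability
bands very good (> 0.81), good (0.61–0.80), moderate (0.41–0.60), fair
(0.21–0.40) and poor (< 0.2). Incomplete specimen rows are dropped and
counted. `stats::aov` is used as an independent oracle in the tests, never
as the implementation.

**Correction.** Per parameter, ordinary least squares of the 3D gold
standard on the standard-pose 2D values gives the calibration
$3D = a \cdot 2D + b$ (this direction is what a clinician needs: predict
the true value from the radiograph). Perturbed-pose 2D measurements at
bounds of 3° and 6° are corrected through these equations and compared to
the 3D truth; the residual table reports signed mean percent errors
before/after correction together with mean-absolute companions, because a
signed mean can hide dispersion. Percent errors of small-valued angle
parameters (MLATa has a ~2° baseline) are intrinsically ill-conditioned
and are expected to remain large after correction.

## Numerical choices

* Circle fits: algebraic (Kåsa) solution refined by a few Gauss–Newton
  orthogonal-distance steps; residual RMS is reported. Mortise and
  trochlea surface point sets are selected by face-normal classification
  (a vertex counts as articular if *any* adjacent face points
  down/upward past the threshold, which is robust at crease vertices),
  and the mortise fit is trimmed iteratively (0.5 mm inlier tolerance).
  Exactly horizontal distal faces are excluded up front: for shallow
  mortise arcs their corner points are nearly cotangent to the arc circle
  and would otherwise leak into the fit.
* The central sagittal slab for the mortise arc is 10% of the fitted
  mortise width, found in two passes (fixed 2 mm window, then resized).
* Extremal landmarks break exact ties lexicographically on ascending
  (x, y, z); the generator places its ground-truth landmarks with the
  same rule, so extraction is reproducible to machine precision.
* Arc length TaAL is the circular arc through F, H, G (the three-point
  circle), not the polyline.
* Rotation composition is extrinsic about the fixed anatomical axes in
  the order X → Y → Z; at the ≤ 6° amplitudes studied, order effects are
  second order.
* Degenerate inputs error loudly: empty meshes, collinear circle points,
  constant ICC matrices, infeasible phantom specs (the violated invariant
  is named).

## Problem sizes and profiles

The full profile matches the emulated imaging chain (0.625 mm voxels,
512 × 512 detector at 0.35 mm). The fast profile (1.25 mm voxels, 192 px
at 0.7 mm) is used for the test suite and the packaged example study
(`inst/extdata/fast_study.yaml`, n = 6): geometric effects of interest are
all ≫ one coarse pixel, and the full study — cohort, 3D measurement,
standard-pose DRRs, two 37-pose sweeps, repeatability and two correction
bounds — completes in minutes on one CPU. The acceptance script uses
CT-matched 0.625 mm voxels with a 256 px detector.

## Known limitations

* Landmark-projection labeling cannot reproduce silhouette-level effects:
  real trochlea-width readings are driven by crest overlap in the image,
  which is why no claim is made about reproducing the large printed TaW
  sensitivities in magnitude.
* Percent-error summaries are unstable for near-zero-valued parameters;
  absolute errors should be consulted alongside (both are reported).
* An image-axis-referenced angle is *not* invariant to in-plane rotation,
  so sensitivity entries for APA under sagittal in-plane rotation differ
  by convention from reading practices that re-reference angles to bone
  axes; the fixed-image-axis convention is retained and documented rather
  than silently compensated.
* Translational positioning errors and ankle plantar-/dorsiflexion are
  out of scope.
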