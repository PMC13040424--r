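---
title: "Methods: automated cervical biometry and volumetry from label maps"
author: "cervimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated cervical biometry and volumetry from label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervimorph)
```

## What the package measures

The late-gestation cervix, segmented from a 3D MRI reconstruction, is
represented here as an integer label volume: outer stroma (1), inner
stroma (2), cervical canal (3), optional canal cyst (4), and an optional
lower-uterine reference region (5). From this single input the package
derives the standard biometric panel used in obstetric imaging:

* **2-point cervical length** — straight distance from internal to
  external os (mm);
* **3-point cervical length** — the two straight segments through the
  canal midpoint, a first-order correction for canal curvature (mm);
* **internal and external os diameters** — widest extent of the canal
  cross-section just inside each os (mm);
* **utero-cervical angle (UCA)** — angle at the internal os between the
  lower-uterine-segment axis and the cervical line (degrees, 0–180);
* **compartment volumes** — total cervix, stroma (labels 1+2), canal,
  cyst (cm^3^).

All geometry is computed in world millimetres through the NIfTI affine
(0-based voxel indices, voxel-center convention), so anisotropic and
oblique volumes are handled uniformly. Volumes are voxel counts times the
voxel volume (|det| of the affine's 3×3 block); the partition
total = stroma + canal + cyst is therefore exact by construction, and the
uterine reference region never contributes to cervical volumes.

## Canal centerline

Every 2D measurement hangs off the canal centerline, so its construction
is the methodological core. We use a distance-penalized geodesic — a
standard skeleton-free centerline construction for tubular organs —
rather than topological thinning, because a voxelized canal at 0.8 mm
grows spurious skeleton branches ("boutonnière" spurs) that a longest-path
search over a thinned skeleton must then prune heuristically. The
construction is:

1. take the largest 26-connected component of the canal ∪ cyst region
   (ties broken towards the lowest voxel index; components under 20
   voxels are rejected as "canal too small");
2. compute the Euclidean distance transform (EDT) inside the component,
   exactly, under anisotropic spacing (separable lower-envelope
   algorithm);
3. run Dijkstra twice over the 26-connected voxel graph (the classic
   pseudo-diameter trick: from the most interior voxel to its farthest
   voxel, then from there to *its* farthest voxel). Edge costs are the
   world step length inflated by `1 + alpha * (1 - dt/dt_max)^2` with
   `alpha = 10`, which holds the path on the medial ridge;
4. smooth with a 5-point moving average (windows shrink symmetrically at
   the ends so endpoints stay anchored), then recenter every interior
   point to the centroid of the component voxels in the 1-voxel slab
   orthogonal to the local tangent (two passes — tangents are re-estimated
   on the first pass's output);
5. rebuild the end runs: the raw geodesic terminates on cap *corners*,
   so the final ~2·dt~max~ of path at each end is discarded and re-grown
   by marching perpendicular-slab centroids along the (gradually turning)
   interior tangent until no component material lies ahead; the final
   four half-voxel steps are replaced by a straight continuation because
   slabs partially cut by the cap plane have laterally biased centroids;
6. extend each endpoint by half the mean voxel size along the end
   tangent. Voxel centers sit about half a voxel inside the physical end
   cap, so the raw polyline systematically under-reaches the anatomical
   os; this is a discretization-bias correction, not a tuning constant.

The endpoint nearer the uterine end of the reference axis is designated
the internal os. The reference axis comes either from a JSON sidecar (two
world-mm points) or, failing that, from the first principal axis of the
label-5 region; an input with neither is rejected with an error naming
both remedies.

## Os diameters and the angle

The os diameter is measured one voxel-diagonal inward from the endpoint:
canal ∪ cyst voxels within a 1-voxel slab orthogonal to the local tangent
(and within half the arc length of the slab point, guarding against a
strongly curved canal re-crossing the plane) are projected onto the
orthogonal plane, and the maximum Feret diameter (largest pairwise
distance) is taken, plus one mean voxel size for the half-voxel physical
extent of the boundary voxels on each side. An empty slab returns 0.

The UCA is the angle between the unit direction of the uterine axis
(oriented away from the cervix) and the internal→external os line,
anchored at the internal os, via the arccosine of the normalized dot
product. We use the straight 2-point line rather than the canal tangent
because the angle is interpreted against the 2-point length construct;
the direction form (rather than a vector to a specific point on the
axis) makes the result independent of how far along the uterus the axis
happens to be annotated.

## The phantom generator

`phantom_spec()` / `make_phantom()` build nested-tube phantoms with
closed-form ground truth: a canal of linearly tapering radius around a
straight or circular-arc centerline, wrapped in inner and outer stroma
shells with flat end caps, an optional spherical intracanal cyst, and a
label-5 bar attached at the internal os at a prescribed UCA. Voxelization
is by signed-distance evaluation at voxel centers on an axis-aligned grid
padded 5 voxels beyond the phantom extent. Ground truth is analytic:

* straight canal volume `pi L (r1^2 + r1 r2 + r2^2)/3` (conical frustum);
* stroma shell `pi L (2 t (r1+r2)/2 + t^2)` with `t` the combined
  thickness;
* arc chords `2R sin(theta/2)` and `4R sin(theta/4)` for the 2-/3-point
  lengths of a curved canal;
* the cyst is constrained to lie strictly inside the canal so its
  closed-form sphere volume can simply be subtracted from the canal.

Rigid rotation is applied to the *geometry* before voxelization, so
rotated phantoms genuinely re-sample the shape on a fixed grid — the
hard version of rotation invariance.

What the phantoms deliberately do **not** emulate: segmentation noise,
partial-volume blur at tissue interfaces, non-tubular canal shapes
(funnelling beyond a linear taper), or any image intensities. Passing the
phantom suite shows the geometry engine is correct at the stated voxel
size; it does not certify performance on imperfect segmentations of real
anatomy.

Validation problem sizes: the randomized recovery suite uses 50 phantoms
at 0.8 mm (canal length 25–40 mm, end radii 1.6–4 mm, half curved with
radius ≥ 18 mm, rotations up to ±40°, a quarter with cysts), chosen to
bracket realistic late-gestation dimensions while keeping a full suite
run near ten seconds.

## The cohort simulator

`make_cohort()` draws a synthetic cohort with the statistical structure
the association battery assumes: demographics uniform over age 19–42
years, BMI 18–32, gestational age 35.71–40.14 weeks; a latent 2-point
cervical length; stroma and canal volumes linear in length and (for
stroma) in age with Gaussian noise; os diameters with a controlled
internal-minus-external difference; and birth outcomes from logistic
models — caesarean on total volume (default odds ratio 1.09 per cm^3^)
and induction on external os diameter (default 0.83 per mm). The
os-difference SD is implied by the two targets
(`mean/qnorm(frac)`, 3.5 mm and 81.8% by default), so both the mean
difference and the internal-larger fraction match in expectation.

Effect magnitudes that are not targets (volume baselines, length slopes,
noise SDs) are package configuration chosen to give realistic cervix
dimensions (~40–50 cm^3^ total volume); they are defaults, not empirical
claims, and each is a `cohort_sim_params()` argument.
`null_cohort_params()` zeroes every effect for type-I-error calibration.

## Statistical battery

Normality screening uses the Shapiro–Wilk test (n between 3 and 5000,
non-constant input enforced). Outlier handling removes values outside
Q1 − 1.5·IQR and Q3 + 1.5·IQR with type-7 (linear-interpolation)
quartiles, applied once to the response of each linear model. Linear
models are ordinary least squares with Wald t intervals; logistic models
are maximum-likelihood fits (IRLS, tolerance 1e-8, up to 100 iterations)
with Wald intervals on the odds-ratio scale, and complete or
quasi-complete separation is flagged rather than silently returned.

Inter-rater agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single rater — from the mean-squares decomposition, with the
F-based 95% confidence interval. The form is a documented choice: where
only "intraclass correlation" is specified, ICC(2,1) is the conservative
default for agreement between interchangeable raters; the mean squares
are exposed in the result for anyone needing a different form. Degenerate
matrices (zero error variance, zero subject variance) return the limits
the variance model dictates (1, and ≤ 0 respectively) with collapsed
intervals.

The association battery (`association_report()`) runs a fixed set of
models — biometry on cervical length, stroma volume on age, caesarean on
total volume controlling for age and ethnicity, induction on external os
diameter corrected for gestational age — and reports the focal term of
each with raw p-values (no multiplicity correction by default, matching
exploratory cohort reporting; Benjamini–Hochberg is available via
`adjust = TRUE`). "Cervical volume" in the caesarean model is total
volume in cm^3^ by default; volumes can be reported in mm^3^ via the run
configuration, which rescales the odds-ratio units accordingly.

## Numerical choices and degenerate inputs

* Component connectivity 26 for the canal, 6 for adjacency warnings;
  minimum canal component 20 voxels.
* Ties in component size break towards the lowest voxel index; the
  Dijkstra source is the global EDT maximum.
* The medial penalty `alpha = 10` makes a boundary step ~11× the cost of
  a medial step; results are insensitive to this within a factor of a
  few, it only needs to dominate the staircase savings.
* The march turn rate is capped at 4° per half-voxel step (a turning
  radius floor of ~5.7 mm at 0.8 mm spacing), so slab-centroid jitter
  cannot fold the end run back into the canal.
* Centerlines require ≥ 3 points and strictly distinct consecutive
  points; zero-length direction vectors in the angle are errors.
* NIfTI stores the affine in float32; round-trips are guaranteed to
  1e-6 mm, not to double precision.

## Known limitations

* Accuracy is quantization-limited at 0.8 mm: expect ~0.5 mm typical
  (≤ 1 voxel median) error in lengths and diameters and ~0.5° in the
  angle on clean segmentations; halving the voxel size halves most of it.
* The canal compartment is thin (~400 mm^3^ at radius 2 mm ≈ 780
  voxels), so re-voxelizing the same shape at a different orientation
  moves its voxel-count volume by up to ~2–4% from grid phase alone —
  an inherent property of center-sampled voxelization, not of the
  measurement, which is exactly rotation-invariant given the voxel data.
  Total and stroma volumes, an order of magnitude larger, re-voxelize
  within ~1%.
* The os-diameter convention (orthogonal slab Feret, one diagonal inward)
  and the UCA reference construction are documented package conventions;
  sites with their own landmark protocol should treat them as defaults to
  review before cross-study comparison.
* The geodesic centerline assumes the canal is a single tubular
  component; a canal fragmented by segmentation dropout is measured on
  its largest fragment only (component sizes are reported in the
  provenance for screening).
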