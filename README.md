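# cervimorph

Automated biometry and volumetry of the late-gestation cervix from 3D
MRI label maps.

Cervical length, os diameters, utero-cervical angle and compartment
volumes are established predictors and correlates of birth outcome, but
measuring them by hand in 3D is slow and rater-dependent. `cervimorph`
takes a multi-label segmentation of the uterocervix (NIfTI; outer
stroma = 1, inner stroma = 2, canal = 3, cyst = 4, optional
lower-uterine reference = 5) and computes the full panel automatically:

* 2-point cervical length `|internal os − external os|` and 3-point
  length through the canal midpoint (mm);
* internal and external os diameters (max Feret of the orthogonal canal
  cross-section at each os, mm);
* utero-cervical angle between the lower-uterine-segment axis **u** and
  the cervical line **c**, `arccos(u·c / |u||c|)` in degrees;
* total / stroma / canal / cyst volumes (voxel count × voxel volume,
  cm³), with total = stroma + canal + cyst exact.

The canal centerline — the backbone of the 2D measurements — is a
distance-penalized geodesic through the largest canal component
(Euclidean distance transform + double Dijkstra, smoothed and
recentered), computed in compiled code. Because no patient images can be
redistributed, the package ships an analytic phantom generator
(`make_phantom()`) whose nested-tube geometry has closed-form ground
truth, and a synthetic cohort simulator (`make_cohort()`) for the
statistical layer: Shapiro–Wilk screening, 1.5×IQR outlier filtering,
ICC(2,1) rater agreement, and the linear/logistic GLM battery relating
biometry to demographics and birth outcomes.

## Worked example

Build a curved phantom with known geometry and measure it:

```r
library(cervimorph)

ph <- make_phantom(phantom_spec(canal_length = 32, canal_radius_internal = 2.5,
                                canal_radius_external = 2,
                                curvature_radius = 30,
                                utero_cervical_angle = 125))
compute_biometry(ph$volume, ph$axis, scan_id = "demo01")
#> Cervical biometry [demo01]
#>   cervical length : 29.7 mm (2-point), 30.8 mm (3-point)
#>   os diameters    : internal 5.7 mm, external 4.7 mm
#>   utero-cervical angle: 123.0 deg
#>   volumes (cm3)   : total 8.50 = stroma 8.00 + canal 0.50 + cyst 0.00
```

The analytic truth for this phantom (`ph$ground_truth`) is 30.5 mm
2-point length, 31.6 mm 3-point, diameters 5.0 / 4.0 mm, angle 125°,
canal 0.51 cm³: every measurement lands within about one 0.8 mm voxel
(and 2° of angle) of truth, which is the accuracy the voxel size
supports. The 2-point length is shorter than the 3-point length because
the canal is curved; both are shorter than the 32 mm arc.

On the statistics side, a synthetic cohort reproduces the structure the
association battery expects — volumes rising with cervical length, os
diameters falling, and a caesarean odds ratio per cm³ of total volume:

```r
co  <- make_cohort(cohort_sim_params(n = 2000, seed = 7))
association_report(co)
#> Cervical biometry association battery (n = 2000, 9 tests)
#>  response          term           type     estimate odds_ratio ...
#>  total_vol_cm3     length_2pt_mm  linear   0.539    NA
#>  ...
#>  caesarean         total_vol_cm3  logistic 0.0710   1.070
#>  induced           ext_os_diam_mm logistic -0.215   0.807
```

The caesarean row is the fitted odds ratio per cm³ (generator default
1.09; at n = 2000 it is estimated at 1.07 with CI [1.06, 1.09]), and the
induction row the odds ratio per mm of external os diameter (default
0.83). `plot(association_report(co))` draws the forest plot.

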