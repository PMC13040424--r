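test_that("ground-truth volumes match independent numerical integration", {
  # linear-taper canal: closed form vs brute-force quadrature of pi r(s)^2
  spec <- phantom_spec(canal_length = 30, canal_radius_internal = 2,
                       canal_radius_external = 1)
  gt <- phantom_ground_truth(spec)
  s <- seq(0, 30, length.out = 20001)
  ds <- s[2] - s[1]
  r <- 2 + (1 - 2) * s / 30
  trap <- function(f) ds * (sum(f) - (f[1] + f[length(f)]) / 2)
  expect_equal(gt$canal_volume * 1000, pi * 30 * (4 + 2 + 1) / 3,
               tolerance = 1e-12)           # frustum: ~219.91 mm3
  expect_equal(gt$canal_volume * 1000, trap(pi * r^2), tolerance = 1e-6)

  tt <- spec$inner_stroma_thickness + spec$outer_stroma_thickness
  expect_equal(gt$stroma_volume * 1000, trap(pi * ((r + tt)^2 - r^2)),
               tolerance = 1e-6)

  # torus chords vs brute-force distances on the parametric curve
  R <- 20; L <- pi * R / 2
  spec2 <- phantom_spec(canal_length = L, curvature_radius = R)
  gt2 <- phantom_ground_truth(spec2)
  curve <- function(ss) {
    th <- ss / R
    c(0, R - R * cos(th), R * sin(th))
  }
  p0 <- curve(0); pm <- curve(L / 2); p1 <- curve(L)
  expect_equal(gt2$length_2pt, sqrt(sum((p1 - p0)^2)), tolerance = 1e-9)
  expect_equal(gt2$length_3pt,
               sqrt(sum((pm - p0)^2)) + sqrt(sum((p1 - pm)^2)),
               tolerance = 1e-9)
  expect_lte(gt2$length_2pt, gt2$length_3pt)
  expect_lte(gt2$length_3pt, gt2$arc_length)
})

test_that("voxelized canal volume matches the frustum closed form", {
  spec <- phantom_spec(canal_length = 30, canal_radius_internal = 2,
                       canal_radius_external = 1)
  ph <- make_phantom(spec)
  vols <- compartment_volumes(ph$volume)
  expect_lt(abs(vols["canal"] - ph$ground_truth$canal_volume) /
              ph$ground_truth$canal_volume, 0.05)
})

test_that("a cyst is carved out of the canal and the partition still holds", {
  spec <- phantom_spec(canal_length = 32,
                       cyst = list(arc_fraction = 0.5, radius = 1.4))
  ph <- make_phantom(spec)
  expect_true(4L %in% ph$volume$labels)
  vols <- compartment_volumes(ph$volume)
  expect_gt(vols["cyst"], 0)
  expect_equal(unname(vols["total"]),
               unname(vols["stroma"] + vols["canal"] + vols["cyst"]))
  # sphere fully inside the canal: measured cyst near (4/3) pi r^3
  sphere <- 4 / 3 * pi * spec$cyst$radius^3 / 1000
  expect_lt(abs(vols["cyst"] - sphere) / sphere, 0.25)
  # ground truth is consistent with its own partition
  gt <- ph$ground_truth
  expect_equal(gt$total_volume,
               gt$stroma_volume + gt$canal_volume + gt$cyst_volume,
               tolerance = 1e-12)
})

test_that("phantom generation is a pure function of the spec", {
  s1 <- phantom_spec(canal_length = 28, seed = 1)
  s2 <- phantom_spec(canal_length = 28, seed = 2)
  ph1 <- make_phantom(s1); ph2 <- make_phantom(s2)
  # no noise model: different seeds give identical geometry
  expect_identical(ph1$volume$voxels, ph2$volume$voxels)
  expect_identical(compartment_volumes(ph1$volume),
                   compartment_volumes(ph2$volume))
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(canal_length = -5))
  expect_error(phantom_spec(utero_cervical_angle = 0))
  expect_error(phantom_spec(curvature_radius = 5), "curvature_radius")
  expect_error(phantom_spec(canal_length = 100, curvature_radius = 25),
               "180 degrees")
  expect_error(phantom_spec(cyst = list(arc_fraction = 0.01, radius = 2)),
               "cyst")
})

test_that("cohort simulator hits its configured moments", {
  p <- cohort_sim_params(n = 20000, seed = 5)
  co <- make_cohort(p)
  expect_identical(nrow(co), 20000L)
  expect_true(all(co$age >= 19 & co$age <= 42))
  expect_true(all(co$bmi >= 18 & co$bmi <= 32))
  expect_true(all(co$ga_weeks >= 35.71 & co$ga_weeks <= 40.14))
  expect_lt(abs(mean(co$int_os_diam_mm > co$ext_os_diam_mm) - 0.818), 0.015)
  expect_lt(abs(mean(co$int_os_diam_mm - co$ext_os_diam_mm) - 3.5), 0.1)
  expect_setequal(unique(co$caesarean), c(0L, 1L))
  # reproducibility under the seed
  expect_identical(co, make_cohort(p))
})

test_that("zero age slope gives a calibrated null for the age regression", {
  # CI for the age slope should cover 0 in about 95% of replicate cohorts
  cover <- vapply(1:100, function(i) {
    co <- make_cohort(cohort_sim_params(n = 150, stroma_vol_age_slope = 0,
                                        seed = 1000 + i))
    f <- fit_linear(co$stroma_vol_cm3, data.frame(age = co$age),
                    filter_outliers = FALSE)
    row <- f$terms[f$terms$term == "age", ]
    row$ci_low <= 0 && 0 <= row$ci_high
  }, logical(1))
  expect_gte(sum(cover), 88)  # binomial(100, .95) lower tail
})

test_that("rating replicates behave as a Gaussian rater model", {
  truth <- c(20, 25, 30, 35, 40, 45)
  r0 <- make_rating_replicates(truth, rater_sd = 0, n_raters = 3, seed = 1)
  expect_identical(r0[, 1], r0[, 2])
  expect_equal(icc(r0)$coefficient, 1.0)

  r1 <- make_rating_replicates(truth, rater_sd = 1, n_raters = 3, seed = 9)
  expect_identical(r1, make_rating_replicates(truth, 1, 3, seed = 9))

  # ICC decreases monotonically as rater noise swamps subject variance
  iccs <- vapply(c(0.5, 2, 8, 32), function(sdv) {
    m <- make_rating_replicates(truth, rater_sd = sdv, n_raters = 3,
                                seed = 42)
    icc(m)$coefficient
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_lt(iccs[4], 0.3)
})
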