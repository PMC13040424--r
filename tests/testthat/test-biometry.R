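test_that("cervical lengths follow the 2-/3-point definitions", {
  # collinear landmarks: both lengths equal exactly
  cl <- new_centerline(cbind(0, 0, seq(0, 30, by = 1)))
  lm <- locate_os_landmarks(cl)
  len <- cervical_length(lm)
  expect_equal(unname(len["length_2pt"]), unname(len["length_3pt"]))
  expect_equal(unname(len["length_2pt"]), 30)

  # straight phantom: both lengths within 2 voxels of 32
  ph <- straight_phantom()
  b <- compute_biometry(ph$volume, ph$axis)
  expect_lt(abs(b$length_2pt - 32), 1.6)
  expect_lt(abs(b$length_3pt - 32), 1.6)

  # quarter torus R=20: chords of the circular arc
  ph2 <- torus_phantom()
  b2 <- compute_biometry(ph2$volume, ph2$axis)
  expect_lt(abs(b2$length_2pt - 2 * 20 * sin(pi / 4)), 1.6)   # 28.284
  expect_lt(abs(b2$length_3pt - 4 * 20 * sin(pi / 8)), 1.6)   # 30.615
  expect_lt(b2$length_2pt, b2$length_3pt)
  expect_lt(b2$length_3pt, b2$arc_length)
})

test_that("triangle property holds on random polyline centerlines", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    pts <- matrix(rnorm(3 * n, sd = 10), n, 3)
    pts <- pts[!duplicated(round(pts, 6)), , drop = FALSE]
    if (nrow(pts) < 3) next
    cl <- new_centerline(pts)
    lm <- locate_os_landmarks(cl)
    len <- cervical_length(lm)
    expect_lte(len["length_2pt"], len["length_3pt"] + 1e-9)
    expect_lte(len["length_3pt"], cl$arc_length + 1e-9)
  }
})

test_that("os diameters recover tube radii and funnel asymmetry", {
  ph <- straight_phantom()
  cl <- extract_canal_centerline(ph$volume, ph$axis)
  di <- os_diameter(ph$volume, cl, "internal")
  de <- os_diameter(ph$volume, cl, "external")
  expect_lt(abs(di - 4), 1.6)
  expect_lt(abs(de - 4), 1.6)
  expect_error(os_diameter(ph$volume, cl, "sideways"))

  # funnel tapering 4.0 -> 1.6 mm: internal strictly larger than external
  phf <- funnel_phantom()
  bf <- compute_biometry(phf$volume, phf$axis)
  expect_gt(bf$internal_os_diameter, bf$external_os_diameter)
  expect_lt(abs(bf$internal_os_diameter - 8), 1.6)
})

test_that("funnel monotonicity: wider internal taper widens the measurement", {
  meas <- vapply(c(2.2, 3.0, 3.8), function(r) {
    ph <- make_phantom(phantom_spec(canal_length = 30,
                                    canal_radius_internal = r,
                                    canal_radius_external = 1.8))
    compute_biometry(ph$volume, ph$axis)$internal_os_diameter
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})

test_that("a single-voxel-wide canal end yields a sub-diagonal diameter", {
  a <- array(0L, dim = c(12, 12, 40))
  a[5:8, 5:8, 4:24] <- 3L      # wide run
  a[6, 6, 25:36] <- 3L         # one-voxel-wide tail at the external end
  v <- label_volume(a, diag(c(0.8, 0.8, 0.8, 1)))
  ax <- uterine_axis(c(4.8, 4.8, 2), c(4.8, 4.8, -20))
  cl <- extract_canal_centerline(v, ax)
  de <- os_diameter(v, cl, "external")
  # single-point cross-section: Feret 0 plus the voxel-extent term
  expect_lte(de, sqrt(3) * 0.8 + 1e-9)
})

test_that("utero-cervical angle matches analytic configurations", {
  lm <- structure(list(internal_os = c(0, 0, 0), external_os = c(0, 0, -30),
                       canal_mid = c(0, 0, -15)), class = "os_landmarks")
  ax_anti <- uterine_axis(c(0, 0, 0), c(0, 0, 40))
  expect_equal(utero_cervical_angle(lm, ax_anti), 180)
  ax_perp <- uterine_axis(c(0, 0, 0), c(0, 40, 0))
  expect_equal(utero_cervical_angle(lm, ax_perp), 90)
  lm_bad <- structure(list(internal_os = c(0, 0, 0), external_os = c(0, 0, 0),
                           canal_mid = c(0, 0, 0)), class = "os_landmarks")
  expect_error(utero_cervical_angle(lm_bad, ax_perp), "zero-length")

  # construction-parameter recovery from the voxelized phantom
  ph <- make_phantom(phantom_spec(canal_length = 32,
                                  utero_cervical_angle = 120))
  b <- compute_biometry(ph$volume, ph$axis)
  expect_lt(abs(b$utero_cervical_angle - 120), 2)
})

test_that("compartment volumes are exact voxel arithmetic in cm3", {
  a <- array(0L, dim = c(20, 20, 20))
  a[1:10, 1:10, 1:10] <- 1L   # 1000 stroma voxels
  v <- label_volume(a, diag(c(0.8, 0.8, 0.8, 1)))
  vols <- compartment_volumes(v)
  expect_equal(unname(vols["stroma"]), 1000 * 0.512 / 1000)  # 0.512 cm3
  expect_equal(unname(vols["total"]), unname(vols["stroma"]))

  # straight tube canal volume vs analytic cylinder pi r^2 L
  ph <- straight_phantom()
  vols2 <- compartment_volumes(ph$volume)
  cyl <- pi * 2^2 * 32 / 1000
  expect_lt(abs(vols2["canal"] - cyl) / cyl, 0.05)

  # partition identity is exact, and label 5 is excluded
  expect_equal(unname(vols2["total"]),
               unname(vols2["stroma"] + vols2["canal"] + vols2["cyst"]))
  with_bar <- sum(ph$volume$voxels %in% 1:4) * 0.512 / 1000
  expect_equal(unname(vols2["total"]), with_bar)
})

test_that("compute_biometry assembles a consistent panel with provenance", {
  ph <- straight_phantom()
  b <- compute_biometry(ph$volume, ph$axis, scan_id = "t1")
  expect_s3_class(b, "cervical_biometry")
  expect_lte(b$length_2pt, b$length_3pt + 1e-9)
  expect_lte(b$length_3pt, b$arc_length + 1e-9)
  expect_true(all(c(b$length_2pt, b$internal_os_diameter,
                    b$external_os_diameter, b$total_volume) >= 0))
  expect_true(b$utero_cervical_angle >= 0 && b$utero_cervical_angle <= 180)
  expect_gt(b$provenance$component_voxels, 20)
  df <- as.data.frame(b)
  expect_identical(df$scan_id, "t1")
  expect_named(df, c("scan_id", "length_2pt_mm", "length_3pt_mm",
                     "int_os_diam_mm", "ext_os_diam_mm", "uca_deg",
                     "total_vol_cm3", "stroma_vol_cm3", "canal_vol_cm3",
                     "cyst_vol_cm3"))

  # errors propagate with the failing stage named
  v0 <- tiny_volume(canal = FALSE)
  expect_error(compute_biometry(v0, tiny_axis()),
               "extract_canal_centerline")
})

test_that("biometry is invariant under rigid rotation of the phantom", {
  ref <- compute_biometry(straight_phantom()$volume, straight_phantom()$axis)
  ph <- make_phantom(phantom_spec(canal_length = 32,
                                  rotation = c(30, 0, 0)))
  b <- compute_biometry(ph$volume, ph$axis)
  expect_lt(abs(b$length_2pt - ref$length_2pt), 1.6)
  expect_lt(abs(b$length_3pt - ref$length_3pt), 1.6)
  expect_lt(abs(b$internal_os_diameter - ref$internal_os_diameter), 1.6)
  expect_lt(abs(b$external_os_diameter - ref$external_os_diameter), 1.6)
  expect_lt(abs(b$utero_cervical_angle - ref$utero_cervical_angle), 2)
  expect_lt(abs(b$total_volume - ref$total_volume) / ref$total_volume, 0.02)
})

test_that("halving the voxel size does not move measurements away from truth", {
  errs <- lapply(c(0.8, 0.4), function(s) {
    ph <- make_phantom(phantom_spec(canal_length = 32,
                                    spacing = rep(s, 3)))
    b <- compute_biometry(ph$volume, ph$axis)
    gt <- ph$ground_truth
    c(l2 = abs(b$length_2pt - gt$length_2pt),
      l3 = abs(b$length_3pt - gt$length_3pt),
      di = abs(b$internal_os_diameter - gt$internal_os_diameter),
      de = abs(b$external_os_diameter - gt$external_os_diameter),
      ang = abs(b$utero_cervical_angle - gt$utero_cervical_angle),
      cv = abs(b$canal_volume - gt$canal_volume) / gt$canal_volume)
  })
  expect_true(all(errs[[2]] <= errs[[1]] + 1e-9))
})
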