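#' Specify an analytic uterocervical phantom
#'
#' A phantom is a nested-tube model of the cervix: a canal of linearly
#' tapering radius around a straight or circular-arc centerline, wrapped in
#' an inner and an outer stroma shell, with an optional intracanal cyst
#' (sphere on the centerline) and a lower-uterine reference bar (label 5)
#' attached at the internal os at a prescribed utero-cervical angle. All
#' dimensions are mm.
#'
#' @param canal_length arc length of the canal centerline (mm).
#' @param canal_radius_internal,canal_radius_external canal radius at the
#'   internal / external os (linear taper between them).
#' @param inner_stroma_thickness,outer_stroma_thickness shell thicknesses.
#' @param curvature_radius radius of the circular-arc centerline, or `NULL`
#'   for a straight canal; must exceed `canal_length / pi` (arc < half
#'   circle) and the outer tube radius.
#' @param utero_cervical_angle prescribed angle (degrees, in (0, 180))
#'   between the uterine bar and the 2-point cervical line.
#' @param cyst `NULL` or `list(arc_fraction=, radius=)`: a spherical cyst
#'   centered on the centerline at that arc fraction. The radius is capped
#'   so the sphere stays strictly inside the canal, keeping the ground
#'   truth closed-form.
#' @param spacing voxel spacing, mm triple (default 0.8 isotropic).
#' @param rotation Euler angles (degrees, about world x, y, z applied in
#'   that order) rigidly rotating the whole phantom before voxelization.
#' @param uterine_bar_length,uterine_bar_radius geometry of the label-5 bar.
#' @param seed integer recorded in the spec (generation is deterministic).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(canal_length = 32,
                         canal_radius_internal = 2,
                         canal_radius_external = 2,
                         inner_stroma_thickness = 3,
                         outer_stroma_thickness = 4,
                         curvature_radius = NULL,
                         utero_cervical_angle = 120,
                         cyst = NULL,
                         spacing = c(0.8, 0.8, 0.8),
                         rotation = c(0, 0, 0),
                         uterine_bar_length = 30,
                         uterine_bar_radius = 3,
                         seed = 1L) {
  stopifnot(canal_length > 0, canal_radius_internal > 0,
            canal_radius_external > 0, inner_stroma_thickness > 0,
            outer_stroma_thickness > 0,
            utero_cervical_angle > 0, utero_cervical_angle < 180,
            length(spacing) == 3L, all(spacing > 0))
  if (!is.null(curvature_radius)) {
    rmax <- max(canal_radius_internal, canal_radius_external) +
      inner_stroma_thickness + outer_stroma_thickness
    if (curvature_radius <= rmax)
      stop("curvature_radius must exceed the outer tube radius (", rmax, " mm)")
    if (canal_length / curvature_radius >= pi)
      stop("arc subtends >= 180 degrees; increase curvature_radius")
  }
  if (!is.null(cyst)) {
    stopifnot(is.list(cyst), !is.null(cyst$arc_fraction), !is.null(cyst$radius))
    s <- cyst$arc_fraction * canal_length
    rs <- min(canal_radius_internal, canal_radius_external) * 0.9
    rs <- min(rs, s - 0.5, canal_length - s - 0.5)
    if (rs <= 0) stop("cyst does not fit inside the canal at that position")
    cyst$radius <- min(cyst$radius, rs)
  }
  structure(list(canal_length = canal_length,
                 canal_radius_internal = canal_radius_internal,
                 canal_radius_external = canal_radius_external,
                 inner_stroma_thickness = inner_stroma_thickness,
                 outer_stroma_thickness = outer_stroma_thickness,
                 curvature_radius = curvature_radius,
                 utero_cervical_angle = utero_cervical_angle,
                 cyst = cyst, spacing = spacing, rotation = rotation,
                 uterine_bar_length = uterine_bar_length,
                 uterine_bar_radius = uterine_bar_radius,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# rotation matrix from Euler angles in degrees (Rx then Ry then Rz)
.euler_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Analytic ground-truth biometry of a phantom
#'
#' Closed forms: chord lengths of the generating arc for 2-/3-point length
#' (equal to the arc length when straight), twice the end radii for os
#' diameters, the prescribed utero-cervical angle, and exact tube-shell
#' integrals for the volumes: canal \eqn{\int_0^L \pi r(s)^2 ds} minus the
#' cyst sphere, stroma \eqn{\int_0^L \pi [(r(s)+t)^2 - r(s)^2] ds} with
#' \eqn{t} the combined shell thickness.
#'
#' @param spec a [phantom_spec()].
#' @return Named list with the `cervical_biometry` panel fields plus
#'   `arc_length`, volumes in cm3.
#' @export
phantom_ground_truth <- function(spec) {
  L <- spec$canal_length
  r1 <- spec$canal_radius_internal
  r2 <- spec$canal_radius_external
  tt <- spec$inner_stroma_thickness + spec$outer_stroma_thickness
  if (is.null(spec$curvature_radius)) {
    l2 <- L; l3 <- L
  } else {
    R <- spec$curvature_radius
    th <- L / R
    l2 <- 2 * R * sin(th / 2)
    l3 <- 4 * R * sin(th / 4)
  }
  # linear taper r(s) = r1 + (r2 - r1) s / L
  canal_mm3 <- pi * L * (r1^2 + r1 * r2 + r2^2) / 3
  # shell: integral of pi[(r+tt)^2 - r^2] = pi[2 tt r + tt^2]
  stroma_mm3 <- pi * (2 * tt * (r1 + r2) / 2 * L + tt^2 * L)
  cyst_mm3 <- 0
  if (!is.null(spec$cyst)) {
    cyst_mm3 <- 4 / 3 * pi * spec$cyst$radius^3
    canal_mm3 <- canal_mm3 - cyst_mm3
  }
  list(length_2pt = l2, length_3pt = l3, arc_length = L,
       internal_os_diameter = 2 * r1, external_os_diameter = 2 * r2,
       utero_cervical_angle = spec$utero_cervical_angle,
       canal_volume = canal_mm3 / 1000,
       stroma_volume = stroma_mm3 / 1000,
       cyst_volume = cyst_mm3 / 1000,
       total_volume = (canal_mm3 + stroma_mm3 + cyst_mm3) / 1000)
}

# analytic centerline geometry after rotation: returns functions/points in
# world space plus the frame used for voxelization
.phantom_geometry <- function(spec) {
  Rm <- .euler_matrix(spec$rotation)
  L <- spec$canal_length
  if (is.null(spec$curvature_radius)) {
    p_int <- c(0, 0, 0)
    dirz <- c(0, 0, 1)
    p_ext <- p_int + L * dirz
    geom <- list(type = "straight", p0 = Rm %*% p_int, u = Rm %*% dirz)
    plane_perp <- c(0, 1, 0)  # in-plane normal used to place the bar
  } else {
    R <- spec$curvature_radius
    th <- L / R
    # arc in the y-z plane, internal os at origin, initial tangent +z,
    # curving towards +y: P(t) = C + R(sin(t) e_z + (1-cos(t)) e_y)... with
    # center at (0, R, 0)
    C <- c(0, R, 0)
    p_int <- c(0, 0, 0)
    p_ext <- C + R * c(0, -cos(th), sin(th))
    geom <- list(type = "arc", C = Rm %*% C,
                 e1 = Rm %*% c(0, -1, 0),   # direction C -> internal os
                 e2 = Rm %*% c(0, 0, 1),    # tangent at internal os
                 e3 = Rm %*% c(1, 0, 0), R = R, theta = th)
    plane_perp <- c(0, 1, 0)
  }
  p_int_w <- as.vector(Rm %*% p_int)
  p_ext_w <- as.vector(Rm %*% p_ext)
  # uterine bar: in the pre-rotation frame, from the internal os at the
  # prescribed angle to the 2-point line, tilted within the curvature plane
  d2 <- (p_ext - p_int); d2 <- d2 / sqrt(sum(d2^2))
  perp <- plane_perp - sum(plane_perp * d2) * d2
  perp <- perp / sqrt(sum(perp^2))
  a <- spec$utero_cervical_angle * pi / 180
  u_bar <- cos(a) * d2 + sin(a) * perp
  bar_a <- p_int
  bar_b <- p_int + spec$uterine_bar_length * u_bar
  list(geom = geom, p_int = p_int_w, p_ext = p_ext_w,
       bar_a = as.vector(Rm %*% bar_a), bar_b = as.vector(Rm %*% bar_b))
}

#' Voxelize a phantom
#'
#' Voxelization is by signed-distance evaluation at voxel centers: a voxel
#' belongs to a compartment if its center's distance to the centerline at
#' the corresponding arc parameter falls inside that compartment's radial
#' band, with flat end caps (arc parameter clamped to \[0, L\]). The grid is
#' axis-aligned, padded 5 voxels beyond the phantom extent, with the affine
#' `diag(spacing)` anchored at the padded corner.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [label_volume()]), `ground_truth`
#'   ([phantom_ground_truth()]), and `axis` (a [uterine_axis()] along the
#'   uterine bar, `point_a` at the internal os).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_geometry(spec)
  L <- spec$canal_length
  r1 <- spec$canal_radius_internal
  r2 <- spec$canal_radius_external
  ti <- spec$inner_stroma_thickness
  to <- spec$outer_stroma_thickness
  r_out <- max(r1, r2) + ti + to
  sp <- spec$spacing

  # bounding box from sampled centerline, tube radius and the bar
  ts <- seq(0, 1, length.out = 65)
  cl_pts <- t(vapply(ts * L, function(s) .phantom_point(g$geom, s),
                     numeric(3)))
  box_pts <- rbind(cl_pts, g$bar_a, g$bar_b)
  lo <- apply(box_pts, 2, min) - max(r_out, spec$uterine_bar_radius)
  hi <- apply(box_pts, 2, max) + max(r_out, spec$uterine_bar_radius)
  lo <- lo - 5 * sp; hi <- hi + 5 * sp
  dims <- pmax(ceiling((hi - lo) / sp) + 1L, 8L)
  if (prod(dims) > 3e7) stop("phantom exceeds the requested grid budget")
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(sp)
  affine[1:3, 4] <- lo

  xs <- lo[1] + sp[1] * (seq_len(dims[1]) - 1L)
  ys <- lo[2] + sp[2] * (seq_len(dims[2]) - 1L)
  zs <- lo[3] + sp[3] * (seq_len(dims[3]) - 1L)
  # voxel-center coordinates, column-major order
  X <- rep(xs, times = dims[2] * dims[3])
  Y <- rep(rep(ys, each = dims[1]), times = dims[3])
  Z <- rep(zs, each = dims[1] * dims[2])

  sd <- .centerline_distance(g$geom, X, Y, Z, L)
  s <- sd$s; dist <- sd$dist; inside_caps <- sd$inside
  r_canal <- r1 + (r2 - r1) * s / L
  lab <- integer(length(X))
  in_outer <- inside_caps & dist <= r_canal + ti + to
  in_inner <- inside_caps & dist <= r_canal + ti
  in_canal <- inside_caps & dist <= r_canal
  lab[in_outer] <- 1L
  lab[in_inner] <- 2L
  lab[in_canal] <- 3L
  if (!is.null(spec$cyst)) {
    cc <- .phantom_point(g$geom, spec$cyst$arc_fraction * L)
    d2c <- (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2
    lab[d2c <= spec$cyst$radius^2 & lab == 3L] <- 4L
  }
  # uterine bar: capsule around segment bar_a -> bar_b, not overwriting cervix
  ba <- g$bar_a; bb <- g$bar_b
  u <- bb - ba; ul <- sqrt(sum(u^2)); u <- u / ul
  t_par <- (X - ba[1]) * u[1] + (Y - ba[2]) * u[2] + (Z - ba[3]) * u[3]
  t_cl <- pmax(0, pmin(t_par, ul))
  dbar2 <- (X - (ba[1] + t_cl * u[1]))^2 + (Y - (ba[2] + t_cl * u[2]))^2 +
    (Z - (ba[3] + t_cl * u[3]))^2
  lab[dbar2 <= spec$uterine_bar_radius^2 & lab == 0L] <- 5L

  vol <- label_volume(array(lab, dim = dims), affine)
  list(volume = vol,
       ground_truth = phantom_ground_truth(spec),
       axis = uterine_axis(g$bar_a, g$bar_b, source = "phantom"))
}

# point on the generating curve at arc length s
.phantom_point <- function(geom, s) {
  if (geom$type == "straight") {
    as.vector(geom$p0 + s * geom$u)
  } else {
    th <- s / geom$R
    as.vector(geom$C + geom$R * (cos(th) * geom$e1 + sin(th) * geom$e2))
  }
}

# distance from points to the curve and their arc parameter; `inside` is
# TRUE where the unclamped parameter lies in [0, L] (flat end caps)
.centerline_distance <- function(geom, X, Y, Z, L) {
  if (geom$type == "straight") {
    p0 <- as.vector(geom$p0); u <- as.vector(geom$u)
    s <- (X - p0[1]) * u[1] + (Y - p0[2]) * u[2] + (Z - p0[3]) * u[3]
    px <- X - p0[1] - s * u[1]
    py <- Y - p0[2] - s * u[2]
    pz <- Z - p0[3] - s * u[3]
    dist <- sqrt(px^2 + py^2 + pz^2)
    list(s = pmax(0, pmin(s, L)), dist = dist, inside = s >= 0 & s <= L)
  } else {
    C <- as.vector(geom$C)
    e1 <- as.vector(geom$e1); e2 <- as.vector(geom$e2)
    e3 <- as.vector(geom$e3); R <- geom$R; th_max <- geom$theta
    qx <- X - C[1]; qy <- Y - C[2]; qz <- Z - C[3]
    a1 <- qx * e1[1] + qy * e1[2] + qz * e1[3]
    a2 <- qx * e2[1] + qy * e2[2] + qz * e2[3]
    h <- qx * e3[1] + qy * e3[2] + qz * e3[3]
    th <- atan2(a2, a1)  # internal os at theta = 0 along e1
    rho <- sqrt(a1^2 + a2^2)
    dist <- sqrt((rho - R)^2 + h^2)
    inside <- th >= 0 & th <= th_max
    list(s = pmax(0, pmin(th, th_max)) * R, dist = dist, inside = inside)
  }
}
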