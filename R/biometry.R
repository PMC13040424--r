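#' Two- and three-point cervical length
#'
#' The 2-point length is the straight internal-to-external os distance; the
#' 3-point length sums the two straight segments through the canal midpoint,
#' approximating canal curvature.
#'
#' @param lm an `os_landmarks` object from [locate_os_landmarks()].
#' @return Named numeric vector `c(length_2pt, length_3pt)` in mm.
#' @export
cervical_length <- function(lm) {
  stopifnot(inherits(lm, "os_landmarks"))
  d <- function(a, b) sqrt(sum((a - b)^2))
  c(length_2pt = d(lm$internal_os, lm$external_os),
    length_3pt = d(lm$internal_os, lm$canal_mid) +
                 d(lm$canal_mid, lm$external_os))
}

#' Os diameter from an orthogonal cross-section
#'
#' At the centerline point one voxel-diagonal inward from the chosen
#' endpoint, the canal-plus-cyst voxels are intersected with a slab one
#' voxel thick orthogonal to the local centerline tangent. The diameter is
#' the maximum Feret diameter (largest pairwise world distance) of the
#' cross-section's voxel centers plus one mean voxel size, accounting for
#' the half-voxel extent of boundary voxels on each side; 0 if the slab is
#' empty.
#'
#' @param vol a [label_volume()].
#' @param cl a `centerline`.
#' @param which `"internal"` or `"external"`.
#' @return Diameter in mm.
#' @export
os_diameter <- function(vol, cl, which = c("internal", "external")) {
  which <- match.arg(which)
  stopifnot(inherits(vol, "label_volume"), inherits(cl, "centerline"))
  pts <- cl$points
  L <- cl$arc_length
  diag_mm <- sqrt(sum(vol$spacing^2))
  s <- if (which == "internal") min(diag_mm, L / 2) else max(L - diag_mm, L / 2)
  q <- .point_at_arc(pts, s)
  tg <- .tangent_at_arc(pts, s)

  idx <- which(vol$voxels == 3L | vol$voxels == 4L)
  if (!length(idx)) return(0)
  xyz <- voxel_world_coords(vol, idx)
  slab <- mean(vol$spacing)
  rel <- sweep(xyz, 2, q)
  along <- as.vector(rel %*% tg)
  # guard against a curved canal re-crossing the section plane far away
  near <- rowSums(rel^2) <= (L / 2)^2
  sel <- abs(along) <= slab / 2 & near
  if (!any(sel)) return(0)
  # project onto the orthogonal plane so slab thickness does not inflate
  # the pairwise distances
  sec <- rel[sel, , drop = FALSE] - outer(along[sel], tg)
  .max_feret(sec) + mean(vol$spacing)
}

# maximum pairwise distance; O(n^2) on the slab's few hundred voxels
.max_feret <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  dd <- dist(pts)
  max(dd)
}

#' Utero-cervical angle
#'
#' The angle at the internal os between the lower-uterine-segment direction
#' (the reference axis direction oriented away from the cervix, `point_b -
#' point_a`) and the straight cervical line (internal to external os),
#' reported in degrees in \[0, 180\].
#'
#' @param lm an `os_landmarks` object.
#' @param axis a [uterine_axis()].
#' @return Angle in degrees.
#' @export
utero_cervical_angle <- function(lm, axis) {
  stopifnot(inherits(lm, "os_landmarks"), inherits(axis, "uterine_axis"))
  u <- axis$point_b - axis$point_a
  v <- lm$external_os - lm$internal_os
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("zero-length vector in utero-cervical angle")
  ct <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Compartment volumes from voxel counts
#'
#' Volume of a label set is its voxel count times the voxel volume (the
#' absolute determinant of the affine's 3x3 block), in cm3. Stroma combines
#' the outer and inner layers (labels 1, 2); the uterine reference region
#' (label 5) is excluded from all cervical volumes.
#'
#' @param vol a [label_volume()].
#' @return Named numeric vector `c(total, stroma, canal, cyst)` in cm3,
#'   with `total = stroma + canal + cyst` exact in voxel counts.
#' @export
compartment_volumes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  vox_mm3 <- abs(det(vol$affine[1:3, 1:3]))
  cnt <- tabulate(vol$voxels + 1L, nbins = 6L)  # labels 0..5
  stroma <- cnt[2] + cnt[3]
  canal <- cnt[4]
  cyst <- cnt[5]
  c(total = (stroma + canal + cyst) * vox_mm3 / 1000,
    stroma = stroma * vox_mm3 / 1000,
    canal = canal * vox_mm3 / 1000,
    cyst = cyst * vox_mm3 / 1000)
}

#' Compute the full cervical biometry panel
#'
#' Orchestrates centerline extraction, os landmark localisation, 2-/3-point
#' cervical length, os diameters, utero-cervical angle and compartment
#' volumes for one scan.
#'
#' @param vol a [label_volume()].
#' @param axis a [uterine_axis()] (see [load_uterine_axis()]).
#' @param scan_id optional identifier carried into the output.
#' @param ... passed to [extract_canal_centerline()].
#' @return Object of class `cervical_biometry`: the measurement panel
#'   (`length_2pt`, `length_3pt`, `internal_os_diameter`,
#'   `external_os_diameter`, `utero_cervical_angle`, `total_volume`,
#'   `stroma_volume`, `canal_volume`, `cyst_volume`) plus `provenance`.
#' @export
compute_biometry <- function(vol, axis, scan_id = NULL, ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cl <- stage("extract_canal_centerline",
              extract_canal_centerline(vol, axis, ...))
  lm <- stage("locate_os_landmarks", locate_os_landmarks(cl))
  len <- stage("cervical_length", cervical_length(lm))
  di <- stage("os_diameter", os_diameter(vol, cl, "internal"))
  de <- stage("os_diameter", os_diameter(vol, cl, "external"))
  uca <- stage("utero_cervical_angle", utero_cervical_angle(lm, axis))
  vols <- stage("compartment_volumes", compartment_volumes(vol))
  structure(list(
    scan_id = scan_id,
    length_2pt = unname(len["length_2pt"]),
    length_3pt = unname(len["length_3pt"]),
    internal_os_diameter = di,
    external_os_diameter = de,
    utero_cervical_angle = uca,
    total_volume = unname(vols["total"]),
    stroma_volume = unname(vols["stroma"]),
    canal_volume = unname(vols["canal"]),
    cyst_volume = unname(vols["cyst"]),
    arc_length = cl$arc_length,
    provenance = c(cl$provenance, list(n_centerline_points = nrow(cl$points)))),
    class = "cervical_biometry")
}

#' @export
print.cervical_biometry <- function(x, ...) {
  cat("Cervical biometry", if (!is.null(x$scan_id)) paste0("[", x$scan_id, "]"),
      "\n")
  cat(sprintf("  cervical length : %.1f mm (2-point), %.1f mm (3-point)\n",
              x$length_2pt, x$length_3pt))
  cat(sprintf("  os diameters    : internal %.1f mm, external %.1f mm\n",
              x$internal_os_diameter, x$external_os_diameter))
  cat(sprintf("  utero-cervical angle: %.1f deg\n", x$utero_cervical_angle))
  cat(sprintf("  volumes (cm3)   : total %.2f = stroma %.2f + canal %.2f + cyst %.2f\n",
              x$total_volume, x$stroma_volume, x$canal_volume, x$cyst_volume))
  invisible(x)
}

#' One-row data frame of a biometry panel
#'
#' @param x a `cervical_biometry`.
#' @param ... unused.
#' @return Data frame with the CSV column scheme used by [run_measure()].
#' @export
as.data.frame.cervical_biometry <- function(x, ...) {
  data.frame(scan_id = if (is.null(x$scan_id)) NA_character_ else x$scan_id,
             length_2pt_mm = x$length_2pt,
             length_3pt_mm = x$length_3pt,
             int_os_diam_mm = x$internal_os_diameter,
             ext_os_diam_mm = x$external_os_diameter,
             uca_deg = x$utero_cervical_angle,
             total_vol_cm3 = x$total_volume,
             stroma_vol_cm3 = x$stroma_volume,
             canal_vol_cm3 = x$canal_volume,
             cyst_vol_cm3 = x$cyst_volume,
             stringsAsFactors = FALSE)
}
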