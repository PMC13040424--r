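#' @useDynLib cervimorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile qf qlogis plogis rnorm runif rbinom
#'   shapiro.test lm glm binomial coef confint vcov pnorm qnorm
#'   as.formula model.matrix setNames dist complete.cases p.adjust
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Allowed voxel labels and their meanings
#'
#' The label scheme used throughout the package: 0 background, 1 outer
#' stroma, 2 inner stroma, 3 cervical canal, 4 canal cyst, 5 lower-uterine
#' reference region. The integers mirror the conventional colour legend of
#' uterocervical segmentation protocols (outer stroma / inner stroma /
#' canal, plus cysts if present); label 5 is a package extension housing an
#' optional segmented reference region for the utero-cervical angle.
#'
#' @format Named integer vector.
#' @export
CERVIX_LABELS <- c(background = 0L, outer_stroma = 1L, inner_stroma = 2L,
                   canal = 3L, cyst = 4L, uterine_ref = 5L)

#' Construct a label volume
#'
#' A `label_volume` is a 3D integer voxel grid together with a 4x4
#' voxel-to-world affine (mm, RAS). Voxel indices are 0-based and a voxel's
#' world position is the affine image of its integer index (voxel-center
#' convention). Spacing is derived from the affine column norms.
#'
#' @param voxels 3D integer array; values must be in `CERVIX_LABELS`.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param check_adjacency if `TRUE`, warn when canal (3) or cyst (4)
#'   components are not 6-adjacent to inner stroma (2).
#' @return An object of class `label_volume` with fields `voxels`, `affine`,
#'   `spacing` and `labels` (sorted labels present).
#' @export
label_volume <- function(voxels, affine, check_adjacency = FALSE) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  storage.mode(voxels) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine is not invertible")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("spacing derived from affine must be strictly positive")
  labs <- sort(unique(as.vector(voxels)))
  bad <- setdiff(labs, unname(CERVIX_LABELS))
  if (length(bad))
    stop("disallowed label value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CERVIX_LABELS, collapse = ", "), ")")
  vol <- structure(list(voxels = voxels, affine = affine,
                        spacing = unname(spacing), labels = labs),
                   class = "label_volume")
  if (check_adjacency) .check_canal_adjacency(vol)
  vol
}

# canal/cyst components should touch inner stroma under 6-connectivity;
# a violation is suspicious segmentation, not a fatal error
.check_canal_adjacency <- function(vol) {
  v <- vol$voxels
  for (lab in c(3L, 4L)) {
    if (!lab %in% vol$labels) next
    m <- v == lab
    touch <- .shift_or(v == 2L)
    if (!any(m & touch))
      warning(sprintf(
        "label %d voxels are not 6-adjacent to inner stroma (label 2)", lab))
  }
  invisible(NULL)
}

# dilation of a logical array by the 6-neighbourhood
.shift_or <- function(m) {
  d <- dim(m)
  out <- m
  idx <- function(n, off) pmax(pmin(seq_len(n) + off, n), 1L)
  out <- out | m[idx(d[1], 1L), , ] | m[idx(d[1], -1L), , ]
  out <- out | m[, idx(d[2], 1L), ] | m[, idx(d[2], -1L), ]
  out <- out | m[, , idx(d[3], 1L)] | m[, , idx(d[3], -1L)]
  out
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Cervical label volume\n")
  cat("  dims   :", paste(dim(x$voxels), collapse = " x "), "voxels\n")
  cat("  spacing:", paste(sprintf("%.3f", x$spacing), collapse = " x "),
      "mm\n")
  cat("  labels :", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a label volume from a NIfTI file
#'
#' @param path path to a NIfTI-1/2 file with integer-valued data.
#' @param check_adjacency passed to [label_volume()].
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, check_adjacency = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim = dim(dat)[1:3])
  if (length(dim(dat)) != 3L)
    stop("expected a 3D volume, got dims ", paste(dim(dat), collapse = "x"))
  r <- round(dat)
  if (max(abs(dat - r)) > 1e-6)
    stop("volume data are not integer-valued (max deviation ",
         format(max(abs(dat - r))), ")")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  label_volume(array(as.integer(r), dim = dim(dat)), aff,
               check_adjacency = check_adjacency)
}

#' Write a label volume to a NIfTI file
#'
#' The written file re-reads voxel-for-voxel identically, with the affine
#' preserved to well below 1e-6 mm.
#'
#' @param vol a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' World coordinates of voxel centers
#'
#' @param vol a [label_volume()].
#' @param which_voxels linear (1-based, column-major) indices into the voxel
#'   array; default all voxels.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_world_coords <- function(vol, which_voxels = NULL) {
  d <- dim(vol$voxels)
  if (is.null(which_voxels)) which_voxels <- seq_len(prod(d))
  ijk <- arrayInd(which_voxels, d) - 1L
  xyz <- cbind(ijk, 1) %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Construct a uterine reference axis
#'
#' @param point_a,point_b distinct finite world-mm coordinates; `point_a` is
#'   the end nearer the cervix (internal os side).
#' @param source provenance tag, one of `"sidecar"`, `"label5-fit"`,
#'   `"phantom"`.
#' @return An object of class `uterine_axis`.
#' @export
uterine_axis <- function(point_a, point_b, source = "sidecar") {
  point_a <- as.numeric(point_a); point_b <- as.numeric(point_b)
  if (length(point_a) != 3L || length(point_b) != 3L)
    stop("axis points must be length-3 world coordinates")
  if (!all(is.finite(c(point_a, point_b))))
    stop("axis points must be finite")
  if (sqrt(sum((point_a - point_b)^2)) < 1e-9)
    stop("axis points must be distinct")
  structure(list(point_a = point_a, point_b = point_b, source = source),
            class = "uterine_axis")
}

#' Load the lower-uterine-segment reference axis
#'
#' The utero-cervical angle needs a reference line for the lower uterine
#' segment. Two sources are accepted, in order of precedence: a JSON sidecar
#' of the form `{"uterine_axis": {"a": [x,y,z], "b": [x,y,z], "units":
#' "mm"}}`, or a segmented reference region (label 5) in the volume, whose
#' first principal axis is used. When fitted from label 5, the axis is
#' oriented so `point_a` is the end nearer the canal's internal-os end.
#'
#' @param vol a [label_volume()].
#' @param sidecar optional path to a JSON sidecar.
#' @return A [uterine_axis()].
#' @export
load_uterine_axis <- function(vol, sidecar = NULL) {
  if (!is.null(sidecar) && file.exists(sidecar)) {
    j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ax <- j[["uterine_axis"]]
    if (is.null(ax) || is.null(ax$a) || is.null(ax$b))
      stop("sidecar ", sidecar, " lacks uterine_axis: {a, b}")
    return(uterine_axis(ax$a, ax$b, source = "sidecar"))
  }
  if (5L %in% vol$labels) {
    idx <- which(vol$voxels == 5L)
    xyz <- voxel_world_coords(vol, idx)
    ctr <- colMeans(xyz)
    cen <- sweep(xyz, 2, ctr)
    ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
    u <- ev$vectors[, 1]
    s <- cen %*% u
    a <- ctr + u * min(s)
    b <- ctr + u * max(s)
    # orient point_a towards the canal if one is present
    if (3L %in% vol$labels) {
      canal <- colMeans(voxel_world_coords(vol, which(vol$voxels == 3L)))
      if (sum((b - canal)^2) < sum((a - canal)^2)) { tmp <- a; a <- b; b <- tmp }
    }
    return(uterine_axis(a, b, source = "label5-fit"))
  }
  stop("no uterine reference available: supply a JSON sidecar with ",
       "uterine_axis {a, b} or segment a reference region as label 5")
}

#' Write a uterine-axis JSON sidecar
#'
#' @param axis a [uterine_axis()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_uterine_axis <- function(axis, path) {
  jsonlite::write_json(
    list(uterine_axis = list(a = axis$point_a, b = axis$point_b,
                             units = "mm")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scan quality records
#'
#' Quality records carry two 1-4 ordinal grades per scan: a reconstruction
#' grade (1 = failed, 2 = poor, 3 = acceptable, 4 = good) and a segmentation
#' grade (1 = poor, 2 = moderate, 3 = good, 4 = excellent). Grade 1 marks
#' exclusion from analysis.
#'
#' @param path CSV with columns `scan_id`, `recon_grade`, `seg_grade`.
#' @return A data frame of validated records.
#' @export
read_quality_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  q <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "recon_grade", "seg_grade")
  miss <- setdiff(need, names(q))
  if (length(miss))
    stop("quality CSV missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("recon_grade", "seg_grade")) {
    g <- q[[col]]
    if (any(!g %in% 1:4))
      stop(col, " must be integer grades 1-4")
  }
  q
}

#' Summarise scan quality records
#'
#' @param records data frame from [read_quality_records()].
#' @return List with the fraction of successful reconstructions (grade > 1),
#'   the fraction of good/acceptable reconstructions among successes
#'   (grade >= 3), the fraction of excellent/good segmentations among
#'   successes, and the grade tables.
#' @export
quality_summary <- function(records) {
  ok <- records$recon_grade > 1L
  list(
    n = nrow(records),
    recon_success_frac = mean(ok),
    recon_good_frac = if (any(ok)) mean(records$recon_grade[ok] >= 3L) else NA_real_,
    seg_good_frac = if (any(ok)) mean(records$seg_grade[ok] >= 3L) else NA_real_,
    recon_table = table(factor(records$recon_grade, levels = 1:4)),
    seg_table = table(factor(records$seg_grade, levels = 1:4)))
}
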