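#' Extract the cervical canal centerline
#'
#' Finds the largest 26-connected component of the canal-plus-cyst region
#' (labels 3 and 4) and traces a medial path through it: a Euclidean
#' distance transform is computed inside the component, and a
#' distance-penalized geodesic (double Dijkstra, edge cost inflated away
#' from the medial ridge) yields the longest centered path — the standard
#' skeleton-free centerline construction for tubular organs. The voxel path
#' is smoothed with a 5-point moving average (edge-truncated windows) and
#' each end is extended by half the mean voxel size along the end tangent,
#' compensating for geodesic endpoints sitting at voxel centers inside the
#' end caps. The endpoint nearer `axis$point_a` (the uterine end of the
#' reference line) is designated the internal os and ordered first.
#'
#' @param vol a [label_volume()] containing canal voxels (label 3).
#' @param axis a [uterine_axis()] used to orient internal vs external os.
#' @param min_voxels minimum size of the canal component (default 20).
#' @param smooth_window moving-average window in points (default 5).
#' @param alpha medial-penalty strength for the geodesic (default 10).
#' @return An object of class `centerline`: `points` (n x 3 world mm,
#'   internal os first), `arc_length` (mm), and `provenance` (component
#'   voxel counts).
#' @export
extract_canal_centerline <- function(vol, axis, min_voxels = 20L,
                                     smooth_window = 5L, alpha = 10) {
  stopifnot(inherits(vol, "label_volume"), inherits(axis, "uterine_axis"))
  d <- dim(vol$voxels)
  mask <- vol$voxels == 3L | vol$voxels == 4L
  if (!any(vol$voxels == 3L))
    stop("no canal voxels (label 3) present")
  comp <- cpp_label_components(as.logical(mask), d)
  ncomp <- attr(comp, "n_components")
  sizes <- tabulate(comp, nbins = ncomp)
  big <- which.max(sizes)  # ties: lowest component id = lowest voxel index
  if (sizes[big] < min_voxels)
    stop(sprintf("canal too small: largest canal component has %d voxels (< %d)",
                 sizes[big], min_voxels))
  cm <- comp == big
  dt <- cpp_edt(cm, d, vol$spacing)

  src <- which.max(ifelse(cm, dt, -Inf)) - 1L
  g1 <- cpp_penalized_geodesic(cm, dt, d, vol$spacing, src, alpha)
  g2 <- cpp_penalized_geodesic(cm, dt, d, vol$spacing, g1$farthest, alpha)

  pts <- voxel_world_coords(vol, g2$path + 1L)
  if (nrow(pts) < 3L)
    stop("canal too small: centerline has fewer than 3 points")
  comp_xyz <- voxel_world_coords(vol, which(cm))
  dtmax <- max(dt[cm])
  vox <- mean(vol$spacing)
  pts <- .moving_average_path(pts, smooth_window)
  # two interior recentering passes (tangents clean away from the ends),
  # then rebuild the end runs: the raw geodesic terminates on cap corners,
  # so the last ~dtmax of path is discarded and re-grown by marching slab
  # centroids along the interior tangent out to the cap
  for (pass in 1:2) {
    pts <- .recenter_path(pts, comp_xyz, vox, dtmax)
    pts <- .dedupe_path(pts)
    pts <- .moving_average_path(pts, smooth_window)
    pts <- .dedupe_path(pts)
  }
  pts <- .rebuild_path_ends(pts, comp_xyz, vox, dtmax)
  pts <- .dedupe_path(pts)
  pts <- .moving_average_path(pts, smooth_window)
  pts <- .extend_path_ends(pts, vox / 2)
  pts <- .dedupe_path(pts)

  # orient: internal os end is nearer the uterine end of the reference axis
  d_first <- sum((pts[1, ] - axis$point_a)^2)
  d_last <- sum((pts[nrow(pts), ] - axis$point_a)^2)
  if (d_last < d_first) pts <- pts[nrow(pts):1, , drop = FALSE]

  new_centerline(pts, provenance = list(
    n_components = ncomp, component_voxels = sizes[big],
    n_path_voxels = length(g2$path)))
}

#' Construct a centerline from an ordered point matrix
#'
#' @param points n x 3 matrix of world mm coordinates, internal os first.
#' @param provenance optional list of extraction metadata.
#' @return Object of class `centerline`.
#' @export
new_centerline <- function(points, provenance = list()) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L)
    stop("centerline needs >= 3 points in 3D")
  gaps <- sqrt(rowSums(diff(points)^2))
  if (any(gaps < 1e-12))
    stop("consecutive centerline points must be distinct")
  structure(list(points = points, arc_length = sum(gaps),
                 provenance = provenance),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("Canal centerline: %d points, arc length %.2f mm\n",
              nrow(x$points), x$arc_length))
  invisible(x)
}

# recenter each path point to the centroid of the component voxels in the
# 1-voxel slab orthogonal to the local tangent — removes the corner bias of
# geodesic endpoints and residual staircase wiggle
.recenter_path <- function(pts, comp_xyz, vox, dtmax) {
  n <- nrow(pts)
  cs <- .cum_arc(pts)
  L <- cs[length(cs)]
  # the radial guard only needs to exclude slab hits from a re-crossing of
  # a strongly curved canal; it must comfortably exceed the widest local
  # cross-section (~2 * dtmax from the slab point)
  guard2 <- (max(3 * dtmax, 6 * vox))^2
  margin <- min(max(dtmax, 2 * vox), L / 4)
  out <- pts
  for (i in seq_len(n)) {
    if (cs[i] < margin || cs[i] > L - margin) next  # ends rebuilt separately
    tg <- tryCatch(.tangent_at_arc(pts, cs[i], h = 2.5 * vox),
                   error = function(e) NULL)
    if (is.null(tg)) next
    rel <- sweep(comp_xyz, 2, pts[i, ])
    along <- as.vector(rel %*% tg)
    sel <- abs(along) <= vox / 2 & rowSums(rel^2) <= guard2
    if (sum(sel) >= 1L)
      out[i, ] <- colMeans(comp_xyz[sel, , drop = FALSE])
  }
  out
}

# discard the path's end runs (length ~dtmax, where the geodesic hugged a
# cap corner) and re-grow each end by marching perpendicular-slab centroids
# along the interior tangent until the slab leaves the component
.rebuild_path_ends <- function(pts, comp_xyz, vox, dtmax) {
  cs <- .cum_arc(pts)
  L <- cs[length(cs)]
  # the corner-seeking run can extend ~2*dtmax along the path
  margin <- min(max(2 * dtmax, 3 * vox), L / 3)
  keep <- cs >= margin & cs <= L - margin
  if (sum(keep) >= 3L) pts <- pts[keep, , drop = FALSE]
  pts <- .march_end(pts, comp_xyz, vox, dtmax, margin, forward = TRUE)
  pts <- .march_end(pts, comp_xyz, vox, dtmax, margin, forward = FALSE)
  pts
}

.march_end <- function(pts, comp_xyz, vox, dtmax, margin, forward) {
  if (!forward) pts <- pts[nrow(pts):1, , drop = FALSE]
  n <- nrow(pts)
  guard2 <- (max(3 * dtmax, 6 * vox))^2
  p <- pts[n, ]
  trail <- pts[max(1L, n - 4L):n, , drop = FALSE]
  tg0 <- p - trail[1, ]
  if (sqrt(sum(tg0^2)) < 1e-9)
    return(if (forward) pts else pts[nrow(pts):1, , drop = FALSE])
  tg_prev <- tg0 / sqrt(sum(tg0^2))
  added <- list()
  # the march only has to re-cover the trimmed margin (plus cap slack)
  n_steps <- ceiling((margin + 2 * vox) / (vox / 2))
  max_turn <- 4 * pi / 180  # per half-voxel step; floor on turning radius
  for (step in seq_len(n_steps)) {
    # tangent re-estimated from the trailing window so the march follows
    # a curved canal instead of extrapolating a straight line; the turn
    # per step is clamped so slab jitter cannot fold the march back
    tg <- p - trail[1, ]
    nt <- sqrt(sum(tg^2))
    if (nt < 1e-9) break
    tg <- tg / nt
    ang <- acos(max(-1, min(1, sum(tg * tg_prev))))
    if (ang > max_turn) {
      ax <- tg - sum(tg * tg_prev) * tg_prev
      nax <- sqrt(sum(ax^2))
      if (nax > 1e-12) {
        ax <- ax / nax
        tg <- cos(max_turn) * tg_prev + sin(max_turn) * ax
      } else tg <- tg_prev
    }
    tg_prev <- tg
    q <- p + (vox / 2) * tg
    rel <- sweep(comp_xyz, 2, q)
    along <- as.vector(rel %*% tg)
    near <- rowSums(rel^2) <= guard2
    # cap reached: no component material ahead of the probe
    if (!any(near) || max(along[near]) < vox / 2) break
    sel <- abs(along) <= vox / 2 & near
    if (!any(sel)) break
    # the probe must remain inside the voxelized component
    if (min(rowSums(rel[sel, , drop = FALSE]^2)) > (0.87 * vox)^2) break
    cen <- colMeans(comp_xyz[sel, , drop = FALSE])
    # keep q's along-tangent progress, adopt the centroid's cross-plane
    # position, so the march cannot stall or run backwards
    p <- q + (cen - q) - sum((cen - q) * tg) * tg
    added[[length(added) + 1L]] <- p
    trail <- rbind(trail[-1, , drop = FALSE], p)
  }
  # the last slabs near the cap are partially cut by the cap plane and
  # their centroids laterally biased; replace that final stretch with a
  # straight continuation of the clean path behind it
  k <- length(added)
  if (k >= 3L) {
    drop_n <- min(4L, k - 1L)
    base_i <- k - drop_n
    base <- added[[base_i]]
    anchor <- if (base_i > 4L) added[[base_i - 4L]] else pts[n, ]
    tgf <- base - anchor
    ntf <- sqrt(sum(tgf^2))
    if (ntf > 1e-9) {
      tgf <- tgf / ntf
      for (j in seq_len(drop_n))
        added[[base_i + j]] <- base + j * (vox / 2) * tgf
    }
  }
  if (length(added))
    pts <- rbind(pts, do.call(rbind, added))
  if (forward) pts else pts[nrow(pts):1, , drop = FALSE]
}

# moving average with edge-truncated windows so the ends are not pulled in
.moving_average_path <- function(pts, w) {
  n <- nrow(pts)
  if (w <= 1L || n <= 2L) return(pts)
  h <- w %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    # symmetric window, shrinking near the ends so endpoints stay anchored
    m <- min(h, i - 1L, n - i)
    out[i, ] <- colMeans(pts[(i - m):(i + m), , drop = FALSE])
  }
  out
}

.extend_path_ends <- function(pts, by) {
  n <- nrow(pts)
  cs <- .cum_arc(pts)
  L <- cs[n]
  # tangent over a ~4*by baseline: a single-segment direction is too noisy
  h <- min(4 * by, L / 3)
  i1 <- max(which(cs <= h)); i2 <- min(which(cs >= L - h))
  t1 <- pts[1, ] - pts[max(i1, 2L), ]
  t2 <- pts[n, ] - pts[min(i2, n - 1L), ]
  n1 <- sqrt(sum(t1^2)); n2 <- sqrt(sum(t2^2))
  if (n1 > 1e-9) pts[1, ] <- pts[1, ] + t1 / n1 * by
  if (n2 > 1e-9) pts[n, ] <- pts[n, ] + t2 / n2 * by
  pts
}

.dedupe_path <- function(pts, tol = 1e-9) {
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > tol)
  pts[keep, , drop = FALSE]
}

# cumulative arc length along a polyline, starting at 0
.cum_arc <- function(pts) {
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# point interpolated at arc-length s along the polyline
.point_at_arc <- function(pts, s) {
  cs <- .cum_arc(pts)
  s <- max(0, min(s, cs[length(cs)]))
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  if (i >= nrow(pts)) return(pts[nrow(pts), ])
  f <- (s - cs[i]) / (cs[i + 1] - cs[i])
  pts[i, ] * (1 - f) + pts[i + 1, ] * f
}

# unit tangent of the polyline at arc-length s (central difference over
# a small arc window)
.tangent_at_arc <- function(pts, s, h = NULL) {
  cs <- .cum_arc(pts)
  L <- cs[length(cs)]
  if (is.null(h)) h <- max(L / 50, 1e-6)
  p1 <- .point_at_arc(pts, max(0, s - h))
  p2 <- .point_at_arc(pts, min(L, s + h))
  t <- p2 - p1
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12) stop("degenerate tangent")
  t / nt
}

#' Locate os landmarks on a centerline
#'
#' @param cl a `centerline` (internal os first).
#' @return Object of class `os_landmarks` with `internal_os`, `external_os`
#'   and `canal_mid` (the interpolated point at half arc length), all world
#'   mm.
#' @export
locate_os_landmarks <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  pts <- cl$points
  structure(list(internal_os = pts[1, ],
                 external_os = pts[nrow(pts), ],
                 canal_mid = .point_at_arc(pts, cl$arc_length / 2)),
            class = "os_landmarks")
}
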