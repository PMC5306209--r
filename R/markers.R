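# Scalar left-atrial shape markers.  All marker definitions assume the
# patient-axis convention x = LR, y = AP, z = FH (mm).  The vertical-asymmetry
# marker is the signed sum, over mirrored slice pairs about the centroid
# height, of the difference in anterior-posterior extent between the superior
# and inferior cross-sections.

#' Least-squares sphere fit
#'
#' Algebraic initialization followed by Gauss-Newton refinement of the
#' geometric objective sum((||p - c|| - R)^2) with the radius profiled out
#' (R = mean distance).
#'
#' @param points N x 3 matrix (N >= 4, non-coplanar).
#' @param max_iter Gauss-Newton iteration cap.
#' @return list with \code{center}, \code{radius}, \code{residuals}.
#' @export
fit_sphere <- function(points, max_iter = 30L) {
  points <- .check_cloud(points, min_n = 4L)
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-10 * ev[1]) stop("degenerate point set: points are coplanar")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  for (it in seq_len(max_iter)) {
    dif <- sweep(points, 2, ctr)
    r <- sqrt(rowSums(dif^2))
    e <- r - mean(r)
    U <- -dif / r
    J <- sweep(U, 2, colMeans(U))
    delta <- tryCatch(solve(crossprod(J), -crossprod(J, e)),
                      error = function(err) matrix(0, 3, 1))
    ctr <- ctr + as.vector(delta)
    if (sqrt(sum(delta^2)) < 1e-10) break
  }
  dif <- sweep(points, 2, ctr)
  r <- sqrt(rowSums(dif^2))
  list(center = unname(ctr), radius = mean(r), residuals = r - mean(r))
}

#' Sphericity of a point set
#'
#' Percent score from the normalized residuals of the best-fit sphere:
#' \code{(1 - mean(|residual|) / R) * 100}.  100 means a perfect sphere; the
#' score is scale-invariant.
#'
#' @param surface_samples N x 3 matrix of surface points, mm.
#' @return sphericity in percent.
#' @export
sphericity <- function(surface_samples) {
  fit <- fit_sphere(surface_samples)
  (1 - mean(abs(fit$residuals)) / fit$radius) * 100
}

# Cross-section machinery: a fixed parametric grid of surface points is
# evaluated once per mesh; each horizontal slice is extracted by locating the
# sign changes of z - z0 along the v direction of every grid column and
# interpolating x and y there.
.slice_grid <- function(mesh, nu = 8L, nv = 17L) {
  nf <- nrow(mesh$faces)
  us <- (seq_len(nu) - 0.5) / nu
  vs <- seq(0, 1, length.out = nv)
  face <- rep(seq_len(nf), each = nu * nv)
  u <- rep(rep(us, each = nv), nf)
  v <- rep(vs, nu * nf)
  B <- .grid_basis(mesh, paste0("slice", nu, "x", nv), face, u, v)
  P <- as.matrix(B %*% .nodes_to_Q(mesh$nodes))
  ncols <- nu * nf
  list(x = matrix(P[, 1], nrow = nv), y = matrix(P[, 2], nrow = nv),
       z = matrix(P[, 3], nrow = nv))
}

.slice_crossings <- function(grid, z0) {
  s <- grid$z - z0
  a <- s[-nrow(s), , drop = FALSE]; b <- s[-1L, , drop = FALSE]
  hit <- which(a * b <= 0 & (a != b))
  if (!length(hit)) return(NULL)
  t <- a[hit] / (a[hit] - b[hit])
  xa <- grid$x[-nrow(s), , drop = FALSE]; xb <- grid$x[-1L, , drop = FALSE]
  ya <- grid$y[-nrow(s), , drop = FALSE]; yb <- grid$y[-1L, , drop = FALSE]
  cbind(x = xa[hit] + t * (xb[hit] - xa[hit]),
        y = ya[hit] + t * (yb[hit] - ya[hit]))
}

#' Cross-section contour points at given heights
#'
#' Intersects the Hermite surface with horizontal planes and returns the
#' in-plane contour points.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param z heights (mm, FH axis).
#' @param nu,nv parametric grid resolution per face.
#' @return list (one entry per height) of matrices with columns x, y; NULL
#'   where the plane misses the surface.
#' @export
mesh_cross_sections <- function(mesh, z, nu = 8L, nv = 17L) {
  grid <- .slice_grid(mesh, nu, nv)
  lapply(z, function(z0) .slice_crossings(grid, z0))
}

#' Anterior-posterior radius from the smooth mesh
#'
#' Half of the minimal caliper width of the equatorial cross-section (the
#' section at the centroid height): the "shortest equatorial radius".  The
#' caliper scan over in-plane directions makes the value invariant to
#' in-plane rotation of the mesh.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param angle_step caliper scan step in degrees.
#' @return radius in mm.
#' @export
ap_radius_mesh <- function(mesh, angle_step = 0.5) {
  z0 <- surface_integrals(mesh)$centroid[3]
  ct <- mesh_cross_sections(mesh, z0, nu = 16L)[[1L]]
  if (is.null(ct) || nrow(ct) < 3L) stop("empty equatorial cross-section")
  th <- seq(0, pi, by = angle_step * pi / 180)
  proj <- ct %*% rbind(cos(th), sin(th))
  widths <- apply(proj, 2, max) - apply(proj, 2, min)
  min(widths) / 2
}

#' Anterior-posterior radius from the segmentation cloud
#'
#' Half of the AP (y) extent of the points within a slab about the cloud's
#' center-of-mass height.
#'
#' @param cloud N x 3 matrix of points, mm.
#' @param slab_halfwidth slab half-thickness in mm (default 2).
#' @return radius in mm.
#' @export
ap_radius_segmentation <- function(cloud, slab_halfwidth = 2) {
  cloud <- .check_cloud(cloud)
  z0 <- mean(cloud[, 3])
  sel <- abs(cloud[, 3] - z0) <= slab_halfwidth
  if (!any(sel)) stop("no points in the equatorial slab")
  (max(cloud[sel, 2]) - min(cloud[sel, 2])) / 2
}

#' Half-extents of the surface along the anatomical axes
#'
#' @param mesh a \code{hermite_mesh}.
#' @param n_per_face surface sampling resolution.
#' @return list with radii \code{lr}, \code{ap}, \code{fh} (mm) and the
#'   dimensionless ratios \code{ap_lr}, \code{lr_fh}, \code{ap_fh}.
#' @export
axis_radii <- function(mesh, n_per_face = 8L) {
  S <- sample_surface(mesh, n_per_face)
  half <- (apply(S, 2, max) - apply(S, 2, min)) / 2
  list(lr = half[1], ap = half[2], fh = half[3],
       ap_lr = half[2] / half[1], lr_fh = half[1] / half[3],
       ap_fh = half[2] / half[3])
}

#' Vertical asymmetry
#'
#' Signed imbalance in anterior-posterior size between the superior and
#' inferior hemispheres.  With z0 the centroid height and H the smaller of
#' the two pole distances, slice pairs are taken at mirrored heights
#' z0 +/- h_j, h_j = (j - 1/2) H / n for j = 1..n; each slice contributes the
#' AP extent (max y - min y) of its cross-section, and the marker is the sum
#' over pairs of superior minus inferior extent (mm).  Positive values mean
#' the superior hemisphere is AP-larger; the value is zero for any shape
#' mirror-symmetric about z0 and flips sign under z-reflection.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param n_slice_pairs number of mirrored slice pairs (default 50).
#' @param nu,nv parametric slicing grid per face.
#' @return vertical asymmetry in mm (sum over slice pairs).
#' @export
vertical_asymmetry <- function(mesh, n_slice_pairs = 50L, nu = 8L, nv = 17L) {
  z0 <- surface_integrals(mesh)$centroid[3]
  grid <- .slice_grid(mesh, nu, nv)
  zmax <- max(grid$z); zmin <- min(grid$z)
  if (zmax <= z0 || zmin >= z0) stop("centroid outside the surface's FH range")
  H <- min(zmax - z0, z0 - zmin)
  h <- (seq_len(n_slice_pairs) - 0.5) * H / n_slice_pairs
  va <- 0; used <- 0L
  for (hj in h) {
    up <- .slice_crossings(grid, z0 + hj)
    lo <- .slice_crossings(grid, z0 - hj)
    if (is.null(up) || is.null(lo)) next
    va <- va + (max(up[, "y"]) - min(up[, "y"])) -
               (max(lo[, "y"]) - min(lo[, "y"]))
    used <- used + 1L
  }
  if (used == 0L) stop("all slices missed the surface")
  if (used < n_slice_pairs)
    warning(sprintf("%d of %d slice pairs missed the surface and were skipped",
                    n_slice_pairs - used, n_slice_pairs))
  va
}

#' Per-subject marker table
#'
#' Computes every mesh-derived marker for each subject, adds
#' segmentation-derived markers where clouds are available, and merges
#' clinical columns (echo AP radius, recurrence labels and censoring flags)
#' by \code{subject_id}.  Missing values stay NA; nothing is imputed.
#'
#' @param meshes named list of fitted \code{hermite_mesh} objects.
#' @param clouds optional named list of segmentation clouds (same ids).
#' @param clinical optional data.frame with \code{subject_id} and any of
#'   \code{ap_radius_echo}, \code{recurrence_12m}, \code{censored_12m},
#'   \code{recurrence_24m}, \code{censored_24m}.
#' @param n_slice_pairs passed to \code{\link{vertical_asymmetry}}.
#' @return an \code{la_marker_table} data.frame.
#' @export
compute_marker_table <- function(meshes, clouds = NULL, clinical = NULL,
                                 n_slice_pairs = 50L) {
  ids <- names(meshes)
  if (is.null(ids)) ids <- as.character(seq_along(meshes))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  rows <- lapply(seq_along(meshes), function(i) {
    m <- meshes[[i]]
    si <- surface_integrals(m)
    ar <- axis_radii(m)
    cl <- if (!is.null(clouds)) clouds[[ids[i]]] else NULL
    sph_pts <- if (!is.null(cl)) cl else sample_surface(m, 8L)
    data.frame(
      subject_id = ids[i],
      volume = si$volume,
      surface_area = si$area,
      ap_radius_mesh = ap_radius_mesh(m),
      ap_radius_segmentation = if (!is.null(cl))
        ap_radius_segmentation(cl) else NA_real_,
      lr_radius = ar$lr, ap_radius = ar$ap, fh_radius = ar$fh,
      ap_lr_ratio = ar$ap_lr, lr_fh_ratio = ar$lr_fh,
      sphericity = sphericity(sph_pts),
      vertical_asymmetry = vertical_asymmetry(m, n_slice_pairs))
  })
  out <- do.call(rbind, rows)
  for (col in c("ap_radius_echo", "recurrence_12m", "censored_12m",
                "recurrence_24m", "censored_24m"))
    out[[col]] <- NA
  if (!is.null(clinical)) {
    if (!"subject_id" %in% names(clinical)) stop("clinical table needs subject_id")
    if (anyDuplicated(clinical$subject_id)) stop("duplicate clinical subject ids")
    j <- match(out$subject_id, as.character(clinical$subject_id))
    for (col in intersect(names(clinical),
                          c("ap_radius_echo", "recurrence_12m", "censored_12m",
                            "recurrence_24m", "censored_24m")))
      out[[col]] <- clinical[[col]][j]
  }
  class(out) <- c("la_marker_table", "data.frame")
  out
}
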