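# Personalization of the spherical template to a subject's endocardial
# segmentation point cloud: similarity initialization, then an ICP-style loop
# alternating closest-surface-point correspondences with a Sobolev-regularized
# linear update of all node DOF.  The regularizer penalizes second parametric
# derivatives of the displacement field from the aligned template, which keeps
# the fitted surfaces smooth and free of segmentation artifacts.

.check_cloud <- function(points, min_n = 4L) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("a segmentation cloud must be an N x 3 matrix (mm)")
  if (!all(is.finite(points))) stop("cloud contains non-finite coordinates")
  if (nrow(points) < min_n) stop("too few cloud points")
  points
}

.nearest_sample <- function(points, S, chunk = 1024L) {
  s2 <- rowSums(S^2)
  n <- nrow(points)
  idx <- integer(n); d2 <- numeric(n)
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    P <- points[st:en, , drop = FALSE]
    D <- matrix(s2, en - st + 1L, length(s2), byrow = TRUE) - 2 * P %*% t(S)
    j <- max.col(-D, ties.method = "first")
    idx[st:en] <- j
    d2[st:en] <- D[cbind(seq_len(nrow(D)), j)] + rowSums(P^2)
  }
  list(idx = idx, d2 = pmax(d2, 0))
}

#' Similarity alignment of the template to a cloud
#'
#' Translation to the cloud centroid plus an isotropic scale matching the RMS
#' radius.  No rotation is estimated: patient axes are trusted, which
#' preserves the inferior-node correspondence across subjects.
#'
#' @param cloud N x 3 matrix of segmentation points, mm.
#' @param template a \code{hermite_mesh}.
#' @return an object of class \code{la_transform} with \code{scale},
#'   \code{cloud_centroid} and \code{template_centroid}.
#' @export
initial_align <- function(cloud, template) {
  cloud <- .check_cloud(cloud)
  ev <- eigen(stats::cov(cloud), symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-8 * ev[1])
    stop("degenerate cloud: covariance is rank-deficient")
  cc <- colMeans(cloud)
  rc <- sqrt(mean(rowSums(sweep(cloud, 2, cc)^2)))
  S <- sample_surface(template, n_per_face = 4L)
  ct <- colMeans(S)
  rt <- sqrt(mean(rowSums(sweep(S, 2, ct)^2)))
  structure(list(scale = rc / rt, cloud_centroid = cc, template_centroid = ct),
            class = "la_transform")
}

#' Apply a similarity alignment to a mesh
#' @param mesh a \code{hermite_mesh}.
#' @param transform an \code{la_transform} from \code{\link{initial_align}}.
#' @export
apply_alignment <- function(mesh, transform) {
  stopifnot(inherits(transform, "la_transform"))
  transform_mesh(mesh, scale = transform$scale,
                 translation = transform$cloud_centroid - transform$template_centroid,
                 center = transform$template_centroid)
}

# second-derivative (Sobolev) rows at Gauss points, cached per topology
.reg_matrix <- function(mesh, q = 3L) {
  key <- paste(.topology_key(mesh), "reg", q, sep = "_")
  hit <- .atriashape_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(q, 0, 1)
  g <- expand.grid(iu = seq_len(q), iv = seq_len(q))
  nf <- nrow(mesh$faces)
  face <- rep(seq_len(nf), each = nrow(g))
  u <- rep(gl$x[g$iu], nf); v <- rep(gl$x[g$iv], nf)
  w <- sqrt(rep(gl$w[g$iu] * gl$w[g$iv], nf))
  Buu <- .hermite_basis(mesh, face, u, v, 2L, 0L) * w
  Bvv <- .hermite_basis(mesh, face, u, v, 0L, 2L) * w
  Buv <- .hermite_basis(mesh, face, u, v, 1L, 1L) * (w * sqrt(2))
  R <- rbind(Buu, Bvv, Buv)
  assign(key, R, envir = .atriashape_cache)
  R
}

#' Fit the template to a segmentation point cloud
#'
#' Iterates (a) correspondence of each cloud point to its closest point on a
#' dense surface sample grid and (b) a linear least-squares update of all node
#' DOF minimizing the summed squared misfit plus
#' \code{stiffness} times the second-derivative energy of the displacement
#' from the aligned template.  The objective is non-increasing across
#' iterations; the fitted mesh keeps the template topology.
#'
#' @param cloud N x 3 matrix of segmentation points (N >= 100), mm.
#' @param template a \code{hermite_mesh} (typically
#'   \code{\link{make_sphere_template}()}).
#' @param stiffness regularization weight (lambda >= 0); larger values give
#'   smoother, more template-like fits.
#' @param max_iter maximum number of correspondence/update iterations.
#' @param tol stop when the RMS misfit improves by less than this (mm).
#' @param samples_per_face correspondence sample-grid resolution.
#' @param align apply \code{\link{initial_align}} first (default TRUE).
#' @return list with \code{mesh} (fitted \code{hermite_mesh}) and
#'   \code{report} (an \code{la_fit_report}; its \code{objective} field traces
#'   the optimized objective).
#' @export
fit_template <- function(cloud, template, stiffness = 0.2, max_iter = 30L,
                         tol = 1e-3, samples_per_face = 6L, align = TRUE) {
  cloud <- .check_cloud(cloud, min_n = 100L)
  if (!is.numeric(stiffness) || stiffness < 0)
    stop("stiffness must be >= 0")
  mesh <- if (align) apply_alignment(template, initial_align(cloud, template)) else template
  g <- .face_grid(nrow(mesh$faces), samples_per_face, samples_per_face)
  B <- .grid_basis(mesh, paste0("fit", samples_per_face), g$face, g$u, g$v)
  R <- .reg_matrix(mesh)
  RtR <- Matrix::crossprod(R)
  Q0 <- .nodes_to_Q(mesh$nodes)
  Q <- Q0
  obj_prev <- Inf
  rms_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    S <- as.matrix(B %*% Q)
    nn <- .nearest_sample(cloud, S)
    obj <- sum(nn$d2) +
      stiffness * sum(as.matrix(R %*% (Q - Q0))^2)
    trace <- c(trace, obj)
    if (obj > obj_prev * (1 + 1e-6))
      stop("fit diverged: objective increased")
    rms <- sqrt(mean(nn$d2))
    if (is.finite(rms_prev) && abs(rms_prev - rms) < tol) {
      converged <- TRUE
      iters <- it
      break
    }
    obj_prev <- obj; rms_prev <- rms; iters <- it
    A <- B[nn$idx, , drop = FALSE]
    M <- Matrix::crossprod(A) + stiffness * RtR
    dM <- Matrix::diag(M)
    fix <- which(dM < 1e-10 * mean(dM))
    rhs <- Matrix::crossprod(A, cloud) + stiffness * (RtR %*% Q0)
    if (length(fix)) {
      M[cbind(fix, fix)] <- mean(dM)
      rhs[fix, ] <- mean(dM) * Q0[fix, ]
    }
    Q <- as.matrix(Matrix::solve(M, rhs))
  }
  mesh$nodes <- .Q_to_nodes(Q)
  report <- fit_error(mesh, cloud)
  report$iterations <- iters
  report$converged <- converged
  report$objective <- trace
  list(mesh = mesh, report = report)
}

#' Point-to-surface fit error
#'
#' Unsigned distance from each cloud point to the Hermite surface: nearest
#' point on a dense per-patch sample grid, then local parametric refinement
#' within that patch.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param cloud N x 3 matrix of points, mm.
#' @param samples_per_face initial sample-grid resolution per direction.
#' @param refine_iter local refinement steps (0 disables refinement).
#' @return an \code{la_fit_report}: \code{mean_error}, \code{sd_error},
#'   \code{per_point_distances} (mm).
#' @export
fit_error <- function(mesh, cloud, samples_per_face = 8L, refine_iter = 9L) {
  cloud <- .check_cloud(cloud)
  Q <- .nodes_to_Q(mesh$nodes)
  g <- .face_grid(nrow(mesh$faces), samples_per_face, samples_per_face)
  B <- .grid_basis(mesh, paste0("err", samples_per_face), g$face, g$u, g$v)
  S <- as.matrix(B %*% Q)
  nn <- .nearest_sample(cloud, S)
  f <- g$face[nn$idx]; u <- g$u[nn$idx]; v <- g$v[nn$idx]
  d2 <- nn$d2
  n <- nrow(cloud)
  if (refine_iter > 0L) {
    h <- 0.5 / samples_per_face
    off <- expand.grid(du = c(-1, 0, 1), dv = c(-1, 0, 1))
    for (it in seq_len(refine_iter)) {
      uu <- pmin(1, pmax(0, rep(u, each = 9L) + rep(off$du, n) * h))
      vv <- pmin(1, pmax(0, rep(v, each = 9L) + rep(off$dv, n) * h))
      ff <- rep(f, each = 9L)
      P <- as.matrix(.hermite_basis(mesh, ff, uu, vv) %*% Q)
      dd <- rowSums((P - cloud[rep(seq_len(n), each = 9L), , drop = FALSE])^2)
      dd <- matrix(dd, nrow = 9L)
      k <- max.col(t(-dd), ties.method = "first")
      pick <- (seq_len(n) - 1L) * 9L + k
      u <- uu[pick]; v <- vv[pick]; d2 <- dd[cbind(k, seq_len(n))]
      h <- h / 2
    }
  }
  d <- sqrt(pmax(d2, 0))
  structure(list(mean_error = mean(d), sd_error = stats::sd(d),
                 per_point_distances = d, iterations = NA_integer_,
                 converged = NA),
            class = "la_fit_report")
}

#' @export
print.la_fit_report <- function(x, ...) {
  cat(sprintf("Fit error: %.3f +/- %.3f mm over %d points\n",
              x$mean_error, x$sd_error, length(x$per_point_distances)))
  invisible(x)
}
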