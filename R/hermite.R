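# Bicubic Hermite closed-surface representation.
#
# A mesh is a closed C1 surface built from quadrilateral patches (pole caps are
# quads with one collapsed edge).  Each node carries 12 scalar degrees of
# freedom: position (x, y, z) and the parametric derivatives du, dv, duv
# (3 components each), expressed per unit of the local patch coordinate.
# Coordinate convention throughout: +x = right-to-left (LR), +y =
# posterior-to-anterior (AP), +z = foot-to-head (FH); units mm.

.atriashape_cache <- new.env(parent = emptyenv())

# cubic Hermite basis (h00, h01, h10, h11) and its derivatives
.hbasis <- function(t, deriv = 0L) {
  if (deriv == 0L) {
    cbind(2 * t^3 - 3 * t^2 + 1, -2 * t^3 + 3 * t^2,
          t^3 - 2 * t^2 + t, t^3 - t^2)
  } else if (deriv == 1L) {
    cbind(6 * t^2 - 6 * t, -6 * t^2 + 6 * t,
          3 * t^2 - 4 * t + 1, 3 * t^2 - 2 * t)
  } else if (deriv == 2L) {
    cbind(12 * t - 6, -12 * t + 6, 6 * t - 4, 6 * t - 2)
  } else stop("basis derivative order must be 0, 1 or 2")
}

.nodes_to_Q <- function(nodes) {
  matrix(t(nodes), ncol = 3L, byrow = TRUE)
}

.Q_to_nodes <- function(Q) {
  matrix(t(Q), ncol = 12L, byrow = TRUE)
}

#' Sparse Hermite basis-weight matrix
#'
#' Maps the per-coordinate stack of node DOF (position, du, dv, duv for each
#' node; 4V columns) to surface evaluations at the requested parametric
#' locations.  Pole corners blend the two stored pole tangents by the column
#' angle, which keeps evaluation linear in the node DOF.
#'
#' @noRd
.hermite_basis <- function(mesh, face, u, v, du_order = 0L, dv_order = 0L) {
  n <- length(face)
  V <- nrow(mesh$nodes)
  Hu <- .hbasis(u, du_order)
  Hv <- .hbasis(v, dv_order)
  # columns of H*: (end0, end1, tangent0, tangent1)
  pole  <- mesh$pole[face]
  th    <- mesh$face_theta[face, , drop = FALSE]
  dth   <- th[, 2L] - th[, 1L]
  ii <- jj <- xx <- vector("list", 4L)
  corner_iu <- c(0L, 1L, 0L, 1L)  # corners n00, n10, n01, n11
  corner_iv <- c(0L, 0L, 1L, 1L)
  for (c in 1:4) {
    iu <- corner_iu[c]; iv <- corner_iv[c]
    nd <- mesh$faces[face, c]
    au <- Hu[, 1L + iu]; bu <- Hu[, 3L + iu]   # value / tangent blending in u
    av <- Hv[, 1L + iv]; bv <- Hv[, 3L + iv]
    wp   <- au * av
    wdu  <- bu * av
    wdv  <- au * bv
    wduv <- bu * bv
    is_pole <- (pole == -1L & iv == 0L) | (pole == 1L & iv == 1L)
    base <- (nd - 1L) * 4L
    reg <- which(!is_pole)
    pol <- which(is_pole)
    i_r <- rep(reg, 4L)
    j_r <- c(base[reg] + 1L, base[reg] + 2L, base[reg] + 3L, base[reg] + 4L)
    x_r <- c(wp[reg], wdu[reg], wdv[reg], wduv[reg])
    if (length(pol)) {
      thc <- if (iu == 0L) th[pol, 1L] else th[pol, 2L]
      ct <- cos(thc); st <- sin(thc)
      # position; dv blends the two stored pole tangents; duv is the
      # u-derivative of that blend; du vanishes along the collapsed edge
      i_p <- rep(pol, 5L)
      j_p <- c(base[pol] + 1L,
               base[pol] + 2L, base[pol] + 3L,
               base[pol] + 2L, base[pol] + 3L)
      x_p <- c(wp[pol],
               wdv[pol] * ct, wdv[pol] * st,
               wduv[pol] * dth[pol] * (-st), wduv[pol] * dth[pol] * ct)
      i_r <- c(i_r, i_p); j_r <- c(j_r, j_p); x_r <- c(x_r, x_p)
    }
    ii[[c]] <- i_r; jj[[c]] <- j_r; xx[[c]] <- x_r
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, 4L * V))
}

.topology_key <- function(mesh) paste0("s", mesh$segments, "r", mesh$rings)

# cached basis for a fixed per-face parametric grid shared by all meshes with
# the same template topology
.grid_basis <- function(mesh, tag, faces, u, v, du_order = 0L, dv_order = 0L) {
  key <- paste(.topology_key(mesh), tag, du_order, dv_order, sep = "_")
  hit <- .atriashape_cache[[key]]
  if (!is.null(hit)) return(hit)
  B <- .hermite_basis(mesh, faces, u, v, du_order, dv_order)
  assign(key, B, envir = .atriashape_cache)
  B
}

.face_grid <- function(n_faces, n_u, n_v, interior = TRUE) {
  if (interior) {
    us <- (seq_len(n_u) - 0.5) / n_u
    vs <- (seq_len(n_v) - 0.5) / n_v
  } else {
    us <- seq(0, 1, length.out = n_u)
    vs <- seq(0, 1, length.out = n_v)
  }
  g <- expand.grid(u = us, v = vs)
  list(face = rep(seq_len(n_faces), each = nrow(g)),
       u = rep(g$u, n_faces), v = rep(g$v, n_faces),
       n_per_face = nrow(g))
}

#' Build a closed Hermite mesh from an analytic parametrization
#'
#' Samples a surface \code{f(theta, phi)} (\code{theta} longitude in
#' \code{[0, 2*pi)}, \code{phi} colatitude in \code{[0, pi]} measured from the
#' inferior pole) on a UV grid and fills the 12 node DOF from finite
#' differences of the parametrization.  \code{f(theta, 0)} and
#' \code{f(theta, pi)} must be independent of \code{theta} (closed poles).
#' Node 1 is the inferior pole; pole nodes store the two orthogonal pole
#' tangents in their du/dv slots.
#'
#' @param f vectorized function of (theta, phi) returning an n x 3 matrix, mm.
#' @param segments number of longitudinal columns (>= 3).
#' @param rings number of latitude rings between the poles (>= 2).
#' @param fd_step finite-difference step in radians.
#' @return an object of class \code{hermite_mesh}.
#' @export
mesh_from_parametrization <- function(f, segments = 12L, rings = 11L,
                                      fd_step = 1e-4) {
  segments <- as.integer(segments); rings <- as.integer(rings)
  if (segments < 3L) stop("segments must be >= 3")
  if (rings < 2L) stop("rings must be >= 2")
  h <- fd_step
  dtheta <- 2 * pi / segments
  dphi <- pi / (rings + 1L)
  V <- segments * rings + 2L
  th <- rep(dtheta * (seq_len(segments) - 1L), times = rings)
  ph <- rep(dphi * seq_len(rings), each = segments)
  fv <- function(t, p) {
    out <- f(t, p)
    if (is.null(dim(out))) out <- matrix(out, ncol = 3L)
    out
  }
  pos <- fv(th, ph)
  du  <- dtheta * (fv(th + h, ph) - fv(th - h, ph)) / (2 * h)
  dv  <- dphi * (fv(th, ph + h) - fv(th, ph - h)) / (2 * h)
  duv <- dtheta * dphi *
    (fv(th + h, ph + h) - fv(th + h, ph - h) -
     fv(th - h, ph + h) + fv(th - h, ph - h)) / (4 * h^2)
  nodes <- matrix(0, V, 12L)
  nodes[2:(V - 1L), ] <- cbind(pos, du, dv, duv)
  # poles: one-sided second-order phi-derivatives along theta = 0 and pi/2
  p_inf <- fv(0, 0); p_sup <- fv(0, pi)
  d_inf <- function(t) dphi * (-3 * fv(t, 0) + 4 * fv(t, h) - fv(t, 2 * h)) / (2 * h)
  d_sup <- function(t) dphi * (3 * fv(t, pi) - 4 * fv(t, pi - h) + fv(t, pi - 2 * h)) / (2 * h)
  nodes[1L, ] <- c(p_inf, d_inf(0), d_inf(pi / 2), 0, 0, 0)
  nodes[V, ]  <- c(p_sup, d_sup(0), d_sup(pi / 2), 0, 0, 0)
  rid <- function(i, j) 1L + (i - 1L) * segments + (j %% segments) + 1L
  j <- 0:(segments - 1L)
  t0 <- dtheta * j; t1 <- dtheta * (j + 1L)
  faces <- rbind(
    cbind(1L, 1L, rid(1L, j), rid(1L, j + 1L)),
    do.call(rbind, lapply(seq_len(rings - 1L), function(i)
      cbind(rid(i, j), rid(i, j + 1L), rid(i + 1L, j), rid(i + 1L, j + 1L)))),
    cbind(rid(rings, j), rid(rings, j + 1L), V, V))
  face_theta <- do.call(rbind, rep(list(cbind(t0, t1)), rings + 1L))
  pole <- c(rep(-1L, segments), rep(0L, segments * (rings - 1L)),
            rep(1L, segments))
  structure(list(nodes = nodes, faces = faces, face_theta = face_theta,
                 pole = pole, segments = segments, rings = rings,
                 axes = "x=LR,y=AP,z=FH"),
            class = "hermite_mesh")
}

#' Spherical Hermite template
#'
#' The standard atlas template: a UV sphere with \code{segments} longitudinal
#' columns and \code{rings} latitude rings plus two pole nodes.  The defaults
#' (12, 11) give 134 nodes and 144 faces (120 quads + 24 pole triangles), i.e.
#' 134 x 12 = 1,608 shape parameters per subject.
#'
#' @param radius sphere radius in mm (default 20).
#' @param segments,rings template resolution.
#' @return a \code{hermite_mesh}.
#' @examples
#' tpl <- make_sphere_template()
#' nrow(tpl$nodes)  # 134
#' nrow(tpl$faces)  # 144
#' @export
make_sphere_template <- function(radius = 20, segments = 12L, rings = 11L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive number")
  f <- function(theta, phi)
    cbind(radius * sin(phi) * cos(theta),
          radius * sin(phi) * sin(theta),
          -radius * cos(phi))
  mesh_from_parametrization(f, segments, rings)
}

#' Evaluate a Hermite patch
#'
#' Bicubic Hermite tensor-product interpolation of a face's four corner nodes.
#' Vectorized over (face, u, v); optional parametric derivatives.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param face face index (or vector of indices).
#' @param u,v parametric coordinates in [0, 1].
#' @param deriv_u,deriv_v derivative order (0, 1 or 2) in each direction.
#' @return n x 3 matrix of points (mm) or parametric derivatives.
#' @export
evaluate_patch <- function(mesh, face, u, v, deriv_u = 0L, deriv_v = 0L) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  n <- max(length(face), length(u), length(v))
  face <- rep_len(as.integer(face), n); u <- rep_len(u, n); v <- rep_len(v, n)
  if (any(face < 1L | face > nrow(mesh$faces)))
    stop("invalid face index")
  if (any(u < -1e-9 | u > 1 + 1e-9 | v < -1e-9 | v > 1 + 1e-9))
    stop("(u, v) must lie in the unit square")
  B <- .hermite_basis(mesh, face, u, v, as.integer(deriv_u), as.integer(deriv_v))
  as.matrix(B %*% .nodes_to_Q(mesh$nodes))
}

# undirected non-degenerate edge table; used for validation and C1 checks
.mesh_edges <- function(mesh) {
  fc <- mesh$faces
  # edge slots: 1 (n00-n10, v=0), 2 (n10-n11, u=1), 3 (n11-n01, v=1), 4 (n01-n00, u=0)
  a <- c(fc[, 1], fc[, 2], fc[, 4], fc[, 3])
  b <- c(fc[, 2], fc[, 4], fc[, 3], fc[, 1])
  face <- rep(seq_len(nrow(fc)), 4L)
  slot <- rep(1:4, each = nrow(fc))
  keep <- a != b
  data.frame(face = face[keep], slot = slot[keep],
             from = a[keep], to = b[keep],
             key = paste(pmin(a, b), pmax(a, b), sep = "-")[keep])
}

#' Validate mesh structure and topology
#'
#' Checks finiteness of all DOF, that every non-degenerate edge is shared by
#' exactly two faces, and that the Euler characteristic V - E + F equals 2.
#'
#' @param mesh a \code{hermite_mesh}.
#' @return invisibly, a list with V, E, F and the Euler characteristic.
#' @export
validate_hermite_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  if (ncol(mesh$nodes) != 12L) stop("nodes must have 12 DOF each")
  if (!all(is.finite(mesh$nodes))) stop("non-finite node DOF")
  ed <- .mesh_edges(mesh)
  cnt <- table(ed$key)
  if (any(cnt != 2L)) stop("mesh is not closed: an edge is not shared by exactly 2 faces")
  V <- nrow(mesh$nodes); E <- length(cnt); F <- nrow(mesh$faces)
  if (V - E + F != 2L) stop("Euler characteristic V - E + F != 2")
  invisible(list(V = V, E = E, F = F, euler = V - E + F))
}

#' Surface area, enclosed volume and centroid
#'
#' Tensor Gauss-Legendre quadrature per patch; the volume uses the divergence
#' theorem (1/3) * integral of x . n dA and the centroid the corresponding
#' first moments.  Requires a closed, outward-oriented mesh.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param quadrature_order Gauss-Legendre points per direction (default 4).
#' @return list with \code{area} (mm^2), \code{volume} (mm^3), \code{centroid}.
#' @export
surface_integrals <- function(mesh, quadrature_order = 4L) {
  validate_hermite_mesh(mesh)
  q <- as.integer(quadrature_order)
  gl <- pracma::gaussLegendre(q, 0, 1)
  g <- expand.grid(iu = seq_len(q), iv = seq_len(q))
  nf <- nrow(mesh$faces)
  face <- rep(seq_len(nf), each = nrow(g))
  u <- rep(gl$x[g$iu], nf); v <- rep(gl$x[g$iv], nf)
  w <- rep(gl$w[g$iu] * gl$w[g$iv], nf)
  tag <- paste0("gl", q)
  Q <- .nodes_to_Q(mesh$nodes)
  p  <- as.matrix(.grid_basis(mesh, tag, face, u, v, 0L, 0L) %*% Q)
  pu <- as.matrix(.grid_basis(mesh, tag, face, u, v, 1L, 0L) %*% Q)
  pv <- as.matrix(.grid_basis(mesh, tag, face, u, v, 0L, 1L) %*% Q)
  nrm <- cbind(pu[, 2] * pv[, 3] - pu[, 3] * pv[, 2],
               pu[, 3] * pv[, 1] - pu[, 1] * pv[, 3],
               pu[, 1] * pv[, 2] - pu[, 2] * pv[, 1])
  area <- sum(w * sqrt(rowSums(nrm^2)))
  volume <- sum(w * rowSums(p * nrm)) / 3
  if (volume <= 0)
    stop("non-positive enclosed volume: mesh orientation is inward or inconsistent")
  centroid <- colSums(w * p^2 * nrm / 2) / volume
  list(area = area, volume = volume, centroid = unname(centroid))
}

#' Flatten a mesh to its shape vector
#'
#' Node-major, component-minor ordering (x, y, z, du, dv, duv per node);
#' length 12 x V (1,608 for the standard template).
#' @param mesh a \code{hermite_mesh}.
#' @export
mesh_to_vector <- function(mesh) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  as.vector(t(mesh$nodes))
}

#' Rebuild a mesh from a shape vector and a topology
#'
#' @param vector numeric vector of length 12 x V.
#' @param topology a \code{hermite_mesh} providing faces and conventions.
#' @export
vector_to_mesh <- function(vector, topology) {
  stopifnot(inherits(topology, "hermite_mesh"))
  V <- nrow(topology$nodes)
  if (length(vector) != 12L * V)
    stop(sprintf("shape vector length %d does not match topology (expected %d)",
                 length(vector), 12L * V))
  out <- topology
  out$nodes <- matrix(vector, ncol = 12L, byrow = TRUE)
  out
}

#' Similarity-transform a mesh
#'
#' Applies an isotropic scale about \code{center} followed by a translation;
#' derivative DOF scale with the geometry.
#' @param mesh a \code{hermite_mesh}.
#' @param scale isotropic scale factor.
#' @param translation length-3 offset, mm.
#' @param center point the scaling is taken about (default origin).
#' @export
transform_mesh <- function(mesh, scale = 1, translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  nd <- mesh$nodes
  nd[, 1:3] <- sweep(sweep(nd[, 1:3, drop = FALSE], 2, center) * scale,
                     2, translation + center, "+")
  nd[, 4:12] <- nd[, 4:12] * scale
  mesh$nodes <- nd
  mesh
}

#' Sample points on the mesh surface
#'
#' Deterministic interior-grid sampling (\code{n_u} x \code{n_v} per face) or
#' random area-weighted sampling.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param n_per_face grid resolution per direction for deterministic sampling.
#' @param n_random if given, that many random surface points are drawn instead
#'   (faces weighted by area, uniform in the patch coordinates).
#' @return n x 3 matrix of surface points, mm.
#' @export
sample_surface <- function(mesh, n_per_face = 8L, n_random = NULL) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  Q <- .nodes_to_Q(mesh$nodes)
  if (is.null(n_random)) {
    g <- .face_grid(nrow(mesh$faces), n_per_face, n_per_face)
    B <- .grid_basis(mesh, paste0("grid", n_per_face), g$face, g$u, g$v)
    return(as.matrix(B %*% Q))
  }
  fa <- .face_areas(mesh)
  face <- sample.int(nrow(mesh$faces), n_random, replace = TRUE, prob = fa)
  u <- stats::runif(n_random); v <- stats::runif(n_random)
  as.matrix(.hermite_basis(mesh, face, u, v) %*% Q)
}

.face_areas <- function(mesh, q = 3L) {
  gl <- pracma::gaussLegendre(q, 0, 1)
  g <- expand.grid(iu = seq_len(q), iv = seq_len(q))
  nf <- nrow(mesh$faces)
  face <- rep(seq_len(nf), each = nrow(g))
  u <- rep(gl$x[g$iu], nf); v <- rep(gl$x[g$iv], nf)
  w <- rep(gl$w[g$iu] * gl$w[g$iv], nf)
  Q <- .nodes_to_Q(mesh$nodes)
  tag <- paste0("fa", q)
  pu <- as.matrix(.grid_basis(mesh, tag, face, u, v, 1L, 0L) %*% Q)
  pv <- as.matrix(.grid_basis(mesh, tag, face, u, v, 0L, 1L) %*% Q)
  nrm2 <- (pu[, 2] * pv[, 3] - pu[, 3] * pv[, 2])^2 +
          (pu[, 3] * pv[, 1] - pu[, 1] * pv[, 3])^2 +
          (pu[, 1] * pv[, 2] - pu[, 2] * pv[, 1])^2
  a <- w * sqrt(nrm2)
  as.vector(tapply(a, face, sum))
}

#' Largest position gap across shared patch edges
#'
#' Evaluates every interior edge from both adjacent patches at
#' \code{n_samples} points and returns the maximum distance between the two
#' evaluations; a C1 surface gives values at numerical round-off.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param n_samples points per edge.
#' @return maximum gap in mm.
#' @export
c1_continuity_gap <- function(mesh, n_samples = 10L) {
  ed <- .mesh_edges(mesh)
  t <- seq(0.05, 0.95, length.out = n_samples)
  # parametric curve along each edge slot, oriented from 'from' to 'to'
  slot_uv <- function(slot, t) switch(slot,
    list(u = t, v = rep(0, length(t))),
    list(u = rep(1, length(t)), v = t),
    list(u = 1 - t, v = rep(1, length(t))),
    list(u = rep(0, length(t)), v = 1 - t))
  gap <- 0
  sp <- split(seq_len(nrow(ed)), ed$key)
  for (idx in sp) {
    if (length(idx) != 2L) next
    e1 <- ed[idx[1L], ]; e2 <- ed[idx[2L], ]
    uv1 <- slot_uv(e1$slot, t)
    t2 <- if (e2$from == e1$from) t else 1 - t
    uv2 <- slot_uv(e2$slot, t2)
    p1 <- evaluate_patch(mesh, e1$face, uv1$u, uv1$v)
    p2 <- evaluate_patch(mesh, e2$face, uv2$u, uv2$v)
    gap <- max(gap, sqrt(max(rowSums((p1 - p2)^2))))
  }
  gap
}

#' @export
print.hermite_mesh <- function(x, ...) {
  cat(sprintf("Hermite mesh: %d nodes, %d faces (%d segments x %d rings), axes %s\n",
              nrow(x$nodes), nrow(x$faces), x$segments, x$rings, x$axes))
  invisible(x)
}
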