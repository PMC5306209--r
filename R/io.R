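# Readers and writers.  Clouds: whitespace xyz, ASCII PLY, legacy-VTK
# polydata.  Hermite meshes: legacy-VTK polydata with the derivative DOF as
# POINT_DATA FIELD arrays ("deriv_u", "deriv_v", "deriv_uv") and the template
# topology recorded in the header line, so a mesh round-trips losslessly.
# All coordinates are mm in the patient axes x = LR, y = AP, z = FH.

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read a segmentation point cloud
#'
#' Supports whitespace-separated xyz tables (.xyz/.txt/.csv), ASCII PLY
#' (.ply) and legacy-VTK polydata (.vtk).
#'
#' @param path input file.
#' @return N x 3 numeric matrix, mm.
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
    xyz = , txt = {
      m <- as.matrix(utils::read.table(path))
      if (ncol(m) < 3L) stop("xyz file must have at least 3 columns")
      m[, 1:3, drop = FALSE]
    },
    csv = {
      m <- as.matrix(utils::read.csv(path))
      if (ncol(m) < 3L) stop("csv cloud must have at least 3 columns")
      m[, 1:3, drop = FALSE]
    },
    ply = .read_ply_points(path),
    vtk = .read_vtk_points(path),
    stop("unsupported cloud format: .", ext))
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("cloud contains non-finite coordinates")
  unname(pts)
}

.read_ply_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply") stop("not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr))) stop("only ASCII PLY is supported")
  vline <- grep("^element\\s+vertex\\s+\\d+", hdr, value = TRUE)
  if (!length(vline)) stop("malformed PLY: no vertex element")
  nv <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1", vline[1L]))
  body <- lines[(hdr_end + 1L):(hdr_end + nv)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  m
}

.read_vtk_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- grep("^POINTS\\s+\\d+", lines)
  if (!length(pl)) stop("malformed VTK file: no POINTS section")
  n <- as.integer(sub("^POINTS\\s+(\\d+).*", "\\1", lines[pl[1L]]))
  vals <- .scan_numbers(lines, pl[1L] + 1L, 3L * n)
  matrix(vals, ncol = 3L, byrow = TRUE)
}

.scan_numbers <- function(lines, start, count) {
  vals <- numeric(0)
  i <- start
  while (length(vals) < count && i <= length(lines)) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    i <- i + 1L
  }
  if (length(vals) < count || anyNA(vals[seq_len(count)]))
    stop("malformed file: expected ", count, " numeric values")
  vals[seq_len(count)]
}

#' Write a point cloud
#' @param points N x 3 matrix, mm.
#' @param path output file; .xyz writes a plain table, .vtk legacy polydata.
#' @export
write_cloud <- function(points, path) {
  points <- .check_cloud(points)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    utils::write.table(points, path, row.names = FALSE, col.names = FALSE)
  } else if (ext == "vtk") {
    n <- nrow(points)
    writeLines(c("# vtk DataFile Version 3.0", "atriashape cloud", "ASCII",
                 "DATASET POLYDATA", sprintf("POINTS %d double", n),
                 apply(points, 1, function(p) paste(.fmt_num(p), collapse = " ")),
                 sprintf("VERTICES %d %d", n, 2L * n),
                 paste("1", seq_len(n) - 1L)), path)
  } else stop("unsupported cloud format: .", ext)
  invisible(path)
}

#' Write a Hermite mesh as legacy-VTK polydata
#'
#' Node positions become POINTS, faces POLYGONS, and the derivative DOF three
#' POINT_DATA FIELD arrays; the template topology is recorded in the header
#' so \code{\link{read_hermite_mesh}} restores the mesh exactly.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param path output .vtk file.
#' @export
write_hermite_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  V <- nrow(mesh$nodes); F <- nrow(mesh$faces)
  # VTK polygon loops: n00, n10, n11, n01 (0-based)
  polys <- apply(mesh$faces[, c(1, 2, 4, 3)] - 1L, 1,
                 function(f) paste(c(4L, f), collapse = " "))
  arr <- function(name, cols)
    c(sprintf("%s 3 %d double", name, V),
      apply(mesh$nodes[, cols, drop = FALSE], 1,
            function(p) paste(.fmt_num(p), collapse = " ")))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("atriashape hermite segments=%d rings=%d",
                       mesh$segments, mesh$rings),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", V),
               apply(mesh$nodes[, 1:3], 1,
                     function(p) paste(.fmt_num(p), collapse = " ")),
               sprintf("POLYGONS %d %d", F, 5L * F), polys,
               sprintf("POINT_DATA %d", V), "FIELD hermite 3",
               arr("deriv_u", 4:6), arr("deriv_v", 7:9),
               arr("deriv_uv", 10:12)), path)
  invisible(path)
}

#' Read a Hermite mesh written by \code{\link{write_hermite_mesh}}
#' @param path .vtk file with deriv_u/deriv_v/deriv_uv point arrays.
#' @return a \code{hermite_mesh}.
#' @export
read_hermite_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("atriashape hermite", lines, value = TRUE)
  if (!length(meta))
    stop("not an atriashape Hermite mesh file (missing topology header)")
  segments <- as.integer(sub(".*segments=(\\d+).*", "\\1", meta[1L]))
  rings <- as.integer(sub(".*rings=(\\d+).*", "\\1", meta[1L]))
  pts <- .read_vtk_points(path)
  V <- nrow(pts)
  if (V != segments * rings + 2L) stop("node count does not match topology header")
  get_field <- function(name) {
    fl <- grep(paste0("^", name, "\\s+3\\s+"), lines)
    if (!length(fl)) stop("missing derivative array: ", name)
    matrix(.scan_numbers(lines, fl[1L] + 1L, 3L * V), ncol = 3L, byrow = TRUE)
  }
  topo <- make_sphere_template(1, segments, rings)
  topo$nodes <- cbind(pts, get_field("deriv_u"), get_field("deriv_v"),
                      get_field("deriv_uv"))
  topo
}

#' Export a triangulated surface to ASCII PLY for visualization
#'
#' Positions-only subdivision of each patch; derivative information is not
#' preserved.
#'
#' @param mesh a \code{hermite_mesh}.
#' @param path output .ply file.
#' @param n_per_face subdivision resolution per patch direction.
#' @export
write_surface_ply <- function(mesh, path, n_per_face = 6L) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  k <- n_per_face
  g <- .face_grid(nrow(mesh$faces), k, k, interior = FALSE)
  P <- evaluate_patch(mesh, g$face, g$u, g$v)
  nf <- nrow(mesh$faces)
  tris <- list()
  for (f in seq_len(nf)) {
    base <- (f - 1L) * k * k
    for (j in seq_len(k - 1L)) for (i in seq_len(k - 1L)) {
      # grid is u-fastest within each face
      a <- base + (j - 1L) * k + i; b <- a + 1L
      c2 <- base + j * k + i; d <- c2 + 1L
      tris[[length(tris) + 1L]] <- c(a, b, d) - 1L
      tris[[length(tris) + 1L]] <- c(a, d, c2) - 1L
    }
  }
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(P)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", length(tris)),
               "property list uchar int vertex_indices", "end_header",
               apply(P, 1, function(p) paste(formatC(p, format = "g", digits = 9),
                                             collapse = " ")),
               vapply(tris, function(t) paste(c(3L, t), collapse = " "), "")),
             path)
  invisible(path)
}
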