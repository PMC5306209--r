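# Shared fixtures built in code: analytic test surfaces and small cohorts.

ellipsoid_mesh <- function(a, b, c, segments = 12L, rings = 11L) {
  mesh_from_parametrization(function(theta, phi)
    cbind(a * sin(phi) * cos(theta), b * sin(phi) * sin(theta),
          -c * cos(phi)), segments, rings)
}

# superior/inferior AP imbalance: y scaled by a smooth ramp g(z)
egg_gamma_ramp <- function(z, gamma, c) 1 + (gamma - 1) * 0.5 * (1 + tanh(z / (0.25 * c)))

egg_mesh <- function(a, b, c, gamma, segments = 12L, rings = 11L) {
  mesh_from_parametrization(function(theta, phi) {
    p <- cbind(a * sin(phi) * cos(theta), b * sin(phi) * sin(theta),
               -c * cos(phi))
    p[, 2] <- p[, 2] * egg_gamma_ramp(p[, 3], gamma, c)
    p
  }, segments, rings)
}

# analytic AP extent of the egg's cross-section at height z
egg_ap_extent <- function(z, a, b, c, gamma)
  2 * b * egg_gamma_ramp(z, gamma, c) * sqrt(pmax(0, 1 - (z / c)^2))

# independent slice-sum oracle for vertical asymmetry, sharing only the slice
# definition (z0, H, n pairs) with the implementation
egg_va_oracle <- function(z0, H, n_pairs, a, b, c, gamma) {
  h <- (seq_len(n_pairs) - 0.5) * H / n_pairs
  sum(egg_ap_extent(z0 + h, a, b, c, gamma) -
      egg_ap_extent(z0 - h, a, b, c, gamma))
}

rotate_mesh <- function(mesh, R, translation = c(0, 0, 0)) {
  for (blk in c(0L, 3L, 6L, 9L))
    mesh$nodes[, blk + 1:3] <- mesh$nodes[, blk + 1:3] %*% t(R)
  mesh$nodes[, 1:3] <- sweep(mesh$nodes[, 1:3], 2, translation, "+")
  mesh
}

rot_z <- function(angle)
  matrix(c(cos(angle), -sin(angle), 0, sin(angle), cos(angle), 0, 0, 0, 1),
         3, 3, byrow = TRUE)

# memoized synthetic cohorts shared across test files
.fixture_env <- new.env()
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(cohort_config(n_subjects = 144L,
                                                         seed = 7L))
  .fixture_env$cohort
}

shared_cohort500 <- function() {
  if (is.null(.fixture_env$cohort500))
    .fixture_env$cohort500 <- generate_cohort(cohort_config(n_subjects = 500L,
                                                            seed = 11L))
  .fixture_env$cohort500
}

# per-mesh markers used in several classification tests
mesh_marker_frame <- function(cohort) {
  key <- paste0("mk", cohort$config$seed, length(cohort$meshes))
  if (is.null(.fixture_env[[key]])) {
    m <- cohort$meshes
    .fixture_env[[key]] <- data.frame(
      subject_id = names(m),
      volume = vapply(m, function(x) surface_integrals(x)$volume, 1),
      ap_radius_mesh = vapply(m, ap_radius_mesh, 1),
      sphericity = vapply(m, function(x) sphericity(sample_surface(x, 8L)), 1),
      vertical_asymmetry = vapply(m, vertical_asymmetry, 1),
      lr_radius = vapply(m, function(x) axis_radii(x)$lr, 1),
      fh_radius = vapply(m, function(x) axis_radii(x)$fh, 1),
      recurrence_12m = cohort$labels$recurrence_12m,
      recurrence_24m = cohort$labels$recurrence_24m,
      censored_24m = cohort$labels$censored_24m)
  }
  .fixture_env[[key]]
}
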