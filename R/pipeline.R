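# End-to-end pipeline: fit -> PCA -> mode selection -> iLDA/oLDA -> markers ->
# recurrence classification, with every stage's parameters captured in a
# RunConfig that is serialized verbatim into the output directory.

#' Pipeline run configuration
#'
#' @param seed RNG seed governing every stochastic stage.
#' @param stiffness,fit_max_iter,fit_tol template-fitting controls.
#' @param pca_threshold reconstruction-error threshold (mm) for
#'   \code{\link{select_num_modes}}.
#' @param olda_min_subset smallest subset size in the oLDA search.
#' @param n_slice_pairs vertical-asymmetry slice pairs.
#' @param slab_halfwidth equatorial slab half-width (mm) for the
#'   segmentation AP radius.
#' @param horizon recurrence horizon, "12m" or "24m".
#' @param fit fit the template to each cloud (TRUE) or use the provided
#'   meshes directly.
#' @param write_meshes also write each fitted mesh as VTK.
#' @return an \code{la_run_config} list.
#' @export
la_run_config <- function(seed = 1L, stiffness = 0.2, fit_max_iter = 30L,
                          fit_tol = 1e-3, pca_threshold = 1,
                          olda_min_subset = 2L, n_slice_pairs = 50L,
                          slab_halfwidth = 2, horizon = "12m",
                          fit = TRUE, write_meshes = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$stiffness >= 0, cfg$pca_threshold > 0,
            cfg$horizon %in% c("12m", "24m"), cfg$olda_min_subset >= 1)
  class(cfg) <- "la_run_config"
  cfg
}

#' Run the full shape-analysis pipeline on a cohort
#'
#' @param cohort an \code{la_cohort} from \code{\link{generate_cohort}}, or a
#'   list with named \code{clouds} (and optionally \code{meshes} when
#'   \code{config$fit} is FALSE) plus a \code{labels} data.frame.
#' @param config an \code{la_run_config}.
#' @param out_dir output directory; created if missing.  The exact
#'   configuration used is written there as \code{config.json}.
#' @return invisibly, a list with the fitted meshes, fit reports, the
#'   \code{la_pca}, selected mode count, discriminant modes, marker table and
#'   the marker-combination search.
#' @export
pipeline_run <- function(cohort, config = la_run_config(), out_dir) {
  stopifnot(inherits(config, "la_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  set.seed(config$seed)
  template <- make_sphere_template()
  clouds <- cohort$clouds
  ids <- names(clouds)
  if (config$fit) {
    fits <- lapply(clouds, function(cl)
      fit_template(cl, template, stiffness = config$stiffness,
                   max_iter = config$fit_max_iter, tol = config$fit_tol))
    meshes <- stats::setNames(lapply(fits, `[[`, "mesh"), ids)
    fit_summary <- data.frame(
      subject_id = ids,
      mean_error = vapply(fits, function(f) f$report$mean_error, 1),
      sd_error = vapply(fits, function(f) f$report$sd_error, 1),
      iterations = vapply(fits, function(f) f$report$iterations, 1L),
      converged = vapply(fits, function(f) f$report$converged, TRUE))
    utils::write.csv(fit_summary, file.path(out_dir, "fit_summary.csv"),
                     row.names = FALSE)
  } else {
    meshes <- cohort$meshes
    fit_summary <- NULL
  }
  if (isTRUE(config$write_meshes)) {
    mdir <- file.path(out_dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    for (id in ids)
      write_hermite_mesh(meshes[[id]], file.path(mdir, paste0(id, ".vtk")))
  }
  pca <- build_pca(lapply(meshes, mesh_to_vector), topology = template)
  k <- select_num_modes(pca, config$pca_threshold)
  utils::write.csv(
    data.frame(mode = seq_along(pca$explained_fraction),
               sd = pca$mode_sd, explained = pca$explained_fraction),
    file.path(out_dir, "pca_summary.csv"), row.names = FALSE)
  labels <- cohort$labels
  ilda <- olda <- NULL
  markers <- compute_marker_table(meshes, clouds,
                                  clinical = labels,
                                  n_slice_pairs = config$n_slice_pairs)
  search <- NULL
  auc_summary <- list(selected_modes = k)
  lab_col <- paste0("recurrence_", config$horizon)
  if (!is.null(labels) && lab_col %in% names(labels)) {
    y <- labels[[lab_col]][match(names(meshes), labels$subject_id)]
    ok <- !is.na(y)
    if (length(unique(y[ok])) == 2L) {
      sub_pca <- build_pca(do.call(rbind, lapply(meshes[ok], mesh_to_vector)),
                           topology = template)
      ilda <- build_ilda(sub_pca, y[ok], max(k, config$olda_min_subset))
      olda <- build_olda(sub_pca, y[ok], max(k, config$olda_min_subset),
                         min_subset = config$olda_min_subset)
      markers$ilda <- markers$olda <- NA_real_
      markers$ilda[match(names(meshes)[ok], markers$subject_id)] <-
        ilda$subject_scores
      markers$olda[match(names(meshes)[ok], markers$subject_id)] <-
        olda$subject_scores
      utils::write.csv(attr(olda, "search_log"),
                       file.path(out_dir, "olda_search_log.csv"),
                       row.names = FALSE)
      search <- marker_combination_search(markers, horizon = config$horizon)
      utils::write.csv(search, file.path(out_dir, "marker_search.csv"),
                       row.names = FALSE)
      auc_summary$olda_subset <- olda$subspace_ids
      auc_summary$olda_loo_auc <- olda$loo_auc
      auc_summary$best_marker_subset <- search$subset[1L]
      auc_summary$best_marker_loo_auc <- search$loo_auc[1L]
      grp_a <- meshes[ok][y[ok] == 1L]; grp_b <- meshes[ok][y[ok] == 0L]
      if (length(grp_a) >= 4L && length(grp_b) >= 4L) {
        nt <- hotelling_per_node(grp_a, grp_b)
        utils::write.csv(nt, file.path(out_dir, "node_tests.csv"),
                         row.names = FALSE)
        auc_summary$n_significant_nodes <- sum(nt$significant)
      }
    } else warning("labels missing or single-class; classification skipped")
  } else warning("no labels supplied; classification skipped")
  utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)
  jsonlite::write_json(auc_summary, file.path(out_dir, "auc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(meshes = meshes, fit_summary = fit_summary, pca = pca,
                 selected_modes = k, ilda = ilda, olda = olda,
                 markers = markers, search = search))
}
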