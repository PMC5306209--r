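# Cohort shape statistics: PCA atlas over shape vectors, reconstruction-error
# mode selection, Fisher LDA in the PCA score space, and the inclusive /
# optimized discriminant modes (iLDA / oLDA).  Modes are unit vectors; the
# per-mode score standard deviations carry the variance.

.as_shape_matrix <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    if (all(vapply(vectors, inherits, TRUE, "hermite_mesh")))
      vectors <- lapply(vectors, mesh_to_vector)
    len <- unique(vapply(vectors, length, 1L))
    if (length(len) != 1L) stop("shape vectors have differing lengths")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors)) stop("expected a matrix or list of shape vectors")
  vectors
}

.position_indices <- function(p) {
  V <- p %/% 12L
  as.vector(outer(1:3, 12L * (seq_len(V) - 1L), "+"))
}

#' Principal component analysis of cohort shape vectors
#'
#' SVD of the row-centered subjects x parameters matrix.  Modes are
#' orthonormal directions in shape space ranked by explained variance; scores
#' reproduce the centered data exactly when all modes are used.
#'
#' @param vectors subjects x parameters matrix, or a list of shape vectors or
#'   \code{hermite_mesh} objects (one per subject).
#' @param topology optional \code{hermite_mesh} giving the template topology;
#'   taken from the input when meshes are supplied.
#' @return an object of class \code{la_pca}: \code{mean_shape}, \code{modes}
#'   (parameters x modes), \code{mode_sd}, \code{explained_fraction},
#'   \code{scores} (subjects x modes).
#' @export
build_pca <- function(vectors, topology = NULL) {
  if (is.list(vectors) && !is.data.frame(vectors) && is.null(topology) &&
      all(vapply(vectors, inherits, TRUE, "hermite_mesh")))
    topology <- vectors[[1L]]
  X <- .as_shape_matrix(vectors)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 subjects")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n, nv = min(n, ncol(X)))
  keep <- sv$d > max(sv$d[1L], 1e-300) * 1e-10
  keep[min(n, ncol(X))] <- keep[min(n, ncol(X))] & FALSE  # centering removes one df
  r <- max(which(keep), 0L)
  if (r == 0L) stop("degenerate cohort: no shape variation")
  modes <- sv$v[, seq_len(r), drop = FALSE]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  structure(list(mean_shape = mu, modes = modes,
                 mode_sd = sv$d[seq_len(r)] / sqrt(n - 1),
                 explained_fraction = sv$d[seq_len(r)]^2 / sum(sv$d^2),
                 scores = scores, n_subjects = n, topology = topology),
            class = "la_pca")
}

#' @export
print.la_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d subjects, %d modes; top modes explain %s\n",
              x$n_subjects, ncol(x$modes),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_fraction, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Reconstruct a subject from the leading k modes
#'
#' @param pca an \code{la_pca}.
#' @param subject subject row index.
#' @param k number of leading modes (0 gives the mean shape).
#' @return a shape vector.
#' @export
reconstruct <- function(pca, subject, k) {
  stopifnot(inherits(pca, "la_pca"))
  if (k < 0L || k > ncol(pca$modes)) stop("k out of range")
  v <- pca$mean_shape
  if (k > 0L)
    v <- v + as.vector(pca$modes[, seq_len(k), drop = FALSE] %*%
                         pca$scores[subject, seq_len(k)])
  v
}

#' Mean node-position distance between two meshes
#'
#' Average Euclidean distance between corresponding node positions;
#' derivative DOF are excluded.
#'
#' @param original,recon \code{hermite_mesh} objects with identical topology.
#' @return mean distance in mm.
#' @export
node_reconstruction_error <- function(original, recon) {
  stopifnot(inherits(original, "hermite_mesh"), inherits(recon, "hermite_mesh"))
  if (!identical(dim(original$nodes), dim(recon$nodes)) ||
      !identical(original$faces, recon$faces))
    stop("meshes have different topology")
  mean(sqrt(rowSums((original$nodes[, 1:3] - recon$nodes[, 1:3])^2)))
}

# cohort-mean node reconstruction error for k = 0..modes (positions only)
.reconstruction_error_curve <- function(pca) {
  pos <- .position_indices(length(pca$mean_shape))
  Rres <- pca$scores %*% t(pca$modes[pos, , drop = FALSE])
  V <- length(pos) / 3L
  nerr <- function(Rm) {
    d <- sqrt(Rm[, seq(1L, 3L * V, by = 3L), drop = FALSE]^2 +
              Rm[, seq(2L, 3L * V, by = 3L), drop = FALSE]^2 +
              Rm[, seq(3L, 3L * V, by = 3L), drop = FALSE]^2)
    mean(rowMeans(d))
  }
  # position components are interleaved x1 y1 z1 x2 ... in pos ordering
  errs <- numeric(ncol(pca$modes) + 1L)
  errs[1L] <- nerr(Rres)
  for (k in seq_len(ncol(pca$modes))) {
    Rres <- Rres - tcrossprod(pca$scores[, k], pca$modes[pos, k])
    errs[k + 1L] <- nerr(Rres)
  }
  errs
}

#' Select the number of PCA modes by reconstruction error
#'
#' Smallest k for which the cohort-mean node-position reconstruction error
#' (per subject, then averaged over subjects) falls below \code{threshold};
#' the full mode count with a warning if the threshold is never reached.
#'
#' @param pca an \code{la_pca} built from 12-DOF shape vectors.
#' @param threshold error threshold in mm (default 1, about half a typical MR
#'   voxel).
#' @return integer mode count.
#' @export
select_num_modes <- function(pca, threshold = 1) {
  stopifnot(inherits(pca, "la_pca"))
  if (threshold <= 0) stop("threshold must be positive")
  errs <- .reconstruction_error_curve(pca)[-1L]  # error after k = 1, 2, ...
  k <- which(errs < threshold)
  if (!length(k)) {
    warning("reconstruction-error threshold never reached; using all modes")
    return(ncol(pca$modes))
  }
  min(k)
}

#' Mean shape of a labelled group
#' @param vectors subjects x parameters matrix or list of shape vectors/meshes.
#' @param labels per-subject labels.
#' @param group the label value selecting the group.
#' @return a shape vector.
#' @export
group_mean_shape <- function(vectors, labels, group) {
  X <- .as_shape_matrix(vectors)
  sel <- which(labels == group)
  if (!length(sel)) stop("empty group")
  colMeans(X[sel, , drop = FALSE])
}

#' Pearson correlation of each PCA mode's scores with a marker
#'
#' The sign is arbitrary (a mode is a direction of change with no preferred
#' sense); magnitudes are the interpretable quantity.
#'
#' @param pca an \code{la_pca}.
#' @param marker_values one value per subject.
#' @return named vector of correlations, one per mode.
#' @export
mode_marker_correlation <- function(pca, marker_values) {
  stopifnot(inherits(pca, "la_pca"))
  if (length(marker_values) != nrow(pca$scores))
    stop("need one marker value per subject")
  if (stats::sd(marker_values) == 0) stop("marker has zero variance")
  rho <- as.vector(stats::cor(pca$scores, marker_values))
  names(rho) <- paste0("mode", seq_along(rho))
  rho
}

.binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels[!is.na(labels)]))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(labels == max(u))
}

# Fisher direction w proportional to Sw^-1 (mu1 - mu0); unit length.  A ridge
# proportional to trace(Sw)/d is added only when Sw is numerically singular.
.fisher_direction <- function(X, y) {
  d <- ncol(X)
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  dm <- m1 - m0
  if (d == 1L) {
    w <- sign(dm); if (w == 0) w <- 1
    return(list(w = w, dm = dm, degenerate = all(dm == 0)))
  }
  X1 <- sweep(X[y == 1L, , drop = FALSE], 2, m1)
  X0 <- sweep(X[y == 0L, , drop = FALSE], 2, m0)
  Sw <- crossprod(X1) + crossprod(X0)
  w <- tryCatch(solve(Sw, dm), error = function(e) {
    solve(Sw + diag(1e-8 * sum(diag(Sw)) / d + 1e-300, d), dm)
  })
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(list(w = c(1, rep(0, d - 1L)), dm = dm, degenerate = TRUE))
  list(w = w / nw, dm = dm, degenerate = all(dm == 0))
}

#' Fisher linear discriminant direction and scores
#'
#' Two-class Fisher LDA: the unit direction proportional to
#' \code{solve(S_w, mu1 - mu0)} with the pooled within-class scatter
#' \code{S_w}, oriented so the positive class has the larger mean score.  A
#' small ridge is added to \code{S_w} only when it is numerically singular.
#'
#' @param x subjects x d feature matrix (a vector is treated as d = 1).
#' @param labels binary labels (the larger value / second factor level /
#'   TRUE is the positive class).
#' @return an \code{la_lda}: \code{direction} (unit d-vector), \code{scores},
#'   \code{fisher_ratio}.
#' @export
fisher_lda <- function(x, labels) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  y <- .binary_labels(labels)
  if (any(is.na(y)) || any(is.na(x))) stop("missing values in LDA input")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fd <- .fisher_direction(x, y)
  if (fd$degenerate)
    warning("identical class means: discriminant direction is degenerate")
  w <- fd$w
  sc <- as.vector(x %*% w)
  if (mean(sc[y == 1L]) < mean(sc[y == 0L])) { w <- -w; sc <- -sc }
  sb <- (mean(sc[y == 1L]) - mean(sc[y == 0L]))^2
  swv <- sum((sc[y == 1L] - mean(sc[y == 1L]))^2) +
         sum((sc[y == 0L] - mean(sc[y == 0L]))^2)
  structure(list(direction = w, scores = sc,
                 fisher_ratio = if (swv > 0) sb / swv else Inf),
            class = "la_lda")
}

# Leave-one-out Fisher decision values by rank-one downdates of the class
# statistics.  The out-of-fold score is the canonical discriminant value
# (x - (mu1 + mu0) / 2)' Sigma^-1 (mu1 - mu0) with Sigma the pooled
# within-class covariance of the training fold, whose log-odds-like units
# make scores comparable across folds when pooled for the LOO AUC.
# Returns NA for folds whose training set loses a class.
.loo_fisher_scores <- function(X, y) {
  n <- nrow(X); d <- ncol(X)
  i1 <- y == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  X1 <- sweep(X[i1, , drop = FALSE], 2, m1)
  X0 <- sweep(X[i0, , drop = FALSE], 2, m0)
  Sw <- crossprod(X1) + crossprod(X0)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (i1[i]) {
      if (n1 <= 1L) next
      mi <- (n1 * m1 - xi) / (n1 - 1L)
      ci <- xi - m1
      Swi <- Sw - (n1 / (n1 - 1L)) * tcrossprod(ci)
      mu1 <- mi; mu0 <- m0
    } else {
      if (n0 <= 1L) next
      mi <- (n0 * m0 - xi) / (n0 - 1L)
      ci <- xi - m0
      Swi <- Sw - (n0 / (n0 - 1L)) * tcrossprod(ci)
      mu1 <- m1; mu0 <- mi
    }
    Sig <- Swi / max(n - 3L, 1L)
    dm <- mu1 - mu0
    w <- tryCatch(solve(Sig, dm), error = function(e)
      solve(Sig + diag(1e-8 * sum(diag(Sig)) / d + 1e-300, d), dm))
    out[i] <- sum((xi - (mu1 + mu0) / 2) * w)
  }
  out
}

.new_dmode <- function(pca, ids, lda, kind) {
  dir_shape <- as.vector(pca$modes[, ids, drop = FALSE] %*% lda$direction)
  structure(list(subspace_ids = ids, direction_pca = lda$direction,
                 direction_shape = dir_shape, subject_scores = lda$scores,
                 kind = kind, score_sd = stats::sd(lda$scores)),
            class = "la_dmode")
}

#' Inclusive discriminant mode (iLDA)
#'
#' Fisher LDA over the scores of all \code{k_selected} leading PCA modes.
#'
#' @param pca an \code{la_pca}.
#' @param labels binary recurrence labels, one per subject.
#' @param k_selected number of leading modes (see
#'   \code{\link{select_num_modes}}).
#' @return an \code{la_dmode} with \code{kind = "inclusive"}.
#' @export
build_ilda <- function(pca, labels, k_selected) {
  stopifnot(inherits(pca, "la_pca"))
  ids <- seq_len(k_selected)
  lda <- fisher_lda(pca$scores[, ids, drop = FALSE], labels)
  .new_dmode(pca, ids, lda, "inclusive")
}

#' Optimized discriminant mode (oLDA) by exhaustive subset search
#'
#' Enumerates every subset of sizes \code{min_subset..k_selected} of the
#' leading \code{k_selected} PCA modes, scores each Fisher combination by
#' leave-one-out AUC, and keeps the subset with the best cross-validated AUC
#' (ties: fewer modes, then lexicographic order).  With the defaults
#' \code{k_selected = 8, min_subset = 2} the search covers 247 combinations;
#' \code{min_subset = 1} gives all 255 non-empty subsets.
#'
#' @inheritParams build_ilda
#' @param min_subset smallest subset size searched (default 2).
#' @return an \code{la_dmode} with \code{kind = "optimized"}; the search log
#'   (one row per subset with resubstitution and LOO AUC) is attached as
#'   \code{attr(, "search_log")}.
#' @export
build_olda <- function(pca, labels, k_selected, min_subset = 2L) {
  stopifnot(inherits(pca, "la_pca"))
  if (k_selected < min_subset) stop("k_selected must be >= min_subset")
  if (min_subset < 1L) stop("min_subset must be >= 1")
  y <- .binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  S <- pca$scores[, seq_len(k_selected), drop = FALSE]
  subsets <- unlist(lapply(min_subset:k_selected, function(sz)
    utils::combn(k_selected, sz, simplify = FALSE)), recursive = FALSE)
  log <- data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                    size = vapply(subsets, length, 1L),
                    resub_auc = NA_real_, loo_auc = NA_real_)
  best <- NULL; best_auc <- -Inf
  for (s in seq_along(subsets)) {
    ids <- subsets[[s]]
    X <- S[, ids, drop = FALSE]
    oof <- .loo_fisher_scores(X, y)
    ok <- !is.na(oof)
    log$loo_auc[s] <- roc_auc(oof[ok], y[ok])$auc
    log$resub_auc[s] <- roc_auc(fisher_lda(X, y)$scores, y)$auc
    if (log$loo_auc[s] > best_auc) { best_auc <- log$loo_auc[s]; best <- ids }
  }
  lda <- fisher_lda(S[, best, drop = FALSE], y)
  dm <- .new_dmode(pca, best, lda, "optimized")
  dm$loo_auc <- best_auc
  attr(dm, "search_log") <- log
  dm
}

#' Synthesize extreme shapes along a discriminant mode
#'
#' Mean shape plus/minus \code{n_sd} standard deviations of the subject
#' scores along the mode's shape-space direction; used to visualize the
#' morphology separating recurrent from non-recurrent atria.
#'
#' @param pca an \code{la_pca}.
#' @param dmode an \code{la_dmode} built from \code{pca}.
#' @param n_sd number of score standard deviations (default 2).
#' @return list with shape vectors \code{plus} and \code{minus}.
#' @export
synthesize_extreme_shapes <- function(pca, dmode, n_sd = 2) {
  stopifnot(inherits(pca, "la_pca"), inherits(dmode, "la_dmode"))
  if (dmode$score_sd == 0) stop("zero-variance discriminant scores")
  step <- n_sd * dmode$score_sd * dmode$direction_shape
  list(plus = pca$mean_shape + step, minus = pca$mean_shape - step)
}
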