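# Recurrence classification: ROC/AUC (Mann-Whitney formulation, ties get half
# credit), leave-one-out cross-validation, exhaustive LDA search over marker
# combinations, Gaussian score-distribution summaries, and per-node Hotelling
# T-squared tests after rigid alignment.

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation; tied scores contribute half.
#' The curve lists the (FPR, TPR) operating points obtained by thresholding
#' the score from above.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels.
#' @return an \code{la_roc}: \code{auc}, \code{thresholds}, \code{fpr},
#'   \code{tpr}, \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels) {
  y <- .binary_labels(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1L), 1)
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0L), 1)
  structure(list(auc = auc, thresholds = c(Inf, thr),
                 fpr = c(0, fp / n0), tpr = c(0, tp / n1),
                 n_pos = n1, n_neg = n0),
            class = "la_roc")
}

#' @export
print.la_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Leave-one-out cross-validation of a score-producing classifier
#'
#' Each subject is scored by a model trained on the other n - 1; the LOO AUC
#' pools these out-of-fold scores.  The resubstitution AUC of the full-data
#' fit is reported alongside as the optimistic reference.  The default
#' classifier is Fisher LDA (computed by fast rank-one downdates); any
#' \code{function(train_x, train_y, test_x)} returning scores can be
#' supplied.  Folds whose training set loses a class are skipped with a
#' warning.
#'
#' @param features subjects x d matrix (or vector for d = 1).
#' @param labels binary labels.
#' @param classifier NULL for Fisher LDA, or a scoring function.
#' @return an \code{la_cv}: \code{scores} (out-of-fold), \code{loo_auc},
#'   \code{resub_auc}.
#' @export
loo_cv <- function(features, labels, classifier = NULL) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  features <- as.matrix(features)
  y <- .binary_labels(labels)
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(classifier)) {
    oof <- .loo_fisher_scores(features, y)
    resub <- fisher_lda(features, y)$scores
  } else {
    oof <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2L) next
      oof[i] <- classifier(features[-i, , drop = FALSE], ytr,
                           features[i, , drop = FALSE])
    }
    resub <- classifier(features, y, features)
  }
  if (anyNA(oof)) warning("some folds skipped (single-class training set)")
  ok <- !is.na(oof)
  structure(list(scores = oof,
                 loo_auc = roc_auc(oof[ok], y[ok])$auc,
                 resub_auc = roc_auc(resub, y)$auc,
                 n_skipped = sum(!ok)),
            class = "la_cv")
}

#' Exhaustive LDA search over marker combinations
#'
#' Evaluates every subset (sizes 1..m) of the chosen markers as an LDA
#' combination under leave-one-out AUC, using for each subset the subjects
#' with complete data for that subset and a non-censored label at the chosen
#' horizon.  63 subsets are evaluated for the standard six markers.
#'
#' @param markers an \code{la_marker_table} (or data.frame) of per-subject
#'   markers and recurrence columns.
#' @param marker_names columns to search over; by default the six study
#'   markers present in the table (volume, mesh AP radius, sphericity,
#'   vertical asymmetry, iLDA, oLDA scores).
#' @param horizon "12m" or "24m" recurrence label.
#' @return data.frame ranked by LOO AUC with columns \code{subset},
#'   \code{size}, \code{n_used}, \code{resub_auc}, \code{loo_auc}.
#' @export
marker_combination_search <- function(markers, marker_names = NULL,
                                      horizon = c("12m", "24m")) {
  horizon <- match.arg(horizon)
  lab_col <- paste0("recurrence_", horizon)
  cen_col <- paste0("censored_", horizon)
  if (!lab_col %in% names(markers)) stop("missing label column: ", lab_col)
  if (is.null(marker_names))
    marker_names <- intersect(c("volume", "ap_radius_mesh", "sphericity",
                                "vertical_asymmetry", "ilda", "olda"),
                              names(markers))
  if (!length(marker_names)) stop("no markers to search over")
  lab <- markers[[lab_col]]
  if (cen_col %in% names(markers)) lab[markers[[cen_col]] %in% TRUE] <- NA
  subsets <- unlist(lapply(seq_along(marker_names), function(sz)
    utils::combn(marker_names, sz, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ids) {
    X <- as.matrix(markers[, ids, drop = FALSE])
    ok <- stats::complete.cases(X) & !is.na(lab)
    res <- data.frame(subset = paste(ids, collapse = "+"), size = length(ids),
                      n_used = sum(ok), resub_auc = NA_real_, loo_auc = NA_real_)
    if (sum(ok) >= 3L && length(unique(lab[ok])) == 2L) {
      cv <- suppressWarnings(loo_cv(X[ok, , drop = FALSE], lab[ok]))
      res$resub_auc <- cv$resub_auc; res$loo_auc <- cv$loo_auc
    }
    res
  })
  out <- do.call(rbind, rows)
  out[order(-out$loo_auc, out$size, out$subset), ]
}

#' Per-group Gaussian fits and their overlap
#'
#' Maximum-likelihood normal fit of the scores in each class, plus the
#' Bhattacharyya coefficient of the two fitted densities as a separation
#' summary (1 = identical distributions, 0 = disjoint).
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return list with per-group \code{mean} and \code{sd} (named vectors) and
#'   \code{overlap}.
#' @export
gaussian_group_fit <- function(scores, labels) {
  y <- .binary_labels(labels)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need at least 2 subjects per group")
  mle_sd <- function(x) sqrt(mean((x - mean(x))^2))
  m <- c(neg = mean(scores[y == 0L]), pos = mean(scores[y == 1L]))
  s <- c(neg = mle_sd(scores[y == 0L]), pos = mle_sd(scores[y == 1L]))
  if (any(s == 0)) stop("zero variance within a group")
  bd <- 0.25 * log(0.25 * (s["pos"]^2 / s["neg"]^2 + s["neg"]^2 / s["pos"]^2 + 2)) +
    0.25 * (m["pos"] - m["neg"])^2 / (s["pos"]^2 + s["neg"]^2)
  list(mean = m, sd = s, overlap = unname(exp(-bd)))
}

# Kabsch rotation + translation aligning X (V x 3) onto ref
.rigid_align <- function(X, ref) {
  cx <- colMeans(X); cr <- colMeans(ref)
  H <- crossprod(sweep(X, 2, cx), sweep(ref, 2, cr))
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(sweep(X, 2, cx) %*% t(R), 2, cr, "+")
}

#' Per-node Hotelling T-squared tests between two mesh groups
#'
#' All meshes are rigidly aligned (rotation + translation, no scaling) to an
#' iterated mean via generalized Procrustes, then each node's 3D positions
#' are compared between groups with a two-sample Hotelling T-squared test and
#' an F-distribution p-value.  No multiple-testing correction is applied by
#' default; a Bonferroni option is available.
#'
#' @param meshes_a,meshes_b lists of \code{hermite_mesh} objects (>= 4 each,
#'   common topology).
#' @param alpha significance level for the per-node flags (default 0.01).
#' @param correction "none" (default) or "bonferroni".
#' @param gpa_iter generalized-Procrustes iterations (default 3).
#' @return data.frame with \code{node}, \code{T2}, \code{p_value},
#'   \code{significant}.
#' @export
hotelling_per_node <- function(meshes_a, meshes_b, alpha = 0.01,
                               correction = c("none", "bonferroni"),
                               gpa_iter = 3L) {
  correction <- match.arg(correction)
  na <- length(meshes_a); nb <- length(meshes_b)
  if (na < 4L || nb < 4L) stop("need at least 4 subjects per group")
  pos <- lapply(c(meshes_a, meshes_b), function(m) m$nodes[, 1:3, drop = FALSE])
  V <- nrow(pos[[1L]])
  if (any(vapply(pos, nrow, 1L) != V)) stop("meshes differ in topology")
  ref <- Reduce(`+`, pos) / length(pos)
  for (it in seq_len(gpa_iter)) {
    pos <- lapply(pos, .rigid_align, ref = ref)
    ref <- Reduce(`+`, pos) / length(pos)
  }
  A <- simplify2array(pos[seq_len(na)])            # V x 3 x na
  B <- simplify2array(pos[na + seq_len(nb)])
  p <- 3L
  T2 <- pv <- numeric(V)
  for (nd in seq_len(V)) {
    Xa <- t(A[nd, , ]); Xb <- t(B[nd, , ])
    ma <- colMeans(Xa); mb <- colMeans(Xb)
    d <- ma - mb
    if (sqrt(sum(d^2)) < 1e-12) { T2[nd] <- 0; pv[nd] <- 1; next }
    Sp <- (crossprod(sweep(Xa, 2, ma)) + crossprod(sweep(Xb, 2, mb))) /
      (na + nb - 2L)
    wi <- tryCatch(solve(Sp, d), error = function(e)
      solve(Sp + diag(1e-10 * sum(diag(Sp)) / p + 1e-300, p), d))
    T2[nd] <- (na * nb / (na + nb)) * sum(d * wi)
    Fst <- (na + nb - p - 1L) / (p * (na + nb - 2L)) * T2[nd]
    pv[nd] <- stats::pf(Fst, p, na + nb - p - 1L, lower.tail = FALSE)
  }
  thr <- if (correction == "bonferroni") alpha / V else alpha
  data.frame(node = seq_len(V), T2 = T2, p_value = pv,
             significant = pv < thr)
}
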