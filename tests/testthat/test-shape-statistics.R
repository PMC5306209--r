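# PCA atlas, mode selection, Fisher LDA and the discriminant-mode builders.

test_that("two subjects give one mode along their difference", {
  v1 <- rnorm(24); v2 <- rnorm(24)
  pca <- build_pca(rbind(v1, v2))
  expect_identical(ncol(pca$modes), 1L)
  dir <- (v2 - v1) / sqrt(sum((v2 - v1)^2))
  expect_equal(abs(sum(pca$modes[, 1] * dir)), 1, tolerance = 1e-9)
  expect_error(build_pca(rbind(v1)), "2 subjects")
})

test_that("a generic cohort yields n - 1 modes with orthonormal directions", {
  set.seed(21)
  X <- matrix(rnorm(144 * 1608), 144)
  pca <- build_pca(X)
  expect_identical(ncol(pca$modes), 143L)
  G <- crossprod(pca$modes)
  expect_lt(max(abs(G - diag(143))), 1e-8)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
})

test_that("reconstruction with all modes is exact and k = 0 gives the mean", {
  set.seed(22)
  X <- matrix(rnorm(12 * 60), 12)
  pca <- build_pca(X)
  for (s in c(1L, 7L)) {
    expect_equal(reconstruct(pca, s, ncol(pca$modes)), unname(X[s, ]),
                 tolerance = 1e-8)
    expect_equal(reconstruct(pca, s, 0L), unname(colMeans(X)), tolerance = 1e-12)
  }
  expect_error(reconstruct(pca, 1, 99), "range")
})

test_that("reconstruction residuals shrink with every added mode", {
  set.seed(23)
  tpl <- make_sphere_template(20, 6, 4)
  meshes <- lapply(1:10, function(i) {
    m <- tpl
    m$nodes[, 1:3] <- m$nodes[, 1:3] + matrix(rnorm(26 * 3, 0, 2), 26)
    m
  })
  pca <- build_pca(meshes)
  X <- do.call(rbind, lapply(meshes, mesh_to_vector))
  # orthogonality: the full-vector residual norm is non-increasing in k
  # for every subject
  for (s in c(2L, 9L)) {
    errs <- vapply(0:ncol(pca$modes), function(k)
      sqrt(sum((X[s, ] - reconstruct(pca, s, k))^2)), 1)
    expect_true(all(diff(errs) <= 1e-9))
  }
  # and the cohort-mean node-position error curve is non-increasing for a
  # structured cohort
  curve <- atriashape:::.reconstruction_error_curve(pca)
  expect_true(all(diff(curve) <= 1e-6))
})

test_that("node error matches direct formulas and a sampling oracle", {
  tpl <- make_sphere_template()
  expect_identical(node_reconstruction_error(tpl, tpl), 0)
  shifted <- transform_mesh(tpl, translation = c(0, 0, 1))
  expect_equal(node_reconstruction_error(tpl, shifted), 1, tolerance = 1e-12)
  # isotropic N(0, sigma^2) perturbations: mean chi_3 distance = 2 sigma sqrt(2/pi)
  set.seed(24)
  sigma <- 0.7
  errs <- replicate(40, {
    m <- tpl
    m$nodes[, 1:3] <- m$nodes[, 1:3] + matrix(rnorm(134 * 3, 0, sigma), 134)
    node_reconstruction_error(tpl, m)
  })
  expect_equal(mean(errs), sigma * 2 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("mode selection recovers a planted rank-3 cohort", {
  set.seed(25)
  tpl <- make_sphere_template()
  V <- 134L
  base <- mesh_to_vector(tpl)
  dirs <- qr.Q(qr(matrix(rnorm(3 * 12 * V), 12 * V, 3)))
  scores <- matrix(rnorm(40 * 3), 40) %*% diag(c(90, 55, 35))
  X <- matrix(base, 40, 12 * V, byrow = TRUE) + scores %*% t(dirs) +
    matrix(rnorm(40 * 12 * V, 0, 0.01), 40)
  pca <- build_pca(X)
  expect_identical(select_num_modes(pca, threshold = 1), 3L)
  # a loose threshold is satisfied by the first mode alone
  expect_identical(select_num_modes(pca, threshold = 1e3), 1L)
  expect_error(select_num_modes(pca, threshold = -1), "positive")
})

test_that("fisher_lda matches the closed form and beats random directions", {
  set.seed(26)
  n <- 2000
  X <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 1), rnorm(n, 0, 1))
  y <- rep(c(0, 1), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 2.5
  lda <- fisher_lda(X, y)
  ang <- acos(abs(sum(lda$direction * c(1, 0, 0)))) * 180 / pi
  expect_lt(ang, 5)
  expect_gt(mean(lda$scores[y == 1]), mean(lda$scores[y == 0]))
  # brute-force oracle: 10,000 random unit directions never beat the
  # closed form's Fisher ratio
  fisher_ratio <- function(w) {
    s <- X %*% w
    (mean(s[y == 1]) - mean(s[y == 0]))^2 /
      (sum((s[y == 1] - mean(s[y == 1]))^2) + sum((s[y == 0] - mean(s[y == 0]))^2))
  }
  W <- matrix(rnorm(3 * 10000), 3)
  W <- W / rep(sqrt(colSums(W^2)), each = 3)
  best_random <- max(apply(W, 2, fisher_ratio))
  expect_lt(best_random, lda$fisher_ratio + 1e-6)
})

test_that("degenerate and one-dimensional LDA inputs are handled", {
  set.seed(27)
  X <- matrix(rnorm(40), 20)
  expect_warning(fisher_lda(rbind(X, X), rep(c(0, 1), each = 20)), "degenerate")
  expect_error(fisher_lda(X, rep(1, 20)), "classes")
  x1 <- c(rnorm(10), rnorm(10, 3))
  l1 <- fisher_lda(x1, rep(c(0, 1), each = 10))
  expect_equal(abs(l1$direction), 1)
  expect_equal(l1$scores, x1 * l1$direction)
})

test_that("iLDA concentrates on the separating mode of a planted cohort", {
  set.seed(28)
  n <- 200
  S <- cbind(rnorm(n, 0, 8), rnorm(n, 0, 4), rnorm(n, 0, 2))
  y <- rep(c(0, 1), each = n / 2)
  S[y == 1, 2] <- S[y == 1, 2] + 6
  modes <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  X <- matrix(rnorm(60), n, 60, byrow = TRUE) + S %*% t(modes)
  pca <- build_pca(X)
  dm <- build_ilda(pca, y, 3L)
  expect_identical(dm$kind, "inclusive")
  expect_gt(abs(dm$direction_pca[2]), 0.9)
  expect_equal(sqrt(sum(dm$direction_pca^2)), 1, tolerance = 1e-9)
  # subject scores are the projection of the subspace scores
  expect_equal(dm$subject_scores,
               as.vector(pca$scores[, 1:3] %*% dm$direction_pca),
               tolerance = 1e-9)
})

test_that("labels independent of shape give chance-level iLDA performance", {
  set.seed(29)
  X <- matrix(rnorm(200 * 20), 200)
  pca <- build_pca(X)
  y <- rep(c(0, 1), 100)
  dm <- build_ilda(pca, y, 5L)
  cv <- loo_cv(pca$scores[, 1:5], y)
  expect_gt(cv$loo_auc, 0.35)
  expect_lt(cv$loo_auc, 0.65)
})

test_that("oLDA search enumerates the documented subset counts", {
  set.seed(30)
  X <- matrix(rnorm(40 * 30), 40)
  pca <- build_pca(X)
  y <- rep(c(0, 1), 20)
  o2 <- build_olda(pca, y, 8L, min_subset = 2L)
  expect_identical(nrow(attr(o2, "search_log")), 247L)
  o1 <- build_olda(pca, y, 8L, min_subset = 1L)
  expect_identical(nrow(attr(o1, "search_log")), 255L)
  # winner attains the maximum logged LOO AUC
  expect_equal(o2$loo_auc, max(attr(o2, "search_log")$loo_auc))
  expect_identical(o2$kind, "optimized")
})

test_that("oLDA recovers a planted two-mode separation", {
  set.seed(31)
  hits <- 0L
  for (r in 1:10) {
    n <- 200
    sds <- c(8, 5, 3.5, 2.5, 2)
    S <- sapply(sds, function(s) rnorm(n, 0, s))
    y <- rep(c(0, 1), each = n / 2)
    S[y == 1, 1] <- S[y == 1, 1] + 4.5
    S[y == 1, 3] <- S[y == 1, 3] + 2.2
    modes <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
    X <- S %*% t(modes)
    pca <- build_pca(X)
    dm <- build_olda(pca, y, 5L)
    if (all(c(1L, 3L) %in% dm$subspace_ids)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("extreme shapes are mirror images reaching +/- n_sd along the mode", {
  set.seed(32)
  X <- matrix(rnorm(30 * 50), 30)
  pca <- build_pca(X)
  y <- rep(c(0, 1), 15)
  dm <- build_ilda(pca, y, 4L)
  ext <- synthesize_extreme_shapes(pca, dm, n_sd = 2)
  expect_equal(pca$mean_shape - ext$minus, ext$plus - pca$mean_shape,
               tolerance = 1e-10)
  proj <- sum((ext$plus - pca$mean_shape) * dm$direction_shape)
  expect_equal(proj, 2 * dm$score_sd, tolerance = 1e-8)
  ext0 <- synthesize_extreme_shapes(pca, dm, n_sd = 0)
  expect_equal(ext0$plus, pca$mean_shape, tolerance = 1e-12)
  expect_equal(ext0$minus, pca$mean_shape, tolerance = 1e-12)
})

test_that("group means behave like arithmetic means", {
  X <- matrix(rnorm(5 * 8), 5)
  lab <- c("a", "b", "a", "b", "b")
  expect_equal(group_mean_shape(X, lab, "a"), colMeans(X[c(1, 3), ]))
  expect_equal(group_mean_shape(X[1, , drop = FALSE], "a", "a"), X[1, ])
  gm <- (2 * group_mean_shape(X, lab, "a") + 3 * group_mean_shape(X, lab, "b")) / 5
  expect_equal(gm, colMeans(X), tolerance = 1e-12)
  expect_error(group_mean_shape(X, lab, "c"), "empty")
})

test_that("mode-marker correlation flags its trivial and null cases", {
  set.seed(33)
  X <- matrix(rnorm(144 * 40), 144)
  pca <- build_pca(X)
  expect_equal(abs(mode_marker_correlation(pca, pca$scores[, 1])[[1]]), 1,
               tolerance = 1e-9)
  rho <- mode_marker_correlation(pca, rnorm(144))
  expect_lt(abs(rho[1]), 0.25)
  expect_error(mode_marker_correlation(pca, rep(1, 144)), "variance")
})
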