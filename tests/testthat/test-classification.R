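# ROC/AUC, leave-one-out cross-validation, marker-combination search,
# Gaussian group fits and the per-node Hotelling tests.

test_that("AUC equals the hand-counted concordant-pair fraction", {
  # pos scores {2, 4} vs neg {1, 3}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  # ties contribute half
  expect_equal(roc_auc(c(1, 1), c(0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  s <- rnorm(300)
  y <- rbinom(300, 1, plogis(1.5 * s))
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-12)
})

test_that("AUC is antisymmetric and invariant to monotone transforms", {
  set.seed(42)
  s <- rnorm(100); y <- rbinom(100, 1, plogis(s))
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(-s, y)$auc, 1 - a, tolerance = 1e-12)
  expect_equal(roc_auc(exp(2 * s) + 5, y)$auc, a, tolerance = 1e-12)
  # permuted labels drift to chance at large n
  set.seed(43)
  yp <- sample(y)
  expect_lt(abs(roc_auc(s, yp)$auc - 0.5), 0.12)
})

test_that("the ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(44)
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.4))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
})

test_that("LOO cross-validation separates signal from noise", {
  set.seed(45)
  y <- rep(c(0, 1), 100)
  noise <- rnorm(200)
  cvn <- loo_cv(noise, y)
  expect_gt(cvn$loo_auc, 0.4); expect_lt(cvn$loo_auc, 0.6)
  signal <- y + rnorm(200, 0, 0.2)
  expect_gt(loo_cv(signal, y)$loo_auc, 0.95)
  # deterministic given fixed inputs
  expect_identical(loo_cv(noise, y)$scores, cvn$scores)
})

test_that("resubstitution AUC is optimistic relative to LOO on null data", {
  set.seed(46)
  gaps <- replicate(100, {
    X <- matrix(rnorm(30 * 3), 30)
    y <- rep(c(0, 1), 15)
    cv <- loo_cv(X, y)
    cv$resub_auc - cv$loo_auc
  })
  expect_gt(mean(gaps), 0)
})

test_that("LOO downdating matches a brute-force refit of every fold", {
  set.seed(47)
  X <- matrix(rnorm(36 * 3), 36)
  y <- rep(c(0L, 1L), 18)
  fast <- atriashape:::.loo_fisher_scores(X, y)
  slow <- vapply(seq_len(36), function(i) {
    tr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    m1 <- colMeans(tr[ytr == 1, ]); m0 <- colMeans(tr[ytr == 0, ])
    Sw <- crossprod(sweep(tr[ytr == 1, ], 2, m1)) +
      crossprod(sweep(tr[ytr == 0, ], 2, m0))
    w <- solve(Sw / (nrow(tr) - 2), m1 - m0)
    sum((X[i, ] - (m1 + m0) / 2) * w)
  }, 1)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("a custom classifier function is cross-validated fold by fold", {
  set.seed(48)
  X <- matrix(rnorm(30), 30)
  y <- rep(c(0, 1), 15)
  cv <- loo_cv(X, y, classifier = function(tx, ty, nx) nx[, 1])
  expect_equal(cv$scores, X[, 1])
})

test_that("the marker search enumerates 63 subsets and singletons reduce to raw AUC", {
  set.seed(49)
  n <- 60
  mk <- data.frame(subject_id = as.character(1:n),
                   volume = rnorm(n), ap_radius_mesh = rnorm(n),
                   sphericity = rnorm(n), vertical_asymmetry = rnorm(n),
                   ilda = rnorm(n), olda = rnorm(n),
                   recurrence_12m = rep(c(0, 1), n / 2))
  sr <- marker_combination_search(mk, horizon = "12m")
  expect_identical(nrow(sr), 63L)
  expect_true(all(sr$n_used == n))
  one <- sr[sr$subset == "sphericity", ]
  raw <- roc_auc(mk$sphericity, mk$recurrence_12m)$auc
  expect_equal(one$resub_auc, max(raw, 1 - raw), tolerance = 1e-9)
})

test_that("per-subset complete-case handling mirrors varying cohort sizes", {
  set.seed(50)
  n <- 40L
  mk <- data.frame(subject_id = as.character(1:n),
                   sphericity = rnorm(n), volume = rnorm(n),
                   recurrence_12m = rep(c(0, 1), n / 2))
  mk$volume[1:6] <- NA
  sr <- marker_combination_search(mk, marker_names = c("sphericity", "volume"))
  expect_identical(sr$n_used[sr$subset == "sphericity"], n)
  expect_identical(sr$n_used[sr$subset == "volume"], n - 6L)
  expect_identical(sr$n_used[sr$subset == "sphericity+volume"], n - 6L)
})

test_that("Gaussian group fits recover parameters and rank separation", {
  set.seed(51)
  y <- rep(c(0, 1), each = 500)
  s_same <- rnorm(1000)
  expect_equal(gaussian_group_fit(s_same, y)$overlap, 1, tolerance = 0.05)
  s_far <- c(rnorm(500, 0, 1), rnorm(500, 50, 1))
  expect_lt(gaussian_group_fit(s_far, y)$overlap, 1e-6)
  s <- c(rnorm(500, 1, 2), rnorm(500, 3, 4))
  fit <- gaussian_group_fit(s, y)
  expect_equal(unname(fit$mean), c(1, 3), tolerance = 0.3)
  expect_equal(unname(fit$sd), c(2, 4), tolerance = 0.3)
  expect_error(gaussian_group_fit(rep(1, 10), rep(c(0, 1), 5)), "variance")
})

test_that("identical mesh groups give zero T-squared everywhere", {
  tpl <- make_sphere_template(20, 6, 4)
  set.seed(52)
  grp <- replicate(5, {
    m <- tpl
    m$nodes[, 1:3] <- m$nodes[, 1:3] + matrix(rnorm(26 * 3), 26)
    m
  }, simplify = FALSE)
  nt <- hotelling_per_node(grp, grp)
  expect_true(all(nt$T2 == 0))
  expect_true(all(!nt$significant))
})

test_that("a planted node displacement is detected at the null rate elsewhere", {
  set.seed(53)
  tpl <- make_sphere_template(20, 6, 4)
  mk <- function(shift5 = 0) {
    m <- tpl
    m$nodes[, 1:3] <- m$nodes[, 1:3] + matrix(rnorm(26 * 3, 0, 0.5), 26)
    m$nodes[5, 1] <- m$nodes[5, 1] + shift5
    m
  }
  hits5 <- 0L; other <- 0
  for (r in 1:20) {
    a <- replicate(10, mk(), simplify = FALSE)
    b <- replicate(10, mk(shift5 = 5), simplify = FALSE)  # 10 x noise sd
    nt <- hotelling_per_node(a, b)
    hits5 <- hits5 + nt$significant[5]
    other <- other + mean(nt$significant[-5])
  }
  expect_gte(hits5, 19L)
  expect_lt(other / 20, 0.06)
})

test_that("node-test flags are invariant to a global rigid motion", {
  set.seed(54)
  tpl <- make_sphere_template(20, 6, 4)
  mk <- function(gamma_bias = 0) {
    m <- tpl
    m$nodes[, 1:3] <- m$nodes[, 1:3] + matrix(rnorm(26 * 3, 0, 0.8), 26)
    m$nodes[, 3] <- m$nodes[, 3] * (1 + gamma_bias)
    m
  }
  a <- replicate(8, mk(), simplify = FALSE)
  b <- replicate(8, mk(0.08), simplify = FALSE)
  nt1 <- hotelling_per_node(a, b)
  R <- rot_z(0.7)
  a2 <- lapply(a, rotate_mesh, R = R, translation = c(5, -3, 11))
  b2 <- lapply(b, rotate_mesh, R = R, translation = c(5, -3, 11))
  nt2 <- hotelling_per_node(a2, b2)
  expect_equal(nt1$T2, nt2$T2, tolerance = 1e-6)
  expect_identical(nt1$significant, nt2$significant)
})
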