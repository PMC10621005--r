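make_signature_data <- function(n = 60, p = 6, sep = FALSE, seed = 60) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  if (sep) X[, 1] <- as.numeric(y) * 6 + rnorm(n, sd = 0.01)
  list(X = X, y = y)
}

test_that("a separating feature gives mean AUC 1 through (0,1)", {
  d <- make_signature_data(sep = TRUE)
  plan <- cv_plan(d$y, folds = 5, repeats = 2, seed = 61)
  rep_ <- cv_signature_auc(d$X, d$y, plan, m = 3)
  expect_equal(rep_$mean_auc, 1)
  expect_equal(rep_$mean_roc$tpr[rep_$mean_roc$fpr == 0], 1)
})

test_that("signature report identities hold", {
  d <- make_signature_data(n = 50)
  plan <- cv_plan(d$y, folds = 5, repeats = 3, seed = 62)
  rep_ <- cv_signature_auc(d$X, d$y, plan, m = 4)
  expect_equal(rep_$mean_auc, mean(rep_$fold_aucs))
  expect_length(rep_$fold_aucs, 15)
  expect_true(all(rep_$fold_aucs >= 0 & rep_$fold_aucs <= 1))
  tpr <- rep_$mean_roc$tpr
  expect_true(all(diff(tpr) >= -1e-12))
  expect_equal(tpr[length(tpr)], 1)
  # determinism
  rep2 <- cv_signature_auc(d$X, d$y, plan, m = 4)
  expect_identical(rep_$fold_aucs, rep2$fold_aucs)
})

test_that("all-noise features produce chance-level AUC", {
  aucs <- vapply(1:8, function(s) {
    d <- make_signature_data(n = 100, p = 8, seed = 1000 + s)
    plan <- cv_plan(d$y, folds = 5, repeats = 4, seed = 1000 + s)
    cv_signature_auc(d$X, d$y, plan, m = 4)$mean_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.02)
})

test_that("train/validate evaluates with discovery-learned parameters", {
  d <- make_signature_data(sep = TRUE)
  rep_ <- train_validate(d$X, d$y, d$X, d$y, features = colnames(d$X))
  expect_equal(rep_$validation$auc, 1)
  expect_error(train_validate(d$X, d$y, d$X[, 1:3], d$y,
                              features = colnames(d$X)),
               "missing in validation")
  # permuted validation labels: chance level
  set.seed(63)
  aucs <- vapply(1:20, function(i) {
    train_validate(d$X, d$y, d$X, sample(d$y), features = colnames(d$X))$validation$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(20) + 0.02)
})

test_that("feature-set comparison shares fold assignments and ranks sets sensibly", {
  sub <- default_subset_params()
  cfg <- sim_config(n_discovery = 90, n_validation = 40, subsets = sub,
                    seed = 64)
  coh <- generate_cohort(cfg)
  disc <- coh$records$cohort == "discovery"
  reports <- compare_feature_sets(
    coh$proportions[disc, ], coh$records[disc, ],
    coh$proportions[!disc, ], coh$records[!disc, ],
    features = headline_subsets(), cfg = analysis_config(seed = 64,
                                                         cv_repeats = 3))
  expect_named(reports, c("cytof_18", "age_sex", "combined"))
  expect_length(reports$cytof_18$fold_aucs, length(reports$age_sex$fold_aucs))
  # subsets carry signal beyond age/sex in this configuration
  expect_gte(reports$combined$mean_auc, reports$age_sex$mean_auc)
  expect_gt(reports$cytof_18$mean_auc, 0.5)
  expect_gt(reports$cytof_18$validation$auc, 0.5)
})

test_that("when only age carries signal the immune set lags", {
  sub <- default_subset_params()
  sub$delta <- 0
  sub$gamma <- 0
  wins <- vapply(1:6, function(s) {
    cfg <- sim_config(n_discovery = 90, n_validation = 0, subsets = sub,
                      beta_age = 1.5, beta_sex = 0, seed = 1100 + s)
    coh <- generate_cohort(cfg)
    reports <- compare_feature_sets(
      coh$proportions, coh$records, features = headline_subsets(),
      cfg = analysis_config(seed = 1100 + s, cv_repeats = 2))
    reports$age_sex$mean_auc > reports$cytof_18$mean_auc
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("PCA projection agrees across algorithms and reconstructs rank-2 data", {
  set.seed(65)
  n <- 30; p <- 8
  basis <- matrix(rnorm(2 * p), 2, p)
  scores <- matrix(rnorm(n * 2), n, 2)
  X2 <- scores %*% basis
  X2 <- sweep(X2, 2, apply(X2, 2, sd) + 0.5, `/`) # keep nonzero variance
  colnames(X2) <- paste0("f", 1:p)
  pca <- fit_pca_project(X2)
  Xs <- scale(X2, pca$center, pca$scale)
  recon <- pca$scores_d %*% t(pca$loadings)
  expect_lt(max(abs(recon - Xs)) / max(abs(Xs)), 1e-8)

  # two-algorithm agreement: svd route vs eigendecomposition route
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  pca2 <- fit_pca_project(X)
  ev <- eigen(cor(X))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pca2$loadings[, j]), v, tolerance = 1e-8)
  }

  # permutation equivariance and discovery-only parameters for validation
  perm <- sample(nrow(X))
  pca3 <- fit_pca_project(X[perm, ])
  expect_equal(abs(pca3$scores_d), abs(pca2$scores_d[perm, ]),
               tolerance = 1e-6, ignore_attr = TRUE)
  pca4 <- fit_pca_project(X, X + 100)
  expect_equal(pca4$scores_v,
               scale(X + 100, pca4$center, pca4$scale) %*% pca4$loadings,
               ignore_attr = TRUE)

  Xz <- X; Xz[, 2] <- 3
  expect_error(fit_pca_project(Xz), "zero-variance feature: g2")
})

test_that("back-mapping on rank-2 data reduces to the exact linear inverse", {
  set.seed(66)
  n <- 40; p <- 6
  basis <- matrix(rnorm(2 * p), 2, p)
  X <- matrix(rnorm(n * 2), n, 2) %*% basis
  colnames(X) <- paste0("f", 1:p)
  y <- X[, 1] > median(X[, 1])
  model <- cadimmune:::svm_fit(X, y)
  res <- suppressWarnings(boundary_map(model, X, grid_n = 25, seed = 66))
  expect_true(res$map$used_fallback)
  # mapped grid equals the rank-2 inverse map loadings^T within RMSE 1e-3
  grid <- as.matrix(expand.grid(PC1 = res$map$pc1, PC2 = res$map$pc2))
  closed <- grid %*% t(res$pca$loadings)
  expect_lt(sqrt(mean((res$map$mapped_features - closed)^2)), 1e-3)
})

test_that("boundary maps are deterministic and separate a linear direction", {
  set.seed(67)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] + 0.1 * rnorm(n) > 0
  model <- cadimmune:::svm_fit(X, y)
  m1 <- boundary_map(model, X, grid_n = 30, seed = 5)
  m2 <- boundary_map(model, X, grid_n = 30, seed = 5)
  expect_identical(m1$map$decision, m2$map$decision)
  expect_setequal(unique(as.vector(m1$map$class)), c(TRUE, FALSE))
  # grid covers all projected points with margin
  pts <- rbind(m1$pca$scores_d)
  expect_true(min(m1$map$pc1) < min(pts[, 1]) && max(m1$map$pc1) > max(pts[, 1]))
})
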