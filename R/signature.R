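# Radial-kernel SVM immune signature on the age-selected sub-cohort:
# repeated-CV ROC/AUC in discovery, train-on-all/evaluate-on-validation,
# feature-set comparison, and the PCA decision-boundary map with a neural
# back-mapping of the PC grid into feature space.

FPR_GRID <- seq(0, 1, by = 0.01)

# Radial SVM on standardised features; scores oriented so the positive
# class has the higher decision value (orientation fixed on training data).
svm_fit <- function(X, y, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- scale(X, mu, sd_)
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  yf <- factor(as.logical(y), levels = c(FALSE, TRUE))
  fit <- e1071::svm(Xs, yf, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  # e1071 assigns positive decision values to its first encountered class;
  # fix orientation using training scores
  tr_dec <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                            "decision.values"))
  flip <- mean(tr_dec[as.logical(y)]) < mean(tr_dec[!as.logical(y)])
  structure(list(fit = fit, mu = mu, sd = sd_, flip = flip,
                 cost = cost, gamma = gamma, features = colnames(X)),
            class = "cad_svm")
}

# Signed decision score for new raw-scale data (higher = more CAD-like).
svm_score <- function(model, Xnew) {
  Xs <- scale(as.matrix(Xnew), model$mu, model$sd)
  dec <- as.numeric(attr(stats::predict(model$fit, Xs, decision.values = TRUE),
                         "decision.values"))
  if (model$flip) -dec else dec
}

new_signature_report <- function(feature_set, fold_aucs, mean_roc,
                                 validation = NULL) {
  structure(list(feature_set = feature_set, fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs),
                 mean_roc = data.frame(fpr = FPR_GRID, tpr = mean_roc),
                 validation = validation),
            class = "signature_report")
}

#' Repeated-CV ROC/AUC of the radial SVM signature
#'
#' Per repeat and fold: optionally screen the top `m` features by AUC on
#' the training split, standardise by training statistics, fit a
#' radial-kernel SVM (cost 1, kernel width 1/p on standardised features),
#' score held-out samples by signed decision value, and compute the fold
#' ROC by threshold sweep with AUC by the rank formulation. Fold ROCs are
#' averaged vertically (mean TPR at a fixed FPR grid, step 0.01) and the
#' mean AUC is the arithmetic mean of per-fold AUCs. Folds whose held-out
#' split lacks a class are re-drawn as in classifiability.
#'
#' @param X Feature matrix (sub-cohort patients x features).
#' @param y Binary outcome.
#' @param plan A [cv_plan()] built on `y`.
#' @param m Features screened per fold; `NULL` uses all columns.
#' @param cost,gamma SVM hyperparameters (defaults: cost 1, gamma 1/p).
#' @param rank_key Screening key, see [screen_by_auc()].
#' @param feature_set Label stored in the report.
#' @return A `"signature_report"`: per-fold AUCs, their mean, and the
#'   vertically averaged ROC.
#' @export
cv_signature_auc <- function(X, y, plan, m = 18L, cost = 1, gamma = NULL,
                             rank_key = c("abs", "raw"),
                             feature_set = "cytof_18") {
  rank_key <- match.arg(rank_key)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y), length(y) >= 25,
            ncol(plan$assignment) == length(y))
  if (!is.null(m)) stopifnot(m <= ncol(X))
  fold_aucs <- numeric(0)
  tpr_sum <- numeric(length(FPR_GRID))
  k <- 0
  for (r in seq_len(plan$repeats)) {
    assign_r <- plan$assignment[r, ]
    for (attempt in seq_len(10)) {
      ok <- all(vapply(seq_len(plan$folds), function(f) {
        length(unique(y[assign_r == f])) == 2 &&
          length(unique(y[assign_r != f])) == 2
      }, TRUE))
      if (ok) break
      message("re-drawing fold assignment for repeat ", r,
              " (single-class fold)")
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(plan$seed, sprintf("svm_redraw_%d_%d", r, attempt)))
      assign_r <- draw_fold_assignment(y, plan$folds, plan$stratified)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
    for (f in seq_len(plan$folds)) {
      test <- assign_r == f
      sel <- if (is.null(m)) seq_len(ncol(X))
             else screen_by_auc(X[!test, , drop = FALSE], y[!test], m, rank_key)
      model <- svm_fit(X[!test, sel, drop = FALSE], y[!test],
                       cost = cost, gamma = gamma)
      scores <- svm_score(model, X[test, sel, drop = FALSE])
      roc <- roc_points(scores, y[test])
      fold_aucs <- c(fold_aucs, auc_rank(scores, y[test]))
      tpr_sum <- tpr_sum + roc_on_grid(roc, FPR_GRID)
      k <- k + 1
    }
  }
  new_signature_report(feature_set, fold_aucs, tpr_sum / k)
}

#' Train the signature on discovery, evaluate on validation
#'
#' Fits the radial SVM on the whole discovery sub-cohort using a fixed
#' feature list (by default the subsets flagged significant by the
#' differential panel), with standardisation learned on discovery only,
#' then computes the ROC and AUC on the validation sub-cohort.
#'
#' @param Xd,yd Discovery features and outcome.
#' @param Xv,yv Validation features and outcome.
#' @param features Character vector of feature columns used (must exist in
#'   both matrices); `NULL` uses all shared columns of `Xd`.
#' @param cost,gamma SVM hyperparameters.
#' @return A `"signature_report"` whose `validation` element holds the
#'   validation `auc`, `roc` and the fitted `model`.
#' @export
train_validate <- function(Xd, yd, Xv, yv, features = NULL,
                           cost = 1, gamma = NULL) {
  if (is.null(features)) features <- colnames(Xd)
  missing_v <- setdiff(features, colnames(Xv))
  if (length(missing_v) > 0) {
    stop("feature(s) missing in validation matrix: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  missing_d <- setdiff(features, colnames(Xd))
  if (length(missing_d) > 0) {
    stop("feature(s) missing in discovery matrix: ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  }
  model <- svm_fit(Xd[, features, drop = FALSE], yd, cost = cost, gamma = gamma)
  scores <- svm_score(model, Xv[, features, drop = FALSE])
  roc <- roc_points(scores, yv)
  new_signature_report(
    "train_validate", auc_rank(scores, yv), roc_on_grid(roc, FPR_GRID),
    validation = list(auc = auc_rank(scores, yv), roc = roc,
                      scores = scores, model = model))
}

#' Compare immune-signature, age/sex and combined feature sets
#'
#' Builds three design matrices — the fixed immune subset signature, age
#' plus a male indicator, and their combination — and evaluates each with
#' an identical CV plan (same seed, so fold assignments coincide) on the
#' discovery sub-cohort, plus train-on-discovery / evaluate-on-validation
#' when a validation cohort is supplied.
#'
#' @param prop_d,records_d Discovery proportions matrix and patient table
#'   (already restricted to the sub-cohort).
#' @param prop_v,records_v Validation equivalents (`NULL` to skip).
#' @param features Signature subset ids.
#' @param cfg An [analysis_config()] (CV geometry and seed).
#' @return Named list of `"signature_report"`s: `cytof_18`, `age_sex`,
#'   `combined`, each with a `validation` element when applicable.
#' @export
compare_feature_sets <- function(prop_d, records_d, prop_v = NULL,
                                 records_v = NULL, features,
                                 cfg = analysis_config()) {
  yd <- cad_status(records_d)
  design <- function(prop, records) {
    list(
      cytof_18 = prop[, features, drop = FALSE],
      age_sex = cbind(age = records$age,
                      male = as.numeric(records$sex == "male")),
      combined = cbind(prop[, features, drop = FALSE],
                       age = records$age,
                       male = as.numeric(records$sex == "male"))
    )
  }
  Xd <- design(prop_d, records_d)
  Xv <- if (!is.null(prop_v)) design(prop_v, records_v)
  plan <- cv_plan(yd, folds = cfg$cv_folds, repeats = cfg$cv_repeats,
                  stratified = TRUE, seed = derive_seed(cfg$seed, "signature"))
  out <- lapply(names(Xd), function(fs) {
    rep_ <- cv_signature_auc(Xd[[fs]], yd, plan, m = NULL, feature_set = fs)
    if (!is.null(Xv)) {
      tv <- train_validate(Xd[[fs]], yd, Xv[[fs]], cad_status(records_v))
      rep_$validation <- tv$validation
    }
    rep_
  })
  names(out) <- names(Xd)
  out
}

#' Standardised PCA with discovery-only parameters
#'
#' Standardises features by the discovery mean and SD, extracts the first
#' two principal components by singular value decomposition, fixes each
#' component's sign by making its largest-magnitude loading positive, and
#' projects the validation cohort using the discovery loadings and
#' standardisation only.
#'
#' @param Xd Discovery feature matrix (>= 3 rows).
#' @param Xv Optional validation matrix with the same columns.
#' @return List with `loadings` (p x 2), `center`, `scale`, `sdev`,
#'   `scores_d`, `scores_v`.
#' @export
fit_pca_project <- function(Xd, Xv = NULL) {
  Xd <- as.matrix(Xd)
  stopifnot(nrow(Xd) >= 3)
  mu <- colMeans(Xd)
  sd_ <- apply(Xd, 2, stats::sd)
  if (any(sd_ == 0)) {
    stop("zero-variance feature: ", colnames(Xd)[which(sd_ == 0)[1]],
         call. = FALSE)
  }
  Xs <- scale(Xd, mu, sd_)
  sv <- svd(Xs)
  load2 <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (load2[which.max(abs(load2[, j])), j] < 0) load2[, j] <- -load2[, j]
  }
  rownames(load2) <- colnames(Xd)
  colnames(load2) <- c("PC1", "PC2")
  scores_d <- Xs %*% load2
  scores_v <- if (!is.null(Xv)) {
    scale(as.matrix(Xv)[, colnames(Xd), drop = FALSE], mu, sd_) %*% load2
  }
  list(loadings = load2, center = mu, scale = sd_,
       sdev = sv$d / sqrt(nrow(Xd) - 1),
       scores_d = scores_d, scores_v = scores_v)
}

#' Back-map the PC grid and draw the SVM decision boundary
#'
#' Lays a grid over the bounding box of the projected points (5% margin),
#' maps each grid point from (PC1, PC2) back to the full standardised
#' feature space with a feed-forward network (2 inputs, one hidden layer
#' of 16 tanh units, linear outputs; seeded initialisation, least-squares
#' training on the discovery projection/feature pairs), and classifies
#' each mapped point with the trained SVM. If the network fails to reach
#' 1.5x the residual error of the rank-2 linear inverse, the exact linear
#' map is used instead (with a warning).
#'
#' @param model A fitted `"cad_svm"` (from the signature ops).
#' @param pca Output of [fit_pca_project()] on the same features.
#' @param grid_n Grid resolution per axis (default 200).
#' @param seed Seed for the network initialisation.
#' @param maxit Training iteration budget.
#' @return List of class `"boundary_map"`: grid axes, predicted class
#'   matrix, decision score matrix, projected points, and `used_fallback`.
#' @export
backmap_decision_boundary <- function(model, pca, grid_n = 200L, seed = 1L,
                                      maxit = 500L) {
  pts <- rbind(pca$scores_d, pca$scores_v)
  pad <- 0.05 * (apply(pts, 2, max) - apply(pts, 2, min))
  g1 <- seq(min(pts[, 1]) - pad[1], max(pts[, 1]) + pad[1], length.out = grid_n)
  g2 <- seq(min(pts[, 2]) - pad[2], max(pts[, 2]) + pad[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(PC1 = g1, PC2 = g2))

  # training pairs: discovery scores -> full standardised features (the
  # rank-2 reconstruction is the fallback, not the training target)
  Xs_d <- attr(pca, "Xs_d")
  if (is.null(Xs_d)) {
    stop("backmap_decision_boundary needs the standardised discovery features; ",
         "call via boundary_map() or attach attr(pca, 'Xs_d')", call. = FALSE)
  }

  lin_fit <- stats::lm.fit(cbind(1, pca$scores_d), Xs_d)
  lin_pred <- cbind(1, pca$scores_d) %*% lin_fit$coefficients
  lin_rmse <- sqrt(mean((lin_pred - Xs_d)^2))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "backmap_nnet"))
  net <- nnet::nnet(x = pca$scores_d, y = Xs_d, size = 16, linout = TRUE,
                    decay = 1e-5, maxit = maxit, trace = FALSE,
                    MaxNWts = 2000)
  net_rmse <- sqrt(mean((stats::predict(net, pca$scores_d) - Xs_d)^2))

  used_fallback <- net_rmse > 1.5 * lin_rmse
  mapped <- if (used_fallback) {
    warning("back-mapping network did not beat the rank-2 linear baseline; ",
            "using the exact linear inverse map", call. = FALSE)
    cbind(1, grid) %*% lin_fit$coefficients
  } else {
    stats::predict(net, grid)
  }
  colnames(mapped) <- colnames(Xs_d)

  # mapped points are standardised features; undo standardisation so the
  # SVM (which standardises internally) sees raw-scale inputs
  raw <- sweep(sweep(mapped, 2, pca$scale[colnames(mapped)], `*`),
               2, pca$center[colnames(mapped)], `+`)
  scores <- svm_score(model, raw[, model$features, drop = FALSE])
  structure(list(
    pc1 = g1, pc2 = g2,
    decision = matrix(scores, grid_n, grid_n),
    class = matrix(scores > 0, grid_n, grid_n),
    mapped_features = mapped,
    scores_d = pca$scores_d, scores_v = pca$scores_v,
    used_fallback = used_fallback, net_rmse = net_rmse, lin_rmse = lin_rmse),
    class = "boundary_map")
}

#' Fit PCA and the decision-boundary map in one step
#'
#' Convenience wrapper: runs [fit_pca_project()] on the signature features,
#' retains the standardised discovery features the back-mapping network
#' trains on, and builds the boundary map for a fitted SVM.
#'
#' @param model A fitted `"cad_svm"`.
#' @param Xd,Xv Discovery / validation feature matrices (raw scale), with
#'   the model's features among their columns.
#' @inheritParams backmap_decision_boundary
#' @return List with `pca` and `map`.
#' @export
boundary_map <- function(model, Xd, Xv = NULL, grid_n = 200L, seed = 1L,
                         maxit = 500L) {
  Xd <- as.matrix(Xd)[, model$features, drop = FALSE]
  if (!is.null(Xv)) Xv <- as.matrix(Xv)[, model$features, drop = FALSE]
  pca <- fit_pca_project(Xd, Xv)
  attr(pca, "Xs_d") <- scale(Xd, pca$center, pca$scale)
  map <- backmap_decision_boundary(model, pca, grid_n = grid_n, seed = seed,
                                   maxit = maxit)
  list(pca = pca, map = map)
}
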