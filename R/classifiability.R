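# Per-patient classifiability under repeated cross-validation:
# AUC-based feature screening inside each training fold, an L1-penalised
# logistic model with inner-CV penalty selection, and the per-patient
# proportion of correct held-out predictions across repeats. Plus the
# modifier-variable regressions and the age-based sub-cohort rule.

#' Build a repeated cross-validation plan
#'
#' Assigns each patient to a fold within each repeat. Stratified assignment
#' (the default) splits each outcome class separately so every fold
#' contains both classes — with prevalence far from one half, unstratified
#' folds are occasionally single-class. All assignments derive from the
#' seed; identical seeds give identical plans.
#'
#' @param y Binary outcome vector (defines n and the strata).
#' @param folds Folds per repeat (>= 2).
#' @param repeats Number of repeats (>= 1).
#' @param stratified Stratify fold assignment by outcome class.
#' @param seed Integer seed.
#' @return List of class `"cv_plan"`: `assignment` is a repeats x n integer
#'   matrix of fold ids.
#' @export
cv_plan <- function(y, folds = 5L, repeats = 20L, stratified = TRUE, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  y <- as.logical(y)
  n <- length(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "cv_plan"))
  assignment <- matrix(0L, repeats, n)
  for (r in seq_len(repeats)) {
    assignment[r, ] <- draw_fold_assignment(y, folds, stratified)
  }
  structure(list(assignment = assignment, folds = as.integer(folds),
                 repeats = as.integer(repeats), stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

draw_fold_assignment <- function(y, folds, stratified) {
  n <- length(y)
  out <- integer(n)
  if (stratified) {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      out[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    out[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  out
}

#' Screen features by AUC on a training split
#'
#' Computes each feature's AUC for the outcome by the rank formulation
#' (mid-rank ties) and returns the indices of the top `m` features ranked
#' by the configured key: distance from 0.5 (default — an AUC of 0.2 is as
#' informative as 0.8) or raw AUC. Ties break by original column order.
#'
#' @param X Training feature matrix.
#' @param y Training outcome (both classes required).
#' @param m Number of features to keep.
#' @param rank_key `"abs"` ranks by `|AUC - 0.5|`, `"raw"` by AUC itself.
#' @return Integer vector of `m` column indices.
#' @export
screen_by_auc <- function(X, y, m, rank_key = c("abs", "raw")) {
  rank_key <- match.arg(rank_key)
  stopifnot(m >= 1, m <= ncol(X))
  aucs <- apply(X, 2, auc_rank, labels = y)
  key <- if (rank_key == "abs") abs(aucs - 0.5) else aucs
  order(key, decreasing = TRUE)[seq_len(m)] # stable: ties keep column order
}

# 50 log-spaced lambdas from the data-driven lambda_max down 3 decades
# (smaller penalties rarely win on deviance and often fail to converge
# on near-separable folds)
lasso_lambda_grid <- function(X, y, n_lambda = 50) {
  yc <- as.numeric(y) - mean(y)
  lmax <- max(abs(crossprod(X, yc))) / length(y)
  exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
}

# Fit lasso logistic on standardised training data with inner-CV penalty
# selection; returns held-out probabilities for X_test.
lasso_predict_holdout <- function(X_train, y_train, X_test, inner_seed) {
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- scale(X_train, mu, sd_)
  Xt <- scale(X_test, mu, sd_)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(inner_seed)
  foldid <- draw_fold_assignment(as.logical(y_train), 5L, stratified = TRUE)
  grid <- lasso_lambda_grid(Xs, y_train)
  cv <- glmnet::cv.glmnet(Xs, as.numeric(y_train), family = "binomial",
                          lambda = grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  as.numeric(stats::predict(cv, Xt, s = "lambda.min", type = "response"))
}

#' Per-patient classifiability under repeated cross-validation
#'
#' For each repeat and fold: screen `m` features by AUC on the training
#' split only, standardise with training statistics, fit an L1-penalised
#' logistic model with the penalty chosen by an inner 5-fold deviance grid
#' (50 log-spaced values) on the training split, predict held-out
#' probabilities, and classify at 0.5. Each patient's classifiability
#' `c_i` is the proportion of repeats in which their held-out prediction
#' was correct; the mean of `c_i` equals overall repeated-CV accuracy by
#' construction. Under non-stratified plans a fold missing a class is
#' re-drawn (at most 10 attempts, with a message).
#'
#' @param X Feature matrix (patients x features, percent scale).
#' @param y Binary outcome.
#' @param plan A [cv_plan()] built on `y`.
#' @param m Features retained per fold (default 18).
#' @param rank_key Screening key, see [screen_by_auc()].
#' @return List of class `"classifiability_profile"`: `score` (c_i per
#'   patient), `n_repeats`, `prob` and `correct` (repeats x patients), and
#'   `selected` (list of per-(repeat,fold) screened feature indices).
#' @export
compute_classifiability <- function(X, y, plan, m = 18L,
                                    rank_key = c("abs", "raw")) {
  rank_key <- match.arg(rank_key)
  y <- as.logical(y)
  n <- length(y)
  stopifnot(nrow(X) == n, ncol(plan$assignment) == n, n >= 25)
  prob <- matrix(NA_real_, plan$repeats, n)
  selected <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    assign_r <- plan$assignment[r, ]
    for (attempt in seq_len(10)) {
      ok <- all(vapply(seq_len(plan$folds), function(f) {
        length(unique(y[assign_r != f])) == 2
      }, TRUE))
      if (ok) break
      message("re-drawing fold assignment for repeat ", r,
              " (single-class training fold)")
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(plan$seed, sprintf("redraw_%d_%d", r, attempt)))
      assign_r <- draw_fold_assignment(y, plan$folds, plan$stratified)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
    sel_r <- vector("list", plan$folds)
    for (f in seq_len(plan$folds)) {
      test <- assign_r == f
      sel <- screen_by_auc(X[!test, , drop = FALSE], y[!test], m, rank_key)
      sel_r[[f]] <- sel
      prob[r, test] <- lasso_predict_holdout(
        X[!test, sel, drop = FALSE], y[!test], X[test, sel, drop = FALSE],
        inner_seed = derive_seed(plan$seed, sprintf("inner_%d_%d", r, f)))
    }
    selected[[r]] <- sel_r
  }
  correct <- sweep(prob >= 0.5, 2, y, `==`)
  structure(list(score = colMeans(correct), n_repeats = plan$repeats,
                 prob = prob, correct = correct, selected = selected),
            class = "classifiability_profile")
}

#' Regress classifiability on candidate modifier variables
#'
#' Ordinary least squares of the per-patient classifiability score on each
#' candidate clinical covariate (simple per-covariate regressions by
#' default; one joint model with `joint = TRUE`), ranked by ascending
#' p-value of the non-zero-coefficient t-test. Constant covariates are
#' flagged untestable. `sex` enters as a male indicator; logical risk
#' factors as 0/1.
#'
#' @param profile A `"classifiability_profile"` (or a numeric score vector).
#' @param records Patient table aligned to the scores.
#' @param covariates Covariate names present in `records`.
#' @param joint Fit one multiple regression instead of per-covariate fits.
#' @return A data.frame with coefficient, se, p per covariate, ranked by p.
#' @export
find_modifiers <- function(profile, records,
                           covariates = c("age", "sex", "hypertension",
                                          "diabetes", "hyperlipidaemia",
                                          "current_smoking",
                                          "smoking_history_gt10py",
                                          "family_history", "statin",
                                          "ace_arb", "antiplatelet",
                                          "beta_blocker"),
                           joint = FALSE) {
  score <- if (inherits(profile, "classifiability_profile")) profile$score
           else as.numeric(profile)
  stopifnot(length(score) == nrow(records))
  missing <- setdiff(covariates, names(records))
  if (length(missing) > 0) {
    stop("covariate(s) absent from records: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  covmat <- sapply(covariates, function(v) {
    if (v == "sex") as.numeric(records$sex == "male")
    else as.numeric(records[[v]])
  })
  degenerate <- stats::sd(score) == 0
  const <- apply(covmat, 2, function(x) stats::sd(x) == 0)

  one_row <- function(name, est, se, note = NA_character_) {
    p <- if (is.na(se) || se == 0) NA_real_
         else 2 * stats::pt(-abs(est / se), df = length(score) - 2)
    data.frame(covariate = name, coefficient = est, se = se, p = p,
               note = note, stringsAsFactors = FALSE)
  }

  if (joint) {
    use <- covariates[!const]
    fit <- stats::lm(score ~ ., data = as.data.frame(covmat[, use, drop = FALSE]))
    sm <- summary(fit)$coefficients
    rows <- lapply(use, function(v) {
      data.frame(covariate = v, coefficient = sm[v, 1], se = sm[v, 2],
                 p = sm[v, 4], note = NA_character_, stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(seq_along(covariates), function(i) {
      v <- covariates[i]
      if (const[i]) return(one_row(v, NA_real_, NA_real_, "untestable: constant covariate"))
      if (degenerate) return(one_row(v, 0, NA_real_, "degenerate: constant classifiability"))
      fit <- stats::lm(score ~ covmat[, i])
      sm <- summary(fit)$coefficients
      data.frame(covariate = v, coefficient = sm[2, 1], se = sm[2, 2],
                 p = sm[2, 4], note = NA_character_, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Select the age-based sub-cohort
#'
#' Patients at or above the age cut-off (boundary inclusive: "55 or
#' older" keeps a 55-year-old).
#'
#' @param records Patient table.
#' @param cutoff Age threshold in years (default 55).
#' @return Integer indices of selected patients, with per-cohort sizes in
#'   attribute `"sizes"`.
#' @export
select_subcohort <- function(records, cutoff = 55) {
  idx <- which(records$age >= cutoff)
  if (length(idx) == 0) stop("empty sub-cohort at cutoff ", cutoff, call. = FALSE)
  attr(idx, "sizes") <- table(records$cohort[idx])
  idx
}

#' Scan age cut-offs for the classifiability step
#'
#' Visual-threshold helper: scans integer candidate cut-offs and returns
#' the one maximising the difference in mean classifiability between the
#' at-or-above and below groups, requiring at least `min_frac` of patients
#' on each side.
#'
#' @param score Classifiability scores.
#' @param age Ages aligned to `score`.
#' @param candidates Candidate cut-offs (default: integer ages spanning the
#'   observed range).
#' @param min_frac Minimum fraction of patients on each side of a
#'   candidate cut-off.
#' @return List with `cutoff` and the scanned `table`.
#' @export
scan_age_cutoff <- function(score, age,
                            candidates = seq(ceiling(min(age)) + 1,
                                             floor(max(age))),
                            min_frac = 0.1) {
  stopifnot(length(score) == length(age))
  rows <- lapply(candidates, function(ct) {
    hi <- age >= ct
    if (mean(hi) < min_frac || mean(!hi) < min_frac) return(NULL)
    data.frame(cutoff = ct, diff = mean(score[hi]) - mean(score[!hi]))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no admissible cut-off candidates", call. = FALSE)
  list(cutoff = tab$cutoff[which.max(tab$diff)], table = tab)
}
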