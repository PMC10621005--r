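# ROC/AUC primitives shared by feature screening and the signature models.

#' AUC by the rank (Mann-Whitney) formulation
#'
#' Probability that a random positive scores above a random negative, with
#' mid-rank handling of ties: `AUC = (R_pos - n_pos (n_pos + 1)/2) /
#' (n_pos n_neg)` where `R_pos` is the rank sum of positive scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps all distinct score thresholds, returning the (FPR, TPR) points
#' from (0, 0) to (1, 1). Trapezoidal area under this curve equals
#' [auc_rank()] exactly (ties traced as diagonal segments).
#'
#' @inheritParams auc_rank
#' @return A data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE) # last index of each tied block
  tp <- cumsum(y)[keep]; fp <- cumsum(!y)[keep]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Trapezoidal area under an ROC curve
#' @param roc Data.frame with `fpr`, `tpr` ordered by `fpr`.
#' @return Area in [0, 1].
#' @export
roc_auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Interpolated TPR at fixed FPR grid points
#'
#' Linear interpolation of an ROC curve onto a fixed FPR grid, the
#' primitive behind vertical ROC averaging (mean TPR over folds at each
#' grid point).
#'
#' @param roc Data.frame with `fpr`, `tpr`.
#' @param grid FPR grid (default 0 to 1 step 0.01).
#' @return Numeric vector of TPR values, one per grid point.
#' @export
roc_on_grid <- function(roc, grid = seq(0, 1, by = 0.01)) {
  stats::approx(roc$fpr, roc$tpr, xout = grid, ties = max, rule = 2)$y
}
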