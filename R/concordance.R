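# Cross-cohort replication: per-subset fold change of CAD+/CAD- group
# means computed within each cohort, Pearson correlation of the two
# fold-change vectors, and the heat-map hierarchical clustering.

#' Fold change of group means per subset
#'
#' For each subset, the ratio of the CAD+ group mean to the CAD- group mean
#' of the subset percentage, computed within the discovery and validation
#' cohorts separately. A zero denominator mean flags the record as
#' undefined; such records are excluded from the concordance correlation
#' with a logged count.
#'
#' @param matrix_ Proportions matrix covering both cohorts.
#' @param records Patient table aligned to the matrix rows.
#' @param subset_ids Subsets to compute (default: all columns).
#' @return A data.frame with fc_discovery, fc_validation and defined flags.
#' @export
fold_change_of_means <- function(matrix_, records, subset_ids = colnames(matrix_)) {
  stopifnot(nrow(matrix_) == nrow(records))
  cad <- cad_status(records)
  fc_one <- function(in_cohort, sid) {
    m0 <- mean(matrix_[in_cohort & !cad, sid])
    m1 <- mean(matrix_[in_cohort & cad, sid])
    if (!is.finite(m0) || m0 == 0) NA_real_ else m1 / m0
  }
  disc <- records$cohort == "discovery"
  vali <- records$cohort == "validation"
  if (!any(cad[disc]) || !any(!cad[disc]) ||
      (any(vali) && (!any(cad[vali]) || !any(!cad[vali])))) {
    stop("both CAD groups must be nonempty within each cohort", call. = FALSE)
  }
  out <- data.frame(
    subset_id = subset_ids,
    fc_discovery = vapply(subset_ids, function(s) fc_one(disc, s), 0),
    fc_validation = if (any(vali))
      vapply(subset_ids, function(s) fc_one(vali, s), 0) else NA_real_,
    stringsAsFactors = FALSE
  )
  out$defined <- is.finite(out$fc_discovery) & is.finite(out$fc_validation)
  rownames(out) <- NULL
  out
}

#' Concordance test between discovery and validation fold changes
#'
#' Pearson correlation of the per-subset fold-change vectors on the raw or
#' log scale, with the two-sided p-value from `t = r sqrt(n-2)/sqrt(1-r^2)`
#' on n - 2 degrees of freedom. Undefined fold-change records are excluded
#' pairwise.
#'
#' @param fc Output of [fold_change_of_means()] (or any data.frame with
#'   fc_discovery / fc_validation columns).
#' @param scale `"raw"` correlates the fold changes as plotted; `"log"`
#'   correlates their logarithms.
#' @return List with `n`, `r`, `t`, `p`, `n_excluded`.
#' @export
concordance_test <- function(fc, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  ok <- is.finite(fc$fc_discovery) & is.finite(fc$fc_validation)
  x <- fc$fc_discovery[ok]
  y <- fc$fc_validation[ok]
  if (scale == "log") {
    x <- log(x); y <- log(y)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 usable fold-change records", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate concordance: zero variance in a fold-change vector",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  res <- correlation_p(r, n)
  list(n = n, r = r, t = res$t, p = res$p, n_excluded = sum(!ok))
}

#' p-value of a Pearson correlation against zero
#'
#' @param r Sample Pearson correlation.
#' @param n Number of paired observations (>= 3).
#' @return List with the t statistic (`n - 2` df) and two-sided `p`.
#' @export
correlation_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) >= 1 - 1e-14) {
    return(list(t = Inf * sign(r), p = .Machine$double.xmin))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Hierarchical clustering of the %total proportions heat map
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (via [stats::hclust()]) on both axes of a patients x subsets matrix of
#' percent-of-total-live proportions, as used for cohort heat maps.
#' Returns merge heights and leaf orders for both axes.
#'
#' @param matrix_ Numeric matrix (>= 2 rows).
#' @return List with `patients` and `subsets`, each holding `merge`,
#'   `height` and `order` from the corresponding dendrogram.
#' @export
hierarchical_cluster <- function(matrix_) {
  stopifnot(nrow(matrix_) >= 2)
  cl <- function(m) {
    h <- stats::hclust(stats::dist(m, method = "euclidean"),
                       method = "complete")
    list(merge = h$merge, height = h$height, order = h$order)
  }
  list(patients = cl(matrix_),
       subsets = if (ncol(matrix_) >= 2) cl(t(matrix_)) else NULL)
}
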