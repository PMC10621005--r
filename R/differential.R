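# Per-subset logistic regression of CAD status on subset proportion,
# unadjusted and age/sex-adjusted. Odds ratios are per unit (percentage
# point) increase in the subset proportion, with 95% Wald intervals.

#' Fit a logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit of a binary outcome on a predictor
#' matrix (intercept added internally) via [stats::glm()]. The covariance
#' is the inverse observed information. Perfect separation is flagged when
#' a standardised coefficient diverges beyond 20.
#'
#' @param y Binary outcome (logical or 0/1), length n.
#' @param X Numeric predictor matrix (n x p) with column names.
#' @return List with `coef` (including `(Intercept)`), `vcov`, `converged`.
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column: ", colnames(X)[which(sds == 0)[1]],
         call. = FALSE)
  }
  if (length(y) <= ncol(X) + 1) {
    stop("too few observations for the number of predictors", call. = FALSE)
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged) {
    stop("logistic fit did not converge in 100 iterations", call. = FALSE)
  }
  beta <- stats::coef(fit)
  std_beta <- beta[-1] * sds
  if (any(abs(std_beta) > 20)) {
    stop("perfect separation suspected for predictor: ",
         names(std_beta)[which.max(abs(std_beta))], call. = FALSE)
  }
  list(coef = beta, vcov = stats::vcov(fit), converged = fit$converged)
}

tier_glyph <- function(p, alpha_tiers = c(0.1, 0.05, 0.01, 0.001)) {
  glyphs <- c("°", "*", "**", "***")
  tiers <- sort(alpha_tiers, decreasing = TRUE)
  out <- character(length(p))
  for (i in seq_along(tiers)) out[!is.na(p) & p < tiers[i]] <- glyphs[i]
  out
}

#' Per-subset logistic association panel
#'
#' Fits, for every subset in the proportions matrix, a logistic regression
#' of CAD status on the subset percentage — either as the only covariate
#' (`adjust = FALSE`) or together with age in years and a male indicator
#' (`adjust = TRUE`). Returns per-subset log-odds, Wald SE, odds ratio with
#' 95% CI (`exp(beta +/- 1.959964 se)`), two-sided Wald p, and significance
#' tier. No multiple-testing correction is applied by default, matching the
#' single-subset presentation convention; Benjamini-Hochberg adjusted
#' p-values are appended when `bh = TRUE`. Zero-variance subsets are
#' flagged untestable rather than dropped.
#'
#' @param matrix_ Proportions matrix (patients x subsets, percent scale).
#' @param records Validated patient table aligned to the matrix rows.
#' @param adjust Include age and sex covariates.
#' @param alpha_tiers Significance thresholds for tier glyphs.
#' @param bh Append a Benjamini-Hochberg adjusted p column.
#' @return A data.frame, one row per subset.
#' @export
run_panel <- function(matrix_, records, adjust = FALSE,
                      alpha_tiers = c(0.1, 0.05, 0.01, 0.001), bh = FALSE) {
  stopifnot(nrow(matrix_) == nrow(records))
  y <- cad_status(records)
  if (sum(y) < 10 || sum(!y) < 10) {
    stop("need at least 10 patients in each CAD group", call. = FALSE)
  }
  z <- 1.959964
  rows <- lapply(colnames(matrix_), function(sid) {
    x <- matrix_[, sid]
    if (stats::sd(x) == 0) {
      return(data.frame(subset_id = sid,
                        model = if (adjust) "age_sex_adjusted" else "unadjusted",
                        beta = NA_real_, se = NA_real_, or_ = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        tier = "", note = "untestable: zero variance",
                        stringsAsFactors = FALSE))
    }
    X <- if (adjust) {
      cbind(proportion = x, age = records$age,
            male = as.numeric(records$sex == "male"))
    } else {
      cbind(proportion = x)
    }
    fit <- fit_logistic(y, X)
    b <- fit$coef[["proportion"]]
    se <- sqrt(fit$vcov["proportion", "proportion"])
    p <- 2 * stats::pnorm(-abs(b / se))
    data.frame(subset_id = sid,
               model = if (adjust) "age_sex_adjusted" else "unadjusted",
               beta = b, se = se, or_ = exp(b),
               ci_low = exp(b - z * se), ci_high = exp(b + z * se),
               p = p, tier = tier_glyph(p, alpha_tiers), note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Forest-plot display table
#'
#' Orders an association panel by major population for forest-plot display,
#' carrying the odds ratio, confidence bounds and significance glyph
#' (degree sign / * / ** / *** for p below 0.1 / 0.05 / 0.01 / 0.001).
#'
#' @param panel Output of [run_panel()].
#' @param catalog Subset catalog supplying labels and major populations.
#' @return A data.frame ordered by major population then subset.
#' @export
forest_table <- function(panel, catalog) {
  stopifnot(nrow(panel) > 0)
  idx <- match(panel$subset_id, catalog$subset_id)
  out <- data.frame(
    major_population = catalog$major_population[idx],
    label = catalog$label[idx],
    panel[, c("subset_id", "model", "or_", "ci_low", "ci_high", "p", "tier")],
    stringsAsFactors = FALSE
  )
  pop_order <- match(out$major_population, major_populations())
  out <- out[order(pop_order, out$subset_id), ]
  rownames(out) <- NULL
  out
}
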