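# End-to-end pipeline assembly: runs every analysis stage in order, writes
# delimited-text outputs and a JSON run manifest, and provides figure-ready
# per-subset group summaries.

#' Per-subset box-plot summaries by CAD group
#'
#' For each requested subset and CAD group: mean, median, quartiles,
#' whisker bounds by the 1.5 IQR rule clamped to the data range, and the
#' values of SMuRFless patients listed separately (plotted as distinct
#' points in the study's figures).
#'
#' @param matrix_ Proportions matrix.
#' @param records Aligned patient table.
#' @param subset_ids Subsets to summarise (default all).
#' @return A data.frame with one row per (subset, CAD group).
#' @export
export_boxplot_data <- function(matrix_, records, subset_ids = colnames(matrix_)) {
  cad <- cad_status(records)
  sm <- smurfless(records)
  rows <- list()
  for (sid in subset_ids) {
    for (grp in c(FALSE, TRUE)) {
      v <- matrix_[cad == grp, sid]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo <- max(min(v), q[1] - 1.5 * iqr)
      hi <- min(max(v), q[3] + 1.5 * iqr)
      rows[[length(rows) + 1]] <- data.frame(
        subset_id = sid, group = if (grp) "CAD+" else "CAD-",
        n = length(v), mean = mean(v), q1 = q[1], median = q[2], q3 = q[3],
        whisker_low = lo, whisker_high = hi,
        smurfless_values = paste(signif(matrix_[cad == grp & sm, sid], 6),
                                 collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: cohort characteristics table, the
#' unadjusted and age/sex-adjusted differential association panels on the
#' discovery cohort, cross-cohort fold-change concordance (when a
#' validation cohort is present), per-patient classifiability with
#' modifier regressions, age-based sub-cohort selection, the three
#' signature feature-set comparisons, and the decision-boundary map.
#' All outputs are written as delimited text (tables) or JSON (manifest)
#' under `out_dir`; identical seed, config and inputs give identical
#' numeric outputs.
#'
#' @param records Validated patient table (one or both cohorts).
#' @param proportions Validated proportions matrix aligned to `records`.
#' @param catalog Subset catalog.
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing files.
#' @return List with every stage's result plus the run `manifest`.
#' @export
run_pipeline <- function(records, proportions, catalog,
                         cfg = analysis_config(), out_dir = NULL) {
  stopifnot(nrow(records) == nrow(proportions))
  stages <- character(0)
  outputs <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, df) {
    stages <<- c(stages, name)
    if (!is.null(out_dir) && is.data.frame(df)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  disc <- records$cohort == "discovery"
  has_validation <- any(records$cohort == "validation")
  rec_d <- records[disc, ]
  prop_d <- proportions[disc, , drop = FALSE]

  # 1. cohort characteristics
  table1 <- build_table1(rec_d, rule = cfg$table1_test_rule)
  emit("table1", table1)

  # 2. differential association, unadjusted and adjusted
  panel_unadj <- run_panel(prop_d, rec_d, adjust = FALSE,
                           alpha_tiers = cfg$alpha_tiers)
  panel_adj <- run_panel(prop_d, rec_d, adjust = TRUE,
                         alpha_tiers = cfg$alpha_tiers)
  forest <- forest_table(rbind(panel_unadj, panel_adj), catalog)
  emit("differential_unadjusted", panel_unadj)
  emit("differential_adjusted", panel_adj)

  # signature features: subsets significant in the unadjusted panel
  sig_features <- panel_unadj$subset_id[!is.na(panel_unadj$p) &
                                          panel_unadj$p < 0.05]
  if (length(sig_features) < 2) sig_features <- panel_unadj$subset_id

  # 3. concordance (two-cohort studies only)
  concordance <- NULL
  if (has_validation) {
    fc <- fold_change_of_means(proportions, records, sig_features)
    concordance <- concordance_test(fc, scale = cfg$fold_change_scale)
    emit("fold_changes", fc)
  }

  # 4. heat-map clustering of %total major populations
  total_cols <- intersect(major_populations_ids(catalog), colnames(proportions))
  clustering <- if (length(total_cols) >= 2) {
    hierarchical_cluster(proportions[, total_cols, drop = FALSE])
  }
  stages <- c(stages, "clustering")

  # 5. classifiability on the discovery cohort
  yd <- cad_status(rec_d)
  plan <- cv_plan(yd, folds = cfg$cv_folds, repeats = cfg$cv_repeats,
                  stratified = TRUE,
                  seed = derive_seed(cfg$seed, "classifiability"))
  profile <- compute_classifiability(prop_d, yd, plan,
                                     m = min(cfg$screen_top_m, ncol(prop_d)),
                                     rank_key = cfg$screen_rank_key)
  modifiers <- find_modifiers(profile, rec_d)
  emit("classifiability",
       data.frame(patient_id = rec_d$patient_id, score = profile$score))
  emit("modifiers", modifiers)

  # 6. sub-cohort selection and signature models
  sub_idx <- select_subcohort(records, cfg$age_cutoff)
  sub_rec <- records[sub_idx, ]
  sub_prop <- proportions[sub_idx, , drop = FALSE]
  sd_ <- sub_rec$cohort == "discovery"
  reports <- compare_feature_sets(
    sub_prop[sd_, , drop = FALSE], sub_rec[sd_, ],
    if (has_validation) sub_prop[!sd_, , drop = FALSE],
    if (has_validation) sub_rec[!sd_, ],
    features = sig_features, cfg = cfg)
  auc_tab <- data.frame(
    feature_set = names(reports),
    mean_cv_auc = vapply(reports, function(r) r$mean_auc, 0),
    validation_auc = vapply(reports, function(r) {
      if (is.null(r$validation)) NA_real_ else r$validation$auc
    }, 0))
  emit("signature_aucs", auc_tab)

  # 7. decision boundary on the signature features
  svm_model <- svm_fit(sub_prop[sd_, sig_features, drop = FALSE],
                       cad_status(sub_rec[sd_, ]))
  boundary <- boundary_map(
    svm_model, sub_prop[sd_, , drop = FALSE],
    if (has_validation) sub_prop[!sd_, , drop = FALSE],
    grid_n = 100L, seed = derive_seed(cfg$seed, "boundary"))
  stages <- c(stages, "boundary")

  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[c("cv_folds", "cv_repeats", "screen_top_m",
                            "age_cutoff", "table1_test_rule",
                            "fold_change_scale", "screen_rank_key")],
    n_patients = nrow(records),
    n_discovery = sum(disc),
    n_validation = sum(!disc),
    n_subsets = ncol(proportions),
    has_validation = has_validation,
    signature_features = sig_features,
    subcohort_sizes = as.list(attr(sub_idx, "sizes")),
    stages = stages
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(table1 = table1, panel_unadjusted = panel_unadj,
       panel_adjusted = panel_adj, forest = forest,
       concordance = concordance, clustering = clustering,
       profile = profile, modifiers = modifiers,
       subcohort = sub_idx, signature = reports, boundary = boundary,
       manifest = manifest)
}
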