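#!/usr/bin/env Rscript
# Stage 6: radial-kernel SVM immune signature on the age >= 55 sub-cohort.
# Repeated-CV ROC/AUC in discovery for three feature sets, train-on-all /
# evaluate-on-validation, and the PCA decision-boundary map.

suppressPackageStartupMessages(library(cadimmune))
seed <- as.integer(Sys.getenv("CADIMMUNE_SEED", "1"))

catalog <- read_subset_catalog("results/data/catalog.csv")
rec <- read_patient_table("results/data/patients.csv")
prop <- read_proportions("results/data/proportions.csv", catalog, rec)
disc <- rec$cohort == "discovery"

# signature features: subsets significant in the discovery panel
un <- run_panel(prop[disc, ], rec[disc, ], adjust = FALSE)
features <- un$subset_id[un$p < 0.05]
cat(sprintf("signature features (discovery p < 0.05): %d subsets\n",
            length(features)))

sub_idx <- select_subcohort(rec, 55)
sub_rec <- rec[sub_idx, ]
sub_prop <- prop[sub_idx, , drop = FALSE]
sd_ <- sub_rec$cohort == "discovery"

reports <- compare_feature_sets(
  sub_prop[sd_, ], sub_rec[sd_, ], sub_prop[!sd_, ], sub_rec[!sd_, ],
  features = features, cfg = analysis_config(seed = seed))
auc_tab <- data.frame(
  feature_set = names(reports),
  mean_cv_auc = sapply(reports, function(r) r$mean_auc),
  validation_auc = sapply(reports, function(r) r$validation$auc))
write.csv(auc_tab, "results/signature_aucs.csv", row.names = FALSE)
write.csv(reports$cytof_18$mean_roc, "results/signature_mean_roc.csv",
          row.names = FALSE)
cat("mean AUCs by feature set:\n")
print(auc_tab, digits = 3, row.names = FALSE)

tv <- train_validate(sub_prop[sd_, ], cad_status(sub_rec[sd_, ]),
                     sub_prop[!sd_, ], cad_status(sub_rec[!sd_, ]),
                     features = features)
model <- tv$validation$model
bm <- boundary_map(model, sub_prop[sd_, ], sub_prop[!sd_, ],
                   grid_n = 100, seed = derive_seed(seed, "boundary"))
write.csv(data.frame(pc1 = rep(bm$map$pc1, times = 100),
                     pc2 = rep(bm$map$pc2, each = 100),
                     cad_predicted = as.vector(bm$map$class)),
          "results/decision_boundary_grid.csv", row.names = FALSE)
write.csv(data.frame(rbind(bm$pca$scores_d, bm$pca$scores_v),
                     cohort = rep(c("discovery", "validation"),
                                  c(sum(sd_), sum(!sd_)))),
          "results/pc_projections.csv", row.names = FALSE)
cat(sprintf("decision boundary: %.0f%% of grid classified CAD+, fallback used: %s\n",
            100 * mean(bm$map$class), bm$map$used_fallback))
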