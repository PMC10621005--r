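#!/usr/bin/env Rscript
# Stage 4: cross-cohort replication. Fold change of CAD+/CAD- group means
# per subset within each cohort, Pearson concordance between the two
# cohorts over the discovery-significant subsets, and the %total heat-map
# clustering.

suppressPackageStartupMessages(library(cadimmune))

catalog <- read_subset_catalog("results/data/catalog.csv")
rec <- read_patient_table("results/data/patients.csv")
prop <- read_proportions("results/data/proportions.csv", catalog, rec)
disc <- rec$cohort == "discovery"

un <- run_panel(prop[disc, ], rec[disc, ], adjust = FALSE)
sig <- un$subset_id[un$p < 0.05]

fc <- fold_change_of_means(prop, rec, sig)
res <- concordance_test(fc)
write.csv(fc, "results/fold_changes.csv", row.names = FALSE)
write.csv(data.frame(n = res$n, r = res$r, t = res$t, p = res$p),
          "results/concordance.csv", row.names = FALSE)
cat(sprintf("concordance over %d discovery-significant subsets: r = %.3f, p = %.4g\n",
            res$n, res$r, res$p))
cat(sprintf("direction retained in validation: %d of %d subsets\n",
            sum(sign(fc$fc_discovery - 1) == sign(fc$fc_validation - 1)),
            nrow(fc)))

cl <- hierarchical_cluster(prop[, grep("^maj_", colnames(prop))])
write.csv(data.frame(patient_id = rec$patient_id[cl$patients$order]),
          "results/heatmap_patient_order.csv", row.names = FALSE)
cat("heat-map clustering: first patient merge at height",
    signif(cl$patients$height[1], 4), "\n")
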