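#!/usr/bin/env Rscript
# Stage 5: per-patient classifiability of the discovery cohort under
# repeated 5-fold CV x 20 with per-fold AUC screening and lasso logistic
# models; modifier-variable regressions; age cut-off scan.

suppressPackageStartupMessages(library(cadimmune))
seed <- as.integer(Sys.getenv("CADIMMUNE_SEED", "1"))

catalog <- read_subset_catalog("results/data/catalog.csv")
rec <- read_patient_table("results/data/patients.csv")
prop <- read_proportions("results/data/proportions.csv", catalog, rec)
disc <- rec$cohort == "discovery"
rec_d <- rec[disc, ]
y <- cad_status(rec_d)

plan <- cv_plan(y, folds = 5, repeats = 20, stratified = TRUE,
                seed = derive_seed(seed, "classifiability"))
prof <- compute_classifiability(prop[disc, ], y, plan, m = 18)
write.csv(data.frame(patient_id = rec_d$patient_id, age = rec_d$age,
                     score = prof$score),
          "results/classifiability.csv", row.names = FALSE)
cat(sprintf("mean classifiability (= repeated-CV accuracy): %.3f\n",
            mean(prof$score)))

mods <- find_modifiers(prof, rec_d)
write.csv(mods, "results/modifiers.csv", row.names = FALSE)
cat("top modifier candidates:\n")
print(head(mods, 3), digits = 3)

scan <- scan_age_cutoff(prof$score, rec_d$age)
write.csv(scan$table, "results/age_cutoff_scan.csv", row.names = FALSE)
cat(sprintf("cut-off maximising the classifiability split: %d years\n",
            scan$cutoff))
sub_idx <- select_subcohort(rec, 55)
cat("age >= 55 sub-cohort sizes:",
    paste(names(attr(sub_idx, "sizes")), attr(sub_idx, "sizes"),
          collapse = ", "), "\n")
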