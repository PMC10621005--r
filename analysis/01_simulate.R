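#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-cohort study the later stages analyse.
# A discovery cohort of 117 and a validation cohort of 58 patients, 82
# subset proportions in 11 major populations, age/sex-confounded CAD labels
# and a logit-scale batch shift in the validation cohort.

suppressPackageStartupMessages(library(cadimmune))
seed <- as.integer(Sys.getenv("CADIMMUNE_SEED", "1"))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
coh <- generate_cohort(cfg)

write_patient_table(coh$records, "results/data/patients.csv")
write_proportions(coh$proportions, "results/data/proportions.csv")
write_subset_catalog(coh$catalog, "results/data/catalog.csv")
write.csv(cfg$subsets, "results/data/truth_subset_params.csv", row.names = FALSE)

cat(sprintf("simulated %d patients (%d discovery / %d validation)\n",
            nrow(coh$records), sum(coh$records$cohort == "discovery"),
            sum(coh$records$cohort == "validation")))
cat(sprintf("CAD prevalence: %.2f (target %.2f)\n",
            mean(cad_status(coh$records)), cfg$prevalence))
cat(sprintf("planted per-percent OR, Treg Ki67+: %.3f\n",
            planted_or(cfg, "treg_ki67")))
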