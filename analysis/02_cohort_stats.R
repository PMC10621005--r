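#!/usr/bin/env Rscript
# Stage 2: cohort characteristics tables. First the worked example — the
# published discovery-cohort margins re-encoded as 117 patients reproduce
# the printed p column exactly under uncorrected chi-squared — then the
# same table on the synthetic discovery cohort.

suppressPackageStartupMessages(library(cadimmune))
dir.create("results", showWarnings = FALSE)

margins <- read_margins(system.file("extdata", "discovery_margins.csv",
                                    package = "cadimmune"))
rec_pub <- records_from_margins(margins)
t1_pub <- build_table1(rec_pub, rule = "chi2_always")
write.csv(t1_pub, "results/table1_published_margins.csv", row.names = FALSE)
cat("characteristics table from published margins:\n")
print(t1_pub[, c("variable", "test_used", "p")], digits = 3)

# footnote rule for comparison: small expected counts route to Fisher
t1_fisher <- build_table1(rec_pub, rule = "paper_footnote")
write.csv(t1_fisher, "results/table1_footnote_rule.csv", row.names = FALSE)
routed <- t1_fisher$variable[t1_fisher$test_used == "fisher_exact"]
cat("\nvariables routed to Fisher under the footnote rule:",
    paste(routed, collapse = ", "), "\n")

rec <- read_patient_table("results/data/patients.csv")
t1_syn <- build_table1(rec[rec$cohort == "discovery", ])
write.csv(t1_syn, "results/table1_synthetic.csv", row.names = FALSE)
cat(sprintf("\nsynthetic discovery cohort: %d variables tested, %d with p < 0.05\n",
            nrow(t1_syn), sum(t1_syn$p < 0.05, na.rm = TRUE)))
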