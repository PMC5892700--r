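#!/usr/bin/env Rscript
# Step 5: decision rules on the battery: heterogeneity group (HP / HB /
# HP/HB / M), cross-cohort validation, per-cohort antagonism replication,
# and novelty against a synthetic prior-evidence table standing in for a
# published-association catalog lookup.

source("analysis/study_config.R")

study <- make_demo_study()
pl <- run_pleiotropy(study, R = 250, seed = STUDY_SEED + 1)

# synthetic prior evidence: one SNP heavily reported before, others not
prior <- data.frame(snp_id = c("rs_ali1", "rs_ali1", "rs_ant2"),
                    phenotype = c("TC", "TG", "SBP"),
                    p = c(1e-12, 1e-9, 0.03))
cl <- classify_snps(pl, prior_evidence = prior)
write_classification(cl, file.path(RESULTS_DIR, "classification.tsv"))

cat("Classification of the simulated panel:\n")
print(cl, row.names = FALSE)
cat("\nGroup counts (GW-significant SNPs only):\n")
print(table(cl$group[cl$group != "none"]))
cat("\nNote the scaled-down sample: genome-wide (5e-8) significance needs\n")
cat("strong effects; antagonistic geometry is still visible in the\n")
cat("replication counts even where the GW flag is not reached.\n")
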