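#!/usr/bin/env Rscript
# Step 4: the stage-2 pleiotropic battery. Phenotype-based (Sigma_P) and
# permutation-based (Sigma_B, 250 dosage permutations per SNP) z-score
# correlation matrices are estimated at cohort and meta scope, then all
# seven tests run along both pathways over the three phenotype domains
# (12 markers, 8 outcomes, all 20). The headline contrast: antagonistic
# SNPs get far smaller omnibus than Fisher p-values.

source("analysis/study_config.R")

study <- make_demo_study()
pl <- run_pleiotropy(study, R = 250, seed = STUDY_SEED + 1)

utils::write.table(pl$table, file.path(RESULTS_DIR, "pleiotropy_long.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pl$wide, file.path(RESULTS_DIR, "pleiotropy_wide.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_sigma(pl$sigma$mP, file.path(RESULTS_DIR, "sigma_P_meta.tsv"))
for (co in names(pl$sigma$jP))
  write_sigma(pl$sigma$jP[[co]],
              file.path(RESULTS_DIR, paste0("sigma_P_", co, ".tsv")))

cat("Best test per SNP (smallest-p domain):\n")
print(pl$wide, digits = 3, row.names = FALSE)

cat("\nOmnibus vs Fisher contrast (best domain; gap in orders of magnitude):\n")
for (snp in c("rs_ant1", "rs_ant2", "rs_ali1")) {
  dd <- pl$results[[snp]]$domains[[pl$results[[snp]]$best_domain]]
  tl <- dd$tests
  cat(sprintf(
    "  %s: OpFc = %6.1f FpFc = %6.1f (gap %4.1f) | MOp = %6.1f MFp = %6.1f (gap %4.1f)\n",
    snp, tl$OpFc$log10_p, tl$FpFc$log10_p,
    tl$FpFc$log10_p - tl$OpFc$log10_p,
    tl$MOp$log10_p, tl$MFp$log10_p, tl$MFp$log10_p - tl$MOp$log10_p))
}
cat("Antagonistic SNPs show omnibus p-values orders of magnitude below the\n")
cat("Fisher p-values (the >= 2-order gap the heterogeneity groups key on);\n")
cat("the aligned SNP of equal effect size shows no such gap, the many null\n")
cat("phenotypes of the domain diluting the pure two-trait geometry.\n")

H <- heatmap_table(pl$meta)
utils::write.table(round(H, 2), file.path(RESULTS_DIR, "heatmap_minuslog10p.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
cat("\n-log10(p) heat-map table (trimmed at 7.3) written.\n")
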