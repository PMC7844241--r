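#!/usr/bin/env Rscript
# Stage 5 - phenotypic overlap: confusion matrices with cross-product ORs
# and Fisher tests for PS x binary comorbidity, rank-sum tests for PS x
# severity scales, and Spearman correlations among quantitative scales,
# per ancestry group.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(OUT_DIR, "cohort.tsv"))

pairs <- list(c("ps", "adhd"), c("ps", "adhd_symptoms"),
              c("ps", "depression"), c("ps", "mania"), c("ps", "anxiety"),
              c("ps", "trauma"), c("ps", "prime"), c("ps", "sops"),
              c("prime", "sops"))
ov <- overlap_battery(cohort, pairs, by = "ancestry")
write.table(ov, file.path(OUT_DIR, "overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# confusion matrices for the two headline overlaps, per cohort
for (flag in c("adhd", "adhd_symptoms")) {
  for (cn in c("All", "EA", "AA")) {
    sel <- if (cn == "All") rep(TRUE, nrow(cohort)) else cohort$ancestry == cn
    ct <- contingency(cohort[[flag]][sel], cohort$ps[sel])
    cat(sprintf("PS x %s [%s]: cells (%d, %d, %d, %d), OR %.1f (%.1f-%.1f), Fisher p = %.2g\n",
                flag, cn, ct$cells["a"], ct$cells["b"], ct$cells["c"],
                ct$cells["d"], ct$or, ct$ci_lo, ct$ci_hi, ct$fisher_p))
  }
}
rho <- rank_correlation(cohort$prime, cohort$sops)
cat(sprintf("PRIME x SOPS: spearman rho %.2f, p = %.2g\n", rho$rho, rho$p))
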