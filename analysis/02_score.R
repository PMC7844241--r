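#!/usr/bin/env Rscript
# Stage 2 - polygenic scoring: harmonize each trait's summary statistics to
# the cohort variants, LD-clump (r2 < 0.1, 500 kb), threshold at p < 0.05,
# score, then residualize on 10 ancestry-specific PCs and standardize
# within each ancestry group. Writes scores_corrected.tsv.

source("analysis/00_config.R")

cfg <- cohort_config()
geno <- regen_genotypes(cfg)  # deterministic regeneration, not stored

gwas_files <- list.files(file.path(OUT_DIR, "gwas"), full.names = TRUE)
stopifnot(length(gwas_files) > 0)
sumstats <- lapply(gwas_files, read_sumstats)
names(sumstats) <- vapply(sumstats, attr, "", "trait")

# the selection rule for GWAS inputs: LD-score heritability z > 5
sumstats <- select_gwas(sumstats, z_min = 5)
cat("traits retained by h2 z-score filter:", length(sumstats), "\n")

pgs <- build_pgs_matrix(sumstats, geno, method = "clump_pt",
                        p_max = 0.05, r2_max = 0.1, window_kb = 500,
                        radius = 500, n_pcs = 10)
write.table(data.frame(id = rownames(pgs$corrected), pgs$corrected,
                       check.names = FALSE),
            file.path(OUT_DIR, "scores_corrected.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (a in unique(geno$ancestry)) {
  sel <- geno$ancestry == a
  stopifnot(max(abs(colMeans(pgs$corrected[sel, ]))) < 1e-8)
}
cat("corrected scores: mean 0 / SD 1 within each ancestry group\n")
cat(sprintf("wrote %d x %d score matrix\n", nrow(pgs$corrected),
            ncol(pgs$corrected)))
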