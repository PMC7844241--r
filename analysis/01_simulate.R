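#!/usr/bin/env Rscript
# Stage 1 - simulate the cohort: two-ancestry genotypes with blockwise LD,
# GWAS summary statistics for 13 brain/behaviour traits, and
# liability-threshold phenotypes (PS, comorbid flags, severity scales).
# Writes cohort.tsv and per-trait summary statistics under results/gwas/.

source("analysis/00_config.R")

cfg <- cohort_config()
geno <- regen_genotypes(cfg)
eff <- regen_effects(cfg, geno)
cohort <- simulate_phenotypes(geno, eff, cfg)

write_cohort(cohort, file.path(OUT_DIR, "cohort.tsv"))
dir.create(file.path(OUT_DIR, "gwas"), showWarnings = FALSE)
for (ts in cfg$trait_specs) {
  ss <- simulate_sumstats(geno$variants, ts, ancestry = "EA",
                          seed = derive_seed(MASTER_SEED,
                                             paste0("gwas_", ts$name)),
                          true_beta = eff$effects[, ts$name])
  write_sumstats(ss, file.path(OUT_DIR, "gwas",
                               paste0(ts$name, ".sumstats.tsv.gz")))
}

ea <- cohort$ancestry == "EA"
cat(sprintf("cohort: %d subjects (%d EA, %d AA), %d variants\n",
            nrow(cohort), sum(ea), sum(!ea), cfg$n_variants))
cat(sprintf("PS prevalence: %.1f%% overall (%.1f%% EA, %.1f%% AA)\n",
            100 * mean(cohort$ps), 100 * mean(cohort$ps[ea]),
            100 * mean(cohort$ps[!ea])))
cat(sprintf("ADHD prevalence: %.1f%%; symptom endorsement: %.1f%%\n",
            100 * mean(cohort$adhd), 100 * mean(cohort$adhd_symptoms)))
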