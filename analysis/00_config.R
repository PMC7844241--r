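# Shared settings for the numbered analysis drivers. Each script is
# self-contained: stage seeds derive from MASTER_SEED, so later scripts can
# regenerate the genotypes deterministically instead of storing them.

library(pgspectrum)

MASTER_SEED <- 20210128L
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

# study conditions: two-ancestry youth cohort, 13 GWAS traits, ADHD genetic
# liability acting on PS in EA (OR 1.23/SD) but not AA, attenuating with age
cohort_config <- function() {
  sim_config(seed = derive_seed(MASTER_SEED, "simulate"))
}

regen_genotypes <- function(cfg = cohort_config()) simulate_genotypes(cfg)

regen_effects <- function(cfg = cohort_config(), geno) {
  simulate_trait_effects(geno$variants, cfg$trait_specs,
                         seed = derive_seed(MASTER_SEED, "effects"))
}
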