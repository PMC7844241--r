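#!/usr/bin/env Rscript
# Stage 3 - multi-PGS classification: elastic net over all corrected PGS,
# tuned over (alpha, lambda) by stratified 10-fold CV maximizing AUC,
# evaluated on repeated stratified 70/30 splits against a within-ancestry
# permutation null, per cohort (All, EA, AA). Also the multivariate-vs-
# univariate comparison the elastic net is judged against.
# Scaled-down loop sizes (the full procedure uses 1000/1000).

source("analysis/00_config.R")

cohort <- read_cohort(file.path(OUT_DIR, "cohort.tsv"))
scores <- read.delim(file.path(OUT_DIR, "scores_corrected.tsv"),
                     check.names = FALSE)
stopifnot(identical(scores$id, cohort$id))
X <- as.matrix(scores[, -1])

N_REPS <- 50; N_PERMS <- 99
cohorts <- list(All = rep(TRUE, nrow(cohort)),
                EA = cohort$ancestry == "EA",
                AA = cohort$ancestry == "AA")
summ <- list(); coefs <- list(); runs <- list()
for (cn in names(cohorts)) {
  sel <- cohorts[[cn]]
  run <- repeat_and_permute(
    X[sel, ], cohort$ps[sel],
    group = if (cn == "All") cohort$ancestry[sel] else NULL,
    n_repetitions = N_REPS, n_permutations = N_PERMS,
    seed = derive_seed(MASTER_SEED, paste0("multipgs_", cn)),
    alpha_grid = c(0, 0.5, 1), folds = 10, nlambda = 30)
  runs[[cn]] <- run
  summ[[cn]] <- data.frame(cohort = cn, mean_auc = run$mean_auc,
                           sd_auc = sd(run$auc),
                           empirical_p = run$empirical_p)
  coefs[[cn]] <- data.frame(cohort = cn, trait = names(run$coef_mean),
                            coef_mean = run$coef_mean,
                            coef_sem = run$coef_sem, row.names = NULL)
  cat(sprintf("%s: mean AUC %.3f (sd %.3f), permutation p = %.3f\n",
              cn, run$mean_auc, sd(run$auc), run$empirical_p))
  top <- which.max(abs(run$coef_mean))
  cat(sprintf("  largest mean |coefficient|: %s (%.3f, sem %.4f)\n",
              names(run$coef_mean)[top], run$coef_mean[top],
              run$coef_sem[top]))
}
write.table(do.call(rbind, summ), file.path(OUT_DIR, "multipgs_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, coefs),
            file.path(OUT_DIR, "multipgs_coefficients.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# does the multi-PGS model beat the ADHD score alone in EA?
sel <- cohorts$EA
run_single <- repeat_and_permute(
  X[sel, "ADHD", drop = FALSE], cohort$ps[sel],
  n_repetitions = N_REPS, n_permutations = 1,
  seed = derive_seed(MASTER_SEED, "single_ea"))
cmp <- compare_auc_runs(runs$EA, run_single)
cat(sprintf("EA multi vs ADHD-only: median AUC %.3f vs %.3f, rank-sum p = %.3g\n",
            cmp$median1, cmp$median2, cmp$p))
write.table(data.frame(median_multi = cmp$median1,
                       median_single = cmp$median2, p = cmp$p),
            file.path(OUT_DIR, "multipgs_vs_univariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
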