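#!/usr/bin/env Rscript
# Stage 4 - univariate association battery: logistic regression of PS on
# each corrected PGS (age, age^2, sex adjusted) per cohort, Bonferroni
# control over the score x cohort grid, PGS x age and PGS x sex
# interactions with age-bin ORs, the decile contrast, and the sensitivity
# refits (ADHD-case and symptom-endorser exclusions, substance covariates,
# trauma exclusion).

source("analysis/00_config.R")

cohort <- read_cohort(file.path(OUT_DIR, "cohort.tsv"))
scores <- read.delim(file.path(OUT_DIR, "scores_corrected.tsv"),
                     check.names = FALSE)
stopifnot(identical(scores$id, cohort$id))
X <- as.matrix(scores[, -1])
covars <- make_covars(cohort)
cohorts <- list(All = rep(TRUE, nrow(cohort)),
                EA = cohort$ancestry == "EA",
                AA = cohort$ancestry == "AA")

rows <- list()
for (cn in names(cohorts)) {
  sel <- cohorts[[cn]]
  for (tr in colnames(X))
    rows[[paste(cn, tr)]] <- fit_univariate(X[sel, tr], cohort$ps[sel],
                                            covars[sel, ], trait = tr,
                                            cohort_label = cn)
}
tab <- do.call(rbind, rows)
bf <- bonferroni_threshold(ncol(X), length(cohorts))
tab$significant <- tab$p < bf$raw
write.table(tab, file.path(OUT_DIR, "assoc_univariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Bonferroni cutoff: %.3g (reported %.3g); %d/%d tests pass\n",
            bf$raw, bf$reported, sum(tab$significant), nrow(tab)))
print(tab[tab$significant, c("trait", "cohort", "or_per_sd", "ci_lo",
                             "ci_hi", "p")], row.names = FALSE)

# follow-up analyses in the cohort driving the signal (EA), on the trait
# with the largest effect
ea <- cohorts$EA
top <- tab$trait[ea_i <- which(tab$cohort == "EA")][which.min(tab$p[ea_i])]
cat("\nfollow-up on", top, "in EA\n")
s <- X[ea, top]; y <- cohort$ps[ea]; cv <- covars[ea, ]

ti <- test_interaction(s, y, cohort$age[ea], cv)
cat(sprintf("age interaction: coef %.4f, p = %.3g\n",
            ti$interaction_coef, ti$interaction_p))
print(ti$bin_results[, c("cohort", "n", "or_per_sd", "ci_lo", "ci_hi")],
      row.names = FALSE)
write.table(ti$bin_results, file.path(OUT_DIR, "assoc_age_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ts <- test_interaction(s, y, as.integer(cohort$sex[ea] == "M"), cv,
                       bins = NULL)
cat(sprintf("sex interaction: p = %.3g\n", ts$interaction_p))

dc <- decile_contrast(s, y, cv)
cat(sprintf("top vs bottom decile: OR %.2f (%.2f, %.2f), p = %.3g\n",
            dc$top_vs_bottom$or, dc$top_vs_bottom$ci_lo,
            dc$top_vs_bottom$ci_hi, dc$top_vs_bottom$p))
write.table(data.frame(decile = seq_len(10),
                       case_proportion = as.numeric(dc$decile_props)),
            file.path(OUT_DIR, "assoc_deciles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sens <- rbind(
  sensitivity_refit(s, y, cv, exclude = cohort$adhd[ea] == 1,
                    trait = top, cohort_label = "EA_noADHD"),
  sensitivity_refit(s, y, cv, exclude = cohort$adhd_symptoms[ea] == 1,
                    trait = top, cohort_label = "EA_noSymptoms"),
  sensitivity_refit(s, y, cv, exclude = cohort$trauma[ea] == 1,
                    trait = top, cohort_label = "EA_noTrauma"),
  sensitivity_refit(s, y, cv,
                    extra_covars = cohort[ea, c("alcohol", "tobacco",
                                                "marijuana")],
                    trait = top, cohort_label = "EA_substanceCov"))
write.table(sens, file.path(OUT_DIR, "assoc_sensitivity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(sens[, c("cohort", "n", "pct_outcome", "or_per_sd", "ci_lo",
               "ci_hi", "p")], row.names = FALSE)

# quantitative severity scales
for (sc in c("prime", "sops")) {
  fq <- fit_quantitative(s, cohort[[sc]][ea], cv)
  cat(sprintf("%s: beta %.3f per SD, p = %.3g\n", toupper(sc), fq$beta,
              fq$p))
}
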