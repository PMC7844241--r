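#' Run the full simulate -> score -> classify -> associate -> overlap pipeline
#'
#' Thin orchestrator over the module functions: simulates the two-ancestry
#' cohort, builds corrected PGS for every trait, runs the (scaled-down by
#' default) elastic-net classification with permutation null per cohort,
#' the univariate association battery with decile and age-bin summaries,
#' and the phenotypic-overlap battery. Each stage derives its own seed from
#' the master seed, so re-running one stage does not depend on another
#' stage's draw count. All result surfaces are written as TSV under
#' `out_dir`, together with a manifest of parameters and seeds.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param master_seed integer master seed (overrides `config$seed`).
#' @param stages character subset of
#'   `c("simulate","score","multipgs","assoc","overlap")`; later stages
#'   require the earlier ones in the same call.
#' @param n_repetitions,n_permutations multi-PGS loop sizes (defaults are
#'   desk-scale, not the study's 1000/1000).
#' @param alpha_grid,folds elastic-net tuning controls.
#' @param n_pcs ancestry PCs per group.
#' @return invisible list with every in-memory stage product.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "results",
                         master_seed = config$seed,
                         stages = c("simulate", "score", "multipgs",
                                    "assoc", "overlap"),
                         n_repetitions = 50, n_permutations = 99,
                         alpha_grid = c(0, 0.5, 1), folds = 10, n_pcs = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(master_seed = master_seed, stages = stages,
                   n_subjects = config$n_subjects_per_ancestry,
                   n_variants = config$n_variants,
                   n_repetitions = n_repetitions,
                   n_permutations = n_permutations)

  if ("simulate" %in% stages) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, "simulate")
    message("simulate: seed ", cfg$seed)
    geno <- simulate_genotypes(cfg)
    eff <- simulate_trait_effects(geno$variants, cfg$trait_specs,
                                  seed = derive_seed(master_seed, "effects"))
    cohort <- simulate_phenotypes(geno, eff, cfg)
    sumstats <- list()
    for (ts in cfg$trait_specs) {
      sumstats[[ts$name]] <- simulate_sumstats(
        geno$variants, ts, ancestry = names(cfg$n_subjects_per_ancestry)[1],
        seed = derive_seed(master_seed, paste0("gwas_", ts$name)),
        true_beta = eff$effects[, ts$name])
    }
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    out <- c(out, list(geno = geno, effects = eff, cohort = cohort,
                       sumstats = sumstats))
  }

  if ("score" %in% stages) {
    message("score: clump+threshold PGS, ", length(out$sumstats), " traits")
    pgs <- build_pgs_matrix(out$sumstats, out$geno, n_pcs = n_pcs)
    utils::write.table(data.frame(id = rownames(pgs$corrected),
                                  pgs$corrected, check.names = FALSE),
                       file.path(out_dir, "scores_corrected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$pgs <- pgs
  }

  if ("multipgs" %in% stages) {
    runs <- list()
    cohorts <- c(list(All = rep(TRUE, nrow(out$cohort))),
                 stats::setNames(
                   lapply(names(config$n_subjects_per_ancestry),
                          function(a) out$cohort$ancestry == a),
                   names(config$n_subjects_per_ancestry)))
    for (cn in names(cohorts)) {
      sel <- cohorts[[cn]]
      message("multipgs: cohort ", cn, " (n=", sum(sel), ")")
      X <- out$pgs$corrected[sel, , drop = FALSE]
      grp <- if (cn == "All") out$cohort$ancestry[sel] else NULL
      runs[[cn]] <- repeat_and_permute(
        X, out$cohort$ps[sel], group = grp,
        n_repetitions = n_repetitions, n_permutations = n_permutations,
        seed = derive_seed(master_seed, paste0("multipgs_", cn)),
        alpha_grid = alpha_grid, folds = folds)
    }
    coef_tab <- do.call(rbind, lapply(names(runs), function(cn)
      data.frame(cohort = cn, trait = names(runs[[cn]]$coef_mean),
                 coef_mean = runs[[cn]]$coef_mean,
                 coef_sem = runs[[cn]]$coef_sem, row.names = NULL)))
    summ <- data.frame(cohort = names(runs),
                       mean_auc = vapply(runs, function(r) r$mean_auc, 0),
                       sd_auc = vapply(runs, function(r) stats::sd(r$auc), 0),
                       empirical_p = vapply(runs, function(r) r$empirical_p, 0))
    utils::write.table(coef_tab, file.path(out_dir, "multipgs_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "multipgs_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$multipgs <- runs
  }

  if ("assoc" %in% stages) {
    message("assoc: univariate battery")
    cohort <- out$cohort
    covars <- make_covars(cohort)
    cohorts <- c(list(All = rep(TRUE, nrow(cohort))),
                 stats::setNames(
                   lapply(names(config$n_subjects_per_ancestry),
                          function(a) cohort$ancestry == a),
                   names(config$n_subjects_per_ancestry)))
    rows <- list()
    for (cn in names(cohorts)) {
      sel <- cohorts[[cn]]
      for (tr in colnames(out$pgs$corrected)) {
        rows[[length(rows) + 1]] <- fit_univariate(
          out$pgs$corrected[sel, tr], cohort$ps[sel],
          covars[sel, , drop = FALSE], trait = tr, cohort_label = cn)
      }
    }
    assoc_tab <- do.call(rbind, rows)
    bf <- bonferroni_threshold(ncol(out$pgs$corrected), length(cohorts))
    assoc_tab$significant <- assoc_tab$p < bf$raw
    utils::write.table(assoc_tab, file.path(out_dir, "assoc_univariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$assoc <- assoc_tab
    out$bonferroni <- bf
  }

  if ("overlap" %in% stages) {
    message("overlap: phenotype battery")
    pairs <- list(c("ps", "adhd"), c("ps", "adhd_symptoms"),
                  c("ps", "depression"), c("ps", "mania"),
                  c("ps", "anxiety"), c("ps", "trauma"),
                  c("ps", "prime"), c("ps", "sops"),
                  c("prime", "sops"))
    ov <- overlap_battery(out$cohort, pairs, by = "ancestry")
    utils::write.table(ov, file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$overlap <- ov
  }

  writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  invisible(out)
}
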