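#' Simulation configuration for a two-ancestry youth cohort
#'
#' Bundles every parameter of the synthetic cohort generator. The defaults
#' describe the study conditions the package is exercised under: a
#' community-based youth cohort with a large European-ancestry (EA) and a
#' smaller African-American (AA) subgroup, a binary psychosis-spectrum (PS)
#' outcome with ancestry-specific prevalence (15% EA, 29% AA), a 5% ADHD
#' outcome, and an ADHD genetic liability acting on PS risk in EA
#' (OR 1.23 per SD) but not in AA, attenuating with age.
#'
#' @param n_subjects_per_ancestry named integer vector, subjects per ancestry
#'   label. Default `c(EA = 4852, AA = 1802)`.
#' @param n_variants total number of variants; must be divisible by
#'   `n_blocks`. Genome scale is not emulated: variants stand in for
#'   LD-pruned genotyping content.
#' @param n_blocks number of independent LD blocks.
#' @param block_rho within-block latent correlation decay base in [0,1);
#'   correlation between variants i,j in a block is `block_rho^|i-j|`.
#' @param fst Balding-Nichols divergence parameter in [0, 0.5]; 0 means both
#'   ancestries share allele frequencies.
#' @param maf_range interval in (0, 0.5] for the ancestral allele frequency.
#' @param trait_specs list of [trait_spec()] objects, one per GWAS trait.
#' @param target_or_per_sd named list `trait -> named numeric by ancestry`:
#'   odds ratio on PS per SD of the trait's true genetic score. Traits
#'   absent from the list have no direct effect.
#' @param ps_prevalence named numeric, PS prevalence per ancestry, in (0,1).
#' @param adhd_prevalence ADHD prevalence (overall), in (0,1).
#' @param age_range numeric length 2, years; ages drawn uniformly.
#' @param age_interaction_slope per-year change of the PS log-OR per SD,
#'   applied along `(age - min(age_range))` to every nonzero trait effect.
#'   The base log-OR is anchored so the configured OR holds at the cohort
#'   mean age.
#' @param comorbid_specs named list of comorbid phenotype specifications,
#'   see [default_comorbid_specs()]. Entries with `ps_liability_log_or != 0`
#'   are generated before PS and feed into the PS liability (mediation);
#'   all others are generated conditional on PS.
#' @param prime_sops_spec list controlling the quantitative PRIME and SOPS
#'   severity scales (means, PS shift, shared-noise loading).
#' @param seed integer; fixes all randomness end-to-end.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects_per_ancestry = c(EA = 4852, AA = 1802),
                       n_variants = 2000,
                       n_blocks = 40,
                       block_rho = 0.8,
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       trait_specs = default_trait_specs(),
                       target_or_per_sd = list(ADHD = c(EA = 1.23, AA = 1.0)),
                       ps_prevalence = c(EA = 0.15, AA = 0.29),
                       adhd_prevalence = 0.05,
                       age_range = c(8, 22),
                       age_interaction_slope = -0.02,
                       comorbid_specs = default_comorbid_specs(adhd_prevalence),
                       prime_sops_spec = list(prime_mu = 1, prime_ps = 2.5,
                                              sops_mu = 1.5, sops_ps = 2,
                                              shared_sd = 0.7, noise_sd = 1),
                       seed = 1L) {
  cfg <- list(n_subjects_per_ancestry = n_subjects_per_ancestry,
              n_variants = as.integer(n_variants),
              n_blocks = as.integer(n_blocks),
              block_rho = block_rho, fst = fst, maf_range = maf_range,
              trait_specs = trait_specs,
              target_or_per_sd = target_or_per_sd,
              ps_prevalence = ps_prevalence,
              adhd_prevalence = adhd_prevalence,
              age_range = age_range,
              age_interaction_slope = age_interaction_slope,
              comorbid_specs = comorbid_specs,
              prime_sops_spec = prime_sops_spec,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$n_subjects_per_ancestry)) ||
      any(!nzchar(names(cfg$n_subjects_per_ancestry))))
    stop("n_subjects_per_ancestry must be a named vector of counts")
  if (any(cfg$n_subjects_per_ancestry < 1))
    stop("subject counts must be positive")
  if (cfg$n_variants %% cfg$n_blocks != 0)
    stop("n_variants must be divisible by n_blocks")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("block_rho must lie in [0, 1)")
  if (cfg$fst < 0 || cfg$fst > 0.5)
    stop("fst must lie in [0, 0.5]")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  anc <- names(cfg$n_subjects_per_ancestry)
  if (!all(anc %in% names(cfg$ps_prevalence)))
    stop("ps_prevalence must name every ancestry")
  if (any(cfg$ps_prevalence <= 0 | cfg$ps_prevalence >= 1))
    stop("prevalences must lie in (0, 1)")
  if (cfg$adhd_prevalence <= 0 || cfg$adhd_prevalence >= 1)
    stop("adhd_prevalence must lie in (0, 1)")
  for (ts in cfg$trait_specs) stopifnot(inherits(ts, "trait_spec"))
  invisible(cfg)
}

#' Specification of one GWAS source trait
#'
#' @param name trait label (e.g. "ADHD").
#' @param gwas_n discovery GWAS sample size.
#' @param h2 heritability captured by the simulated variants, in [0,1]
#'   (variance of the true standardized effect vector).
#' @param prop_causal fraction of variants with nonzero effect, in (0,1].
#' @param rg_to_ps_liability genetic correlation between the trait's true
#'   effects and the latent PS liability effects, in [-1,1].
#' @return object of class `trait_spec`.
#' @export
trait_spec <- function(name, gwas_n, h2, prop_causal = 0.1,
                       rg_to_ps_liability = 0) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (gwas_n <= 0) stop("gwas_n must be positive")
  if (prop_causal <= 0 || prop_causal > 1)
    stop("prop_causal must lie in (0, 1]")
  if (abs(rg_to_ps_liability) > 1) stop("rg must lie in [-1, 1]")
  structure(list(name = name, gwas_n = as.integer(gwas_n), h2 = h2,
                 prop_causal = prop_causal,
                 rg_to_ps_liability = rg_to_ps_liability),
            class = "trait_spec")
}

#' Default battery of GWAS trait specifications
#'
#' Thirteen psychiatric, brain-volume and behavioural traits mirroring the
#' scale of public GWAS used for multi-PGS work on youth psychopathology.
#' Only ADHD carries genetic correlation with the PS liability by default;
#' the others act as correlated-but-null predictors for the elastic net.
#'
#' @return list of [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  list(
    trait_spec("ADHD",        55374, 0.22, 0.15, rg_to_ps_liability = 0.85),
    trait_spec("SCZ",        105318, 0.24, 0.20),
    trait_spec("BIP",         51710, 0.20, 0.15),
    trait_spec("MDD",        173005, 0.09, 0.20),
    trait_spec("Autism",      46350, 0.12, 0.15),
    trait_spec("CrossDis",    33332, 0.18, 0.20),
    trait_spec("DeprSymp",   105739, 0.06, 0.20),
    trait_spec("ConvergeMDD", 10640, 0.10, 0.15),
    trait_spec("Caudate",     30717, 0.15, 0.10),
    trait_spec("Putamen",     30717, 0.15, 0.10),
    trait_spec("Morningness", 89283, 0.10, 0.20),
    trait_spec("Neuroticism", 170911, 0.09, 0.20),
    trait_spec("SWB",        298420, 0.04, 0.20)
  )
}

#' Default comorbid-phenotype generation settings
#'
#' Each entry defines a binary flag generated around the PS outcome:
#' `prevalence` is the marginal target, `log_or_ps` the log odds ratio of
#' the flag given PS (this is what 2x2 cross-product ORs recover),
#' `log_or_g` an optional named vector of log-ORs per SD of true genetic
#' scores, `missing_rate` the fraction of subjects with the flag unobserved
#' (substance-use items were only partially assessed), and
#' `ps_liability_log_or` a mediation path: if nonzero the flag is generated
#' before PS and enters the PS liability with that log-OR.
#'
#' Defaults target contingency odds ratios of about 3 for ADHD x PS and
#' about 4.7 for symptom endorsement x PS, with mood/anxiety overlap of the
#' same order and weaker trauma/substance overlap.
#'
#' @param adhd_prevalence marginal ADHD prevalence used for the `adhd` flag.
#' @return named list of comorbid specifications.
#' @export
default_comorbid_specs <- function(adhd_prevalence = 0.05) {
  list(
    adhd          = list(prevalence = adhd_prevalence, log_or_ps = log(3.0)),
    adhd_symptoms = list(prevalence = 0.50, log_or_ps = log(4.7)),
    depression    = list(prevalence = 0.15, log_or_ps = log(3.0)),
    mania         = list(prevalence = 0.10, log_or_ps = log(3.0)),
    anxiety       = list(prevalence = 0.20, log_or_ps = log(2.5)),
    trauma        = list(prevalence = 0.20, log_or_ps = log(1.5)),
    alcohol       = list(prevalence = 0.15, log_or_ps = log(1.5),
                         missing_rate = 0.57),
    tobacco       = list(prevalence = 0.10, log_or_ps = log(1.5),
                         missing_rate = 0.57),
    marijuana     = list(prevalence = 0.12, log_or_ps = log(1.5),
                         missing_rate = 0.57),
    cocaine       = list(prevalence = 0.01, log_or_ps = log(1.2),
                         missing_rate = 0.57),
    otc           = list(prevalence = 0.05, log_or_ps = log(1.2),
                         missing_rate = 0.57)
  )
}

#' Simulate two-ancestry genotypes with blockwise LD
#'
#' Allele frequencies diverge between ancestries under a Balding-Nichols
#' model: given an ancestral frequency p, each ancestry's frequency is drawn
#' from Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `fst`. Haplotypes are
#' generated from a Gaussian copula whose latent correlation decays as
#' `block_rho^|i-j|` within a block and is zero across blocks; thresholding
#' at the frequency quantile yields alleles, and dosages are sums of two
#' haplotypes (so dosage LD is slightly below the latent correlation).
#'
#' @param config a [sim_config()].
#' @return list with `variants` (data.frame: chrom, pos, id, a1, a2, block,
#'   and one `freq_<ancestry>` column per group), `genotypes` (subjects x
#'   variants integer dosage matrix, rownames = subject ids), `ancestry`
#'   (character vector aligned with rows).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  M <- config$n_variants
  B <- config$n_blocks
  bs <- M %/% B
  anc <- names(config$n_subjects_per_ancestry)

  p0 <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  freqs <- matrix(NA_real_, M, length(anc), dimnames = list(NULL, anc))
  for (a in anc) {
    if (config$fst == 0) {
      freqs[, a] <- p0
    } else {
      freqs[, a] <- stats::rbeta(M, p0 * (1 - config$fst) / config$fst,
                                 (1 - p0) * (1 - config$fst) / config$fst)
    }
  }
  freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)

  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, M, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1))

  # positions: 2 kb spacing within a block, 1 Mb gap between blocks
  block <- rep(seq_len(B), each = bs)
  within <- rep(seq_len(bs), B)
  pos <- (block - 1L) * 1000000L + within * 2000L
  variants <- data.frame(chrom = "1", pos = pos,
                         id = paste0("rs", seq_len(M)),
                         a1 = a1, a2 = a2, block = block,
                         stringsAsFactors = FALSE)
  for (a in anc) variants[[paste0("freq_", a)]] <- freqs[, a]

  n_total <- sum(config$n_subjects_per_ancestry)
  geno <- matrix(0L, n_total, M)
  ancestry <- rep(anc, times = config$n_subjects_per_ancestry)
  row0 <- 0L
  for (a in anc) {
    n <- config$n_subjects_per_ancestry[[a]]
    hap <- .sim_haplotypes(2L * n, M, bs, config$block_rho, freqs[, a])
    geno[row0 + seq_len(n), ] <- hap[seq(1, 2 * n, by = 2), , drop = FALSE] +
      hap[seq(2, 2 * n, by = 2), , drop = FALSE]
    row0 <- row0 + n
  }
  rownames(geno) <- paste0("S", seq_len(n_total))
  colnames(geno) <- variants$id
  list(variants = variants, genotypes = geno, ancestry = ancestry)
}

# latent AR(1) per block, thresholded at the allele-frequency quantile
.sim_haplotypes <- function(n_hap, M, bs, rho, freq) {
  hap <- matrix(0L, n_hap, M)
  thr <- stats::qnorm(freq)
  s <- sqrt(1 - rho^2)
  for (b in seq_len(M %/% bs)) {
    cols <- (b - 1L) * bs + seq_len(bs)
    z <- matrix(0, n_hap, bs)
    z[, 1] <- stats::rnorm(n_hap)
    if (bs > 1) for (j in 2:bs) z[, j] <- rho * z[, j - 1] + s * stats::rnorm(n_hap)
    hap[, cols] <- 1L * (z < rep(thr[cols], each = n_hap))
  }
  hap
}

#' Simulate true per-variant effects for all traits
#'
#' Draws a latent PS-liability effect vector (point-normal) and, for each
#' trait, an effect vector with the requested genetic correlation to it:
#' `beta_t = rg * u_ps * sqrt(h2_t/h2_ps) + sqrt(1-rg^2) * e_t`, where `e_t`
#' is an independent point-normal vector scaled to `h2_t`. Effects are on
#' the standardized-genotype scale (summed squared effects = h2).
#'
#' @param variants variant table from [simulate_genotypes()].
#' @param trait_specs list of [trait_spec()]s.
#' @param seed integer seed.
#' @param ps_h2 heritability of the latent PS liability component.
#' @param ps_prop_causal causal fraction of the PS liability component.
#' @return list with `effects` (variants x traits matrix of true
#'   standardized effects) and `ps_effects` (the latent PS vector).
#' @export
simulate_trait_effects <- function(variants, trait_specs, seed,
                                   ps_h2 = 0.25, ps_prop_causal = 0.2) {
  set.seed(seed)
  M <- nrow(variants)
  u <- .point_normal(M, ps_prop_causal, ps_h2)
  eff <- matrix(0, M, length(trait_specs),
                dimnames = list(variants$id,
                                vapply(trait_specs, `[[`, "", "name")))
  for (k in seq_along(trait_specs)) {
    ts <- trait_specs[[k]]
    rg <- ts$rg_to_ps_liability
    indep <- .point_normal(M, ts$prop_causal, ts$h2)
    eff[, k] <- rg * u * sqrt(ts$h2 / ps_h2) + sqrt(1 - rg^2) * indep
  }
  list(effects = eff, ps_effects = u)
}

.point_normal <- function(M, prop_causal, h2) {
  m_c <- max(1L, round(prop_causal * M))
  idx <- sample.int(M, m_c)
  b <- numeric(M)
  if (h2 > 0) {
    b[idx] <- stats::rnorm(m_c)
    b <- b * sqrt(h2 / sum(b^2))
  }
  b
}

#' Simulate GWAS summary statistics for one trait
#'
#' Observed marginal effects are the true per-allele effects plus sampling
#' noise with standard error `1/sqrt(2 n p (1-p))` (the standard
#' approximation for a standardized continuous outcome); two-sided p-values
#' come from the Wald z-ratio. Effect alleles match the variant table's a1.
#'
#' @param variants variant table (needs `freq_<ancestry>` column).
#' @param spec a [trait_spec()].
#' @param ancestry ancestry label whose allele frequencies scale the
#'   per-allele effects and standard errors.
#' @param seed integer seed.
#' @param true_beta optional true standardized effect vector (e.g. a column
#'   of [simulate_trait_effects()]); drawn point-normal from `spec` if NULL.
#' @param h2_zscore LD-score-style heritability z metadata attached to the
#'   result (used by [select_gwas()]); the default `h2 * sqrt(gwas_n) / 2`
#'   is a crude proxy for LD-score regression power, under which every
#'   default trait battery member passes the z > 5 selection rule.
#' @return `sumstats` data.frame (SNP, CHR, BP, A1, A2, BETA, SE, P, N) with
#'   attributes `trait` and `h2_zscore`.
#' @export
simulate_sumstats <- function(variants, spec, ancestry, seed,
                              true_beta = NULL, h2_zscore = NULL) {
  if (spec$h2 < 0 || spec$h2 > 1) stop("h2 must lie in [0, 1]")
  fcol <- paste0("freq_", ancestry)
  if (!fcol %in% names(variants)) stop("unknown ancestry: ", ancestry)
  set.seed(seed)
  M <- nrow(variants)
  if (is.null(true_beta))
    true_beta <- .point_normal(M, spec$prop_causal, spec$h2)
  p <- variants[[fcol]]
  sd_g <- sqrt(2 * p * (1 - p))
  beta_allele <- true_beta / sd_g
  se <- 1 / (sqrt(spec$gwas_n) * sd_g)
  beta_hat <- beta_allele + stats::rnorm(M) * se
  z <- beta_hat / se
  pval <- 2 * stats::pnorm(-abs(z))
  pval <- pmax(pval, .Machine$double.xmin)  # keep p in (0,1]
  ss <- data.frame(SNP = variants$id, CHR = variants$chrom, BP = variants$pos,
                   A1 = variants$a1, A2 = variants$a2,
                   BETA = beta_hat, SE = se, P = pval,
                   N = spec$gwas_n, stringsAsFactors = FALSE)
  attr(ss, "trait") <- spec$name
  attr(ss, "h2_zscore") <-
    if (is.null(h2_zscore)) spec$h2 * sqrt(spec$gwas_n) / 2 else h2_zscore
  class(ss) <- c("sumstats", "data.frame")
  ss
}

#' Simulate phenotypes on a liability-threshold model
#'
#' The PS outcome arises from a liability with a genetic part (the true
#' standardized genetic scores weighted by configured log-ORs per SD, with a
#' linear age modulation of those log-ORs), optional mediator flags, and a
#' logistic-distributed residual; the per-ancestry threshold is solved
#' numerically so realized prevalence matches `ps_prevalence`. Using a
#' logistic residual makes the configured odds ratio per SD hold exactly
#' under the downstream logistic regression. Comorbid flags are then drawn
#' conditional on PS with configured log-ORs and marginal prevalences;
#' PRIME/SOPS quantitative severity scales share a latent noise component so
#' they are mutually rank-correlated and elevated under PS.
#'
#' @param geno output of [simulate_genotypes()].
#' @param effects output of [simulate_trait_effects()] (or a compatible
#'   list with an `effects` matrix).
#' @param config the [sim_config()].
#' @return `data.frame` cohort table: id, age, sex, ancestry, ps, comorbid
#'   flags, prime, sops, substance flags (NA = not assessed), and one
#'   `g_<trait>` column per trait with a configured effect (the true
#'   standardized genetic score; retained for parameter-recovery checks).
#' @export
simulate_phenotypes <- function(geno, effects, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  ancestry <- geno$ancestry
  n <- length(ancestry)
  anc_levels <- names(config$n_subjects_per_ancestry)

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(rep(c("M", "F"), length.out = n))

  # true standardized genetic scores, per trait, standardized within ancestry
  or_traits <- names(config$target_or_per_sd)
  gmat <- matrix(0, n, length(or_traits),
                 dimnames = list(NULL, or_traits))
  for (tr in or_traits) {
    b <- effects$effects[, tr]
    raw <- as.numeric(scale_genotypes_by_group(geno$genotypes, ancestry) %*% b)
    gmat[, tr] <- standardize_by_group(raw, ancestry)
  }

  age0 <- config$age_range[1]
  age_mid <- mean(config$age_range)
  eta <- numeric(n)
  for (tr in or_traits) {
    ors <- config$target_or_per_sd[[tr]]
    for (a in anc_levels) {
      sel <- ancestry == a
      base <- log(ors[[a]])
      if (base != 0) {
        slope <- config$age_interaction_slope
        g8 <- base - slope * (age_mid - age0)
        eta[sel] <- eta[sel] + (g8 + slope * (age[sel] - age0)) * gmat[sel, tr]
      }
    }
  }

  # mediator flags (feed the PS liability) are generated before PS
  med_names <- names(Filter(function(s) !is.null(s$ps_liability_log_or) &&
                              s$ps_liability_log_or != 0, config$comorbid_specs))
  flags <- list()
  for (fl in med_names) {
    s <- config$comorbid_specs[[fl]]
    lp <- numeric(n)
    if (!is.null(s$log_or_g))
      for (tr in names(s$log_or_g)) lp <- lp + s$log_or_g[[tr]] * gmat[, tr]
    a0 <- .solve_intercept(lp, s$prevalence)
    flags[[fl]] <- stats::rbinom(n, 1, stats::plogis(a0 + lp))
    eta <- eta + s$ps_liability_log_or * flags[[fl]]
  }

  ps <- integer(n)
  for (a in anc_levels) {
    sel <- ancestry == a
    t_a <- .solve_intercept(eta[sel], config$ps_prevalence[[a]])
    ps[sel] <- stats::rbinom(sum(sel), 1, stats::plogis(t_a + eta[sel]))
  }

  # remaining comorbid flags, conditional on PS
  for (fl in setdiff(names(config$comorbid_specs), med_names)) {
    s <- config$comorbid_specs[[fl]]
    lp <- s$log_or_ps * ps
    if (!is.null(s$log_or_g))
      for (tr in names(s$log_or_g)) lp <- lp + s$log_or_g[[tr]] * gmat[, tr]
    a0 <- .solve_intercept(lp, s$prevalence)
    flags[[fl]] <- stats::rbinom(n, 1, stats::plogis(a0 + lp))
  }
  for (fl in names(config$comorbid_specs)) {
    s <- config$comorbid_specs[[fl]]
    if (!is.null(s$missing_rate) && s$missing_rate > 0)
      flags[[fl]][stats::runif(n) < s$missing_rate] <- NA_integer_
  }

  pss <- config$prime_sops_spec
  shared <- stats::rnorm(n, sd = pss$shared_sd)
  g_adhd <- if ("ADHD" %in% colnames(gmat)) gmat[, "ADHD"] else 0
  prime <- pmax(0, round(pss$prime_mu + pss$prime_ps * ps + 0.2 * g_adhd +
                           shared + stats::rnorm(n, sd = pss$noise_sd), 1))
  sops <- pmax(0, round(pss$sops_mu + pss$sops_ps * ps + 0.1 * g_adhd +
                          shared + stats::rnorm(n, sd = pss$noise_sd), 1))

  cohort <- data.frame(id = rownames(geno$genotypes), age = age, sex = sex,
                       ancestry = ancestry, ps = ps,
                       stringsAsFactors = FALSE)
  for (fl in names(config$comorbid_specs)) cohort[[fl]] <- flags[[fl]]
  cohort$prime <- prime
  cohort$sops <- sops
  for (tr in or_traits) cohort[[paste0("g_", tr)]] <- gmat[, tr]
  cohort
}

# solve intercept a so that mean(plogis(a + lp)) = target prevalence
.solve_intercept <- function(lp, target) {
  if (target <= 0 || target >= 1) stop("prevalence must lie in (0,1)")
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

#' Standardize a genotype matrix within ancestry groups
#'
#' Columns are centred and scaled to unit variance separately within each
#' group; monomorphic columns within a group are set to 0.
#'
#' @param geno subjects x variants dosage matrix.
#' @param group character vector of group labels per subject.
#' @return numeric matrix of the same shape.
#' @export
scale_genotypes_by_group <- function(geno, group) {
  out <- matrix(0, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  for (g in unique(group)) {
    sel <- group == g
    x <- geno[sel, , drop = FALSE]
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- Inf
    out[sel, ] <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  }
  out
}

standardize_by_group <- function(x, group) {
  out <- numeric(length(x))
  for (g in unique(group)) {
    sel <- group == g
    s <- stats::sd(x[sel])
    if (s == 0) stop("degenerate score: zero variance within group ", g)
    out[sel] <- (x[sel] - mean(x[sel])) / s
  }
  out
}

#' Derive a stage seed from a master seed
#'
#' Stage re-runs must not depend on other stages' draw counts, so each stage
#' gets its own seed derived from the master seed and the stage label.
#'
#' @param master_seed integer.
#' @param label stage label.
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, label) {
  h <- as.double(master_seed %% 2147483647L)
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h + 1)
}
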