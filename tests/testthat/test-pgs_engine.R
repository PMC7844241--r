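target_variants <- function() {
  data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L,
                                  600L, 700L, 800L, 900L, 1000L),
             id = paste0("rs", 1:10),
             a1 = c("A", "A", "C", "G", "A", "C", "T", "G", "A", "C"),
             a2 = c("G", "C", "T", "A", "T", "G", "C", "A", "G", "A"),
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns, negates, flips and excludes correctly", {
  v <- target_variants()
  # swap: stats effect allele is the target's other allele
  ss <- data.frame(SNP = "rs1", A1 = "G", A2 = "A", BETA = 0.2, P = 0.01)
  hw <- harmonize(ss, v)
  expect_equal(hw$weights$beta, -0.2)

  # A/T pair dropped under default policy with the right reason
  ss2 <- data.frame(SNP = "rs5", A1 = "A", A2 = "T", BETA = 0.3, P = 0.01)
  hw2 <- harmonize(ss2, v)
  expect_equal(nrow(hw2$weights), 0)
  expect_equal(hw2$exclusions$reason, "strand-ambiguous")
  hw2k <- harmonize(ss2, v, policy = "keep_ambiguous")
  expect_equal(hw2k$weights$beta, 0.3)

  # 10-variant fixture: 2 swapped, 1 strand-flipped, 1 ambiguous, 1 absent
  ss10 <- data.frame(
    SNP = c(paste0("rs", 1:9), "rs99"),
    A1 = c("G", "C", "C", "G", "A", "C", "A", "C", "A", "A"),
    A2 = c("A", "A", "T", "A", "T", "G", "G", "T", "G", "G"),
    BETA = rep(0.1, 10), P = rep(0.01, 10), stringsAsFactors = FALSE)
  # rs1, rs2 swapped; rs7 flipped (A/G complements T/C); rs5 ambiguous A/T;
  # rs6 ambiguous C/G; rs99 absent -> under drop policy 10 - 3 excl = 7...
  hw10 <- harmonize(ss10, v)
  expect_equal(sort(hw10$exclusions$reason),
               sort(c("strand-ambiguous", "strand-ambiguous",
                      "absent-from-target")))
  expect_equal(nrow(hw10$weights), 7)
  expect_equal(hw10$weights$beta[hw10$weights$id %in% c("rs1", "rs2")],
               c(-0.1, -0.1))
})

test_that("greedy clumping follows the forced cases and matches brute force", {
  fx <- small_geno_fixture(n = 400, M = 50, n_blocks = 5,
                           anc = c(EA = 400), fst = 0)
  geno <- fx$geno
  ld <- ld_view(geno$genotypes, geno$variants, radius = 49)
  R <- stats::cor(geno$genotypes)

  # all pairwise r2 ~ 0 (across blocks) -> everything retained
  pick <- c(1, 11, 21, 31, 41)
  w0 <- data.frame(id = geno$variants$id[pick], chrom = "1",
                   pos = geno$variants$pos[pick],
                   p = c(1e-8, 1e-6, 1e-4, 1e-3, 1e-2), idx = pick)
  expect_setequal(ld_clump(w0, ld, r2_max = 0.1), w0$id)

  # adjacent correlated variants: only the smallest p survives
  pick2 <- c(1, 2, 3)
  stopifnot(all(R[pick2, pick2]^2 > 0.05))
  w1 <- data.frame(id = geno$variants$id[pick2], chrom = "1",
                   pos = geno$variants$pos[pick2],
                   p = c(1e-8, 1e-6, 1e-4), idx = pick2)
  expect_equal(ld_clump(w1, ld, r2_max = 0.05), geno$variants$id[1])

  # row-order invariance
  w_sh <- w0[sample(nrow(w0)), ]
  expect_setequal(ld_clump(w_sh, ld), ld_clump(w0, ld))

  # random instances against the dense brute-force oracle
  set.seed(99)
  for (rep in 1:20) {
    ids <- sort(sample(50, 30))
    w <- data.frame(id = geno$variants$id[ids], chrom = "1",
                    pos = geno$variants$pos[ids],
                    p = stats::runif(30), idx = ids)
    got <- ld_clump(w, ld, r2_max = 0.2, window_kb = 300)
    df <- data.frame(id = w$id, chrom = w$chrom, pos = w$pos, p = w$p)
    want <- clump_oracle(df, R[ids, ids], r2_max = 0.2, window_bp = 3e5)
    expect_equal(sort(got), sort(want))
  }
})

test_that("p thresholding is strict and calibrated on null statistics", {
  w <- data.frame(id = c("a", "b", "c"), beta = 1,
                  p = c(0.049, 0.05, 0.051))
  expect_equal(suppressMessages(p_threshold(w))$id, "a")
  expect_equal(nrow(suppressMessages(p_threshold(w, p_max = 1.0))), 3)

  set.seed(4)
  wn <- data.frame(id = paste0("v", 1:10000), beta = 0,
                   p = 2 * stats::pnorm(-abs(stats::rnorm(10000))))
  frac <- nrow(suppressMessages(p_threshold(wn))) / 10000
  expect_equal(frac, 0.05, tolerance = 0.01 / 0.05)
})

test_that("scoring is exact, linear and flip-invariant after correction", {
  G <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(NULL, c("v1", "v2")))
  w <- data.frame(id = c("v1", "v2"), beta = c(0.1, -0.2))
  expect_equal(pgs_score(G, w), c(-0.4, -0.1, 0.2))
  expect_equal(pgs_score(G, transform(w, beta = 0)), c(0, 0, 0))
  # linearity
  w2 <- data.frame(id = c("v1", "v2"), beta = c(0.3, 0.5))
  expect_equal(pgs_score(G, transform(w, beta = w$beta + w2$beta)),
               pgs_score(G, w) + pgs_score(G, w2))
  expect_error(pgs_score(G, data.frame(id = "zz", beta = 1)), "no scoring")

  # swapping effect/other allele (dosage -> 2 - dosage, beta -> -beta)
  # shifts raw scores by a constant; corrected scores are unchanged
  set.seed(8)
  Gr <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10,
               dimnames = list(NULL, paste0("v", 1:10)))
  wr <- data.frame(id = paste0("v", 1:10), beta = stats::rnorm(10))
  s1 <- pgs_score(Gr, wr)
  s2 <- pgs_score(2 - Gr, transform(wr, beta = -beta))
  expect_equal(stats::sd(s1 - s2), 0, tolerance = 1e-12)
  expect_equal(residualize_standardize(s1), residualize_standardize(s2),
               tolerance = 1e-10)
})

test_that("missing dosages are mean-imputed within ancestry group", {
  G <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
              dimnames = list(NULL, c("v1", "v2")))
  w <- data.frame(id = c("v1", "v2"), beta = c(1, 0))
  # pooled imputation: mean of (0,2) = 1
  expect_equal(pgs_score(G, w)[3], 1)
  # group imputation: subject 3 alone in its group -> mean of itself is NaN
  # guarded by using the two-subject group mean for the first group
  grp <- c("A", "A", "A")
  expect_equal(pgs_score(G, w, group = grp)[3], 1)
})

test_that("infinitesimal LD adjustment matches closed forms and dense solve", {
  # identity LD: pure shrinkage by n h2 / (n h2 + m)
  b <- c(0.1, -0.2, 0.3)
  got <- ldpred_inf(b, ld = NULL, h2 = 0.5, n = 1e4, m = 5000)
  expect_equal(got, b * (1e4 * 0.5) / (1e4 * 0.5 + 5000), tolerance = 1e-12)

  # shrinkage factor is monotone in n h2 / m and approaches 1
  f <- function(h2) ldpred_inf(1, NULL, h2 = h2, n = 1e4, m = 5000)
  expect_true(f(0.2) < f(0.5) && f(0.5) < f(0.99))
  expect_equal(ldpred_inf(1, NULL, h2 = 1, n = 1e9, m = 10), 1,
               tolerance = 1e-6)

  # banded system equals the dense whole-matrix solve when the radius
  # covers the bandwidth
  fx <- small_geno_fixture(n = 500, M = 200, n_blocks = 10, anc = c(EA = 500))
  geno <- fx$geno
  ld <- ld_view(geno$genotypes, geno$variants, radius = 199)
  set.seed(12)
  bh <- stats::rnorm(200, sd = 0.02)
  got <- ldpred_inf(bh, ld, h2 = 0.3, n = 5e4)
  X <- scale(geno$genotypes)
  D <- stats::cor(geno$genotypes)
  lam <- 200 / (5e4 * 0.3)
  want <- solve(D + diag(lam, 200), bh)
  expect_equal(got, as.numeric(want), tolerance = 1e-6)
})

test_that("ancestry PCs are orthonormal, duplicate-stable and separate groups", {
  fx <- small_geno_fixture(n = 300, M = 120, n_blocks = 12, fst = 0.1,
                           anc = c(EA = 200, AA = 100))
  geno <- fx$geno
  pcs <- compute_pcs(geno$genotypes, k = 4)
  expect_equal(crossprod(pcs), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # PC1 separates the two ancestries almost perfectly
  a <- auc_rank(as.integer(geno$ancestry == "AA"), pcs[, 1])
  expect_gt(max(a, 1 - a), 0.99)

  # duplicated subjects get identical PC coordinates
  G2 <- rbind(geno$genotypes, geno$genotypes[1:5, ])
  pcs2 <- compute_pcs(G2, k = 3)
  expect_equal(pcs2[301:305, ], pcs2[1:5, ], tolerance = 1e-8)

  expect_error(compute_pcs(geno$genotypes[1:4, ], k = 5), "smaller")
})

test_that("PC residualization matches the normal-equations oracle", {
  set.seed(13)
  n <- 150
  pcs <- qr.Q(qr(matrix(stats::rnorm(n * 3), n, 3)))
  score <- stats::rnorm(n)
  got <- residualize_standardize(score, pcs)
  res <- residual_oracle(score, pcs)
  expect_equal(got, (res - mean(res)) / stats::sd(res), tolerance = 1e-10)
  expect_equal(mean(got), 0, tolerance = 1e-10)
  expect_equal(stats::sd(got), 1, tolerance = 1e-10)
  expect_lt(max(abs(stats::cor(got, pcs))), 1e-8)

  # PCs orthogonal to the intercept and the score leave plain standardization
  pc_orth <- qr.Q(qr(cbind(1, score, matrix(stats::rnorm(n * 2), n, 2))))[, 3:4]
  expect_equal(residualize_standardize(score, pc_orth),
               as.numeric(scale(score)), tolerance = 1e-8)

  # score equal to PC1: degenerate
  expect_error(residualize_standardize(pcs[, 1], pcs), "degenerate")
})

test_that("a PS-correlated trait yields reliably positive PGS association", {
  cfg <- sim_config(n_subjects_per_ancestry = c(EA = 4852),
                    ps_prevalence = c(EA = 0.15), n_variants = 200,
                    n_blocks = 4, age_interaction_slope = 0,
                    trait_specs = list(
                      trait_spec("ADHD", 55374, 0.22, 0.15,
                                 rg_to_ps_liability = 0.85),
                      trait_spec("NullT", 55374, 0.22, 0.15,
                                 rg_to_ps_liability = 0)),
                    target_or_per_sd = list(ADHD = c(EA = 1.23)),
                    seed = 71)
  geno <- simulate_genotypes(cfg)
  n_pos <- 0; n_null_sig <- 0; n_rep <- 40
  for (r in seq_len(n_rep)) {
    eff <- simulate_trait_effects(geno$variants, cfg$trait_specs,
                                  seed = 1000 + r)
    cfg_r <- cfg; cfg_r$seed <- 2000 + r
    coh <- simulate_phenotypes(geno, eff, cfg_r)
    ss <- simulate_sumstats(geno$variants, cfg$trait_specs[[1]], "EA",
                            seed = 3000 + r,
                            true_beta = eff$effects[, "ADHD"])
    ssn <- simulate_sumstats(geno$variants, cfg$trait_specs[[2]], "EA",
                             seed = 4000 + r,
                             true_beta = eff$effects[, "NullT"])
    pgs <- build_pgs_matrix(list(ADHD = ss, NullT = ssn), geno, n_pcs = 4,
                            radius = 50)
    fit <- fit_univariate(pgs$corrected[, "ADHD"], coh$ps, make_covars(coh))
    fitn <- fit_univariate(pgs$corrected[, "NullT"], coh$ps, make_covars(coh))
    n_pos <- n_pos + (fit$or_per_sd > 1)
    n_null_sig <- n_null_sig + (fitn$p < 0.05)
  }
  expect_gte(n_pos / n_rep, 0.95)
  expect_lte(n_null_sig / n_rep, 0.2)  # null trait near nominal level
})
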