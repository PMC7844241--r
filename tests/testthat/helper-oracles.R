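# Independent oracles used across tests; each is a deliberately naive
# implementation kept separate from the package's code paths.

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by 1-D quadrature over the conditional normal
orthant_prob <- function(a, b, rho) {
  f <- function(z) stats::pnorm((b - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Pearson correlation between two Bernoulli indicators 1(Z1 < qnorm(p1)),
# 1(Z2 < qnorm(p2)) under latent correlation rho (equals the dosage
# correlation when dosages sum two independent such haplotypes)
binary_corr_oracle <- function(p1, p2, rho) {
  p11 <- orthant_prob(stats::qnorm(p1), stats::qnorm(p2), rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# brute-force greedy clumping on a dense correlation matrix
clump_oracle <- function(df, R, r2_max, window_bp) {
  claimed <- rep(FALSE, nrow(df))
  out <- character(0)
  repeat {
    cand <- which(!claimed)
    if (length(cand) == 0) break
    o <- cand[order(df$p[cand], df$chrom[cand], df$pos[cand])]
    i <- o[1]
    out <- c(out, df$id[i])
    claimed[i] <- TRUE
    for (j in which(!claimed)) {
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window_bp &&
          R[i, j]^2 >= r2_max) claimed[j] <- TRUE
    }
  }
  out
}

# exact two-sided Fisher p by exhaustive enumeration over tables with the
# observed margins (probability-summation convention)
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration over all group assignments
ranksum_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[seq_len(nx)])
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# least-squares residual via explicit normal equations
residual_oracle <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  as.numeric(y - Xi %*% beta)
}

# small deterministic genotype set for engine tests
small_geno_fixture <- function(n = 300, M = 60, n_blocks = 6, seed = 5,
                               fst = 0.1, anc = c(EA = 200, AA = 100)) {
  cfg <- sim_config(n_subjects_per_ancestry = anc, n_variants = M,
                    n_blocks = n_blocks, fst = fst,
                    trait_specs = default_trait_specs()[1:2], seed = seed)
  list(cfg = cfg, geno = simulate_genotypes(cfg))
}
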