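#' Harmonize GWAS summary statistics to a target variant table
#'
#' Aligns effect alleles to the target's a1/a2 by id: identical allele pairs
#' keep their beta, swapped pairs negate it, strand-flipped pairs (both
#' alleles complemented) are resolved then matched. Strand-ambiguous pairs
#' (A/T, C/G) cannot be disambiguated and are dropped under the default
#' policy. Every exclusion is logged with a reason, never silent.
#'
#' @param stats `sumstats` data.frame (SNP, A1, A2, BETA, P, ...).
#' @param variants target variant table (id, a1, a2, chrom, pos).
#' @param policy "drop_ambiguous" (default) or "keep_ambiguous".
#' @return list of class `harmonized_weights`: `weights` (data.frame id,
#'   chrom, pos, beta, p, idx = column index in the variant table) and
#'   `exclusions` (data.frame id, reason).
#' @export
harmonize <- function(stats, variants, policy = c("drop_ambiguous",
                                                  "keep_ambiguous")) {
  policy <- match.arg(policy)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- match(stats$SNP, variants$id)
  excl <- list()
  keep_id <- character(0); keep_beta <- numeric(0)
  keep_p <- numeric(0); keep_idx <- integer(0)
  for (i in seq_len(nrow(stats))) {
    if (is.na(m[i])) {
      excl[[length(excl) + 1]] <- c(stats$SNP[i], "absent-from-target")
      next
    }
    sa1 <- stats$A1[i]; sa2 <- stats$A2[i]
    ta1 <- variants$a1[m[i]]; ta2 <- variants$a2[m[i]]
    ambiguous <- comp[sa1] == sa2
    if (ambiguous && policy == "drop_ambiguous") {
      excl[[length(excl) + 1]] <- c(stats$SNP[i], "strand-ambiguous")
      next
    }
    beta <- if (sa1 == ta1 && sa2 == ta2) {
      stats$BETA[i]
    } else if (sa1 == ta2 && sa2 == ta1) {
      -stats$BETA[i]
    } else if (comp[sa1] == ta1 && comp[sa2] == ta2) {
      stats$BETA[i]
    } else if (comp[sa1] == ta2 && comp[sa2] == ta1) {
      -stats$BETA[i]
    } else {
      excl[[length(excl) + 1]] <- c(stats$SNP[i], "allele-mismatch")
      next
    }
    keep_id <- c(keep_id, stats$SNP[i])
    keep_beta <- c(keep_beta, beta)
    keep_p <- c(keep_p, stats$P[i])
    keep_idx <- c(keep_idx, m[i])
  }
  exclusions <- if (length(excl)) {
    data.frame(id = vapply(excl, `[`, "", 1),
               reason = vapply(excl, `[`, "", 2), stringsAsFactors = FALSE)
  } else data.frame(id = character(0), reason = character(0))
  structure(list(
    weights = data.frame(id = keep_id,
                         chrom = variants$chrom[keep_idx],
                         pos = variants$pos[keep_idx],
                         beta = keep_beta, p = keep_p, idx = keep_idx,
                         stringsAsFactors = FALSE),
    exclusions = exclusions), class = "harmonized_weights")
}

#' Banded LD view of a genotype matrix
#'
#' Precomputes dosage correlations r(j, j+l) for lags l = 1..radius from
#' standardized genotypes; correlations across chromosome boundaries are
#' zero by construction (and beyond the radius by definition).
#'
#' @param genotypes subjects x variants dosage matrix (no missing values;
#'   mean-impute first if needed).
#' @param variants variant table aligned with the columns (chrom, pos).
#' @param radius band half-width in number of flanking variants.
#' @return object of class `ld_view`.
#' @export
ld_view <- function(genotypes, variants, radius = 500) {
  M <- ncol(genotypes)
  n <- nrow(genotypes)
  X <- scale(genotypes)
  X[is.na(X)] <- 0  # monomorphic columns: zero correlation with everything
  radius <- min(radius, M - 1L)
  band <- matrix(0, max(radius, 1L), M)
  for (l in seq_len(radius)) {
    j <- seq_len(M - l)
    band[l, j] <- colSums(X[, j, drop = FALSE] * X[, j + l, drop = FALSE]) / (n - 1)
    same_chrom <- variants$chrom[j] == variants$chrom[j + l]
    band[l, j][!same_chrom] <- 0
  }
  structure(list(band = band, radius = radius, M = M,
                 chrom = variants$chrom, pos = variants$pos),
            class = "ld_view")
}

#' Correlation accessor for an [ld_view()]
#'
#' @param ld an `ld_view`.
#' @param i,j variant column indices.
#' @return r(i, j); 1 on the diagonal, 0 beyond the radius.
#' @export
ld_r <- function(ld, i, j) {
  if (i == j) return(1)
  l <- abs(i - j)
  if (l > ld$radius) return(0)
  ld$band[l, min(i, j)]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed variant as an index and removes
#' every unclaimed variant within `window_kb` of it whose r-squared with the
#' index is at least `r2_max`. Ties on p are broken by ascending (chrom,
#' pos), so the result is independent of input row order.
#'
#' @param weights a `harmonized_weights` (or its `weights` data.frame; needs
#'   id, chrom, pos, p, idx aligned with the LD view's columns).
#' @param ld an [ld_view()] over the full variant table.
#' @param r2_max r-squared ceiling (default 0.1).
#' @param window_kb window half-width in kilobases (default 500).
#' @return character vector of index variant ids (in selection order).
#' @export
ld_clump <- function(weights, ld, r2_max = 0.1, window_kb = 500) {
  w <- if (inherits(weights, "harmonized_weights")) weights$weights else weights
  if (nrow(w) == 0) return(character(0))
  ord <- order(w$p, w$chrom, w$pos)
  active <- rep(TRUE, ld$M)        # indexed by variant-table column
  present <- rep(FALSE, ld$M)
  present[w$idx] <- TRUE
  active <- active & present
  id_of <- character(ld$M); id_of[w$idx] <- w$id
  out <- character(0)
  win <- window_kb * 1000
  for (r in ord) {
    v <- w$idx[r]
    if (!active[v]) next
    out <- c(out, w$id[r])
    active[v] <- FALSE
    lo <- max(1L, v - ld$radius); hi <- min(ld$M, v + ld$radius)
    for (j in seq(lo, hi)) {
      if (!active[j]) next
      if (ld$chrom[j] != ld$chrom[v]) next
      if (abs(ld$pos[j] - ld$pos[v]) > win) next
      if (ld_r(ld, v, j)^2 >= r2_max) active[j] <- FALSE
    }
  }
  out
}

#' P-value thresholding of harmonized weights
#'
#' Retains variants with p strictly below `p_max` (the conventional
#' "threshold of 0.05" read strictly; configurable).
#'
#' @param weights a `harmonized_weights` or its `weights` data.frame.
#' @param p_max threshold (default 0.05).
#' @param keep_ids optional id subset to intersect with first (e.g. clump
#'   indices).
#' @return the filtered `weights` data.frame; retained count in a message.
#' @export
p_threshold <- function(weights, p_max = 0.05, keep_ids = NULL) {
  w <- if (inherits(weights, "harmonized_weights")) weights$weights else weights
  if (!is.null(keep_ids)) w <- w[w$id %in% keep_ids, , drop = FALSE]
  out <- w[w$p < p_max, , drop = FALSE]
  message(nrow(out), " variant(s) retained at p < ", p_max)
  out
}

#' Compute raw polygenic scores
#'
#' score_s = sum_v beta_v * dosage_{s,v}. Missing dosages are mean-imputed
#' per variant, within ancestry group when `group` is given.
#'
#' @param genotypes subjects x variants dosage matrix (column names = ids).
#' @param weights `weights` data.frame (id, beta) or `harmonized_weights`.
#' @param group optional ancestry labels for within-group mean imputation.
#' @return numeric score vector, one per subject.
#' @export
pgs_score <- function(genotypes, weights, group = NULL) {
  w <- if (inherits(weights, "harmonized_weights")) weights$weights else weights
  keep <- w$id %in% colnames(genotypes)
  if (!any(keep)) stop("no scoring variants overlap the genotype matrix")
  w <- w[keep, , drop = FALSE]
  G <- genotypes[, w$id, drop = FALSE]
  if (anyNA(G)) {
    groups <- if (is.null(group)) rep("all", nrow(G)) else group
    for (g in unique(groups)) {
      sel <- groups == g
      sub <- G[sel, , drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na_idx)) sub[na_idx] <- mu[na_idx[, 2]]
      G[sel, ] <- sub
    }
  }
  as.numeric(G %*% w$beta)
}

#' Infinitesimal-model LD adjustment of marginal effects
#'
#' Solves (D + (m/(n h2)) I) beta_adj = beta_hat where D is the banded LD
#' correlation matrix, i.e. the posterior mean effect under an
#' infinitesimal genetic architecture given LD from the target sample. The
#' system is solved exactly over the whole band (sparse Cholesky), which
#' coincides with the dense whole-matrix solution whenever the band covers
#' the true LD bandwidth. Under identity LD the adjustment reduces to
#' multiplication by n h2 / (n h2 + m).
#'
#' @param beta_hat numeric vector of marginal effects (aligned with the LD
#'   view's columns; standardized-genotype scale).
#' @param ld an [ld_view()] (or NULL for identity LD).
#' @param h2 assumed heritability of the trait, in (0, 1]; user input, not
#'   estimated here.
#' @param n GWAS sample size.
#' @param m number of variants (defaults to `length(beta_hat)`).
#' @return adjusted effect vector.
#' @export
ldpred_inf <- function(beta_hat, ld = NULL, h2, n, m = length(beta_hat)) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  lam <- m / (n * h2)
  if (is.null(ld)) return(beta_hat / (1 + lam))
  M <- length(beta_hat)
  if (M != ld$M) stop("beta_hat must align with the LD view")
  diags <- vector("list", ld$radius + 1)
  diags[[1]] <- rep(1 + lam, M)
  for (l in seq_len(ld$radius)) diags[[l + 1]] <- ld$band[l, seq_len(M - l)]
  A <- Matrix::bandSparse(M, M, k = 0:ld$radius, diagonals = diags,
                          symmetric = TRUE)
  x <- tryCatch(as.numeric(Matrix::solve(A, beta_hat)),
                error = function(e) {
                  message("singular LD system; adding 1e-6 ridge jitter")
                  A2 <- A + Matrix::Diagonal(M, 1e-6)
                  as.numeric(Matrix::solve(A2, beta_hat))
                })
  x
}

#' Ancestry principal components of a genotype matrix
#'
#' Top-k left singular vectors of the column-standardized genotype matrix
#' restricted to the given subjects (equivalently, eigenvectors of the
#' subject-subject covariance). Columns are orthonormal; each PC's sign is
#' fixed by making its largest-magnitude entry positive.
#'
#' @param genotypes subjects x variants dosage matrix.
#' @param subset optional logical/integer subject subset (an ancestry
#'   group); PCs are computed within it.
#' @param k number of components (default 10).
#' @return subjects-in-subset x k matrix.
#' @export
compute_pcs <- function(genotypes, subset = NULL, k = 10) {
  G <- if (is.null(subset)) genotypes else genotypes[subset, , drop = FALSE]
  n <- nrow(G); M <- ncol(G)
  if (k >= n) stop("k must be smaller than the number of subjects")
  X <- scale(G)
  X[is.na(X)] <- 0
  if (n <= M) {
    K <- tcrossprod(X)
    ev <- eigen(K, symmetric = TRUE)
    U <- ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    C <- crossprod(X)
    ev <- eigen(C, symmetric = TRUE)
    V <- ev$vectors[, seq_len(k), drop = FALSE]
    d <- sqrt(pmax(ev$values[seq_len(k)], .Machine$double.eps))
    U <- X %*% V %*% diag(1 / d, k)
    U <- qr.Q(qr(U))  # re-orthonormalize against numerical drift
  }
  for (j in seq_len(k)) {
    s <- U[which.max(abs(U[, j])), j]
    if (s < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("PC", seq_len(k))
  U
}

#' Residualize a score on PCs and standardize
#'
#' Least-squares residual of the score on an intercept plus the PCs,
#' divided by the residual standard deviation: mean 0, SD 1, and
#' uncorrelated with every PC within the group it was corrected in. These
#' corrected scores are what all downstream analyses consume.
#'
#' @param score numeric raw score vector.
#' @param pcs matrix of PC covariates (same subjects), or NULL for plain
#'   standardization.
#' @return corrected score vector.
#' @export
residualize_standardize <- function(score, pcs = NULL) {
  if (stats::sd(score) == 0) stop("degenerate score: zero variance")
  X <- if (is.null(pcs)) matrix(1, length(score), 1) else cbind(1, pcs)
  res <- stats::lm.fit(X, score)$residuals
  s <- stats::sd(res)
  if (s < 1e-12) stop("degenerate score: zero residual variance")
  (res - mean(res)) / s
}

#' Build a corrected PGS matrix for several traits
#'
#' Convenience wrapper: clump + threshold + score each trait's harmonized
#' weights, then PC-correct and standardize within each ancestry group.
#'
#' @param sumstats_list named list of `sumstats` objects.
#' @param geno list with `variants`, `genotypes`, `ancestry` (as produced
#'   by [simulate_genotypes()] or assembled from VCF input).
#' @param method "clump_pt" (default) or "ldpred_inf".
#' @param p_max,r2_max,window_kb clumping/thresholding parameters.
#' @param radius LD band radius (both clumping and ldpred_inf).
#' @param h2_map named numeric, per-trait assumed h2 (required for
#'   ldpred_inf).
#' @param n_pcs ancestry PCs per group (default 10).
#' @return list with `raw` and `corrected` subjects x traits matrices.
#' @export
build_pgs_matrix <- function(sumstats_list, geno,
                             method = c("clump_pt", "ldpred_inf"),
                             p_max = 0.05, r2_max = 0.1, window_kb = 500,
                             radius = 500, h2_map = NULL, n_pcs = 10) {
  method <- match.arg(method)
  ld <- ld_view(geno$genotypes, geno$variants, radius = radius)
  traits <- names(sumstats_list)
  n <- nrow(geno$genotypes)
  raw <- matrix(NA_real_, n, length(traits),
                dimnames = list(rownames(geno$genotypes), traits))
  for (tr in traits) {
    hw <- harmonize(sumstats_list[[tr]], geno$variants)
    if (method == "clump_pt") {
      idx <- ld_clump(hw, ld, r2_max = r2_max, window_kb = window_kb)
      w <- suppressMessages(p_threshold(hw, p_max = p_max, keep_ids = idx))
      raw[, tr] <- pgs_score(geno$genotypes, w, group = geno$ancestry)
    } else {
      if (is.null(h2_map) || is.null(h2_map[[tr]]))
        stop("ldpred_inf requires h2_map entries for every trait")
      w <- hw$weights
      beta_full <- numeric(ld$M)
      beta_full[w$idx] <- w$beta
      ss <- sumstats_list[[tr]]
      n_gwas <- stats::median(ss$N)
      adj <- ldpred_inf(beta_full, ld, h2 = h2_map[[tr]], n = n_gwas,
                        m = nrow(w))
      w$beta <- adj[w$idx]
      raw[, tr] <- pgs_score(geno$genotypes, w, group = geno$ancestry)
    }
  }
  corrected <- raw
  for (a in unique(geno$ancestry)) {
    sel <- geno$ancestry == a
    pcs <- compute_pcs(geno$genotypes, subset = sel,
                       k = min(n_pcs, sum(sel) - 1))
    for (tr in traits)
      corrected[sel, tr] <- residualize_standardize(raw[sel, tr], pcs)
  }
  list(raw = raw, corrected = corrected)
}
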