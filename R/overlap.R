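#' 2x2 contingency analysis of two binary phenotypes
#'
#' Tabulates (exposed&case, exposed&control, unexposed&case,
#' unexposed&control), reports the sample cross-product odds ratio
#' (a d)/(b c) with a Woolf log-scale 95% CI, and the exact two-sided
#' Fisher p (probability-summation convention). Subjects with a missing
#' value in either vector are dropped and counted. A zero cell triggers a
#' Haldane-Anscombe 0.5 correction for the OR/CI only, never for the
#' Fisher p; a zero margin leaves the OR undefined (flagged) with the
#' Fisher p still reported. The conditional-MLE OR (the Fisher-test
#' convention) is available behind a flag.
#'
#' @param exposure,outcome binary 0/1 vectors (NA allowed).
#' @param conditional_mle also report the conditional MLE OR.
#' @return list of class `contingency_result`: cells (a,b,c,d), or, ci_lo,
#'   ci_hi, fisher_p, n_missing, or_defined, (or_cmle).
#' @export
contingency <- function(exposure, outcome, conditional_mle = FALSE) {
  keep <- !is.na(exposure) & !is.na(outcome)
  n_missing <- sum(!keep)
  e <- exposure[keep]; o <- outcome[keep]
  a <- sum(e == 1 & o == 1); b <- sum(e == 1 & o == 0)
  c_ <- sum(e == 0 & o == 1); d <- sum(e == 0 & o == 0)
  ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
  margin_zero <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
  if (margin_zero) {
    or <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
    aa <- a + cc; bb <- b + cc; cc_ <- c_ + cc; dd <- d + cc
    or <- (aa * dd) / (bb * cc_)
    se <- sqrt(1 / aa + 1 / bb + 1 / cc_ + 1 / dd)
    lo <- exp(log(or) - 1.96 * se); hi <- exp(log(or) + 1.96 * se)
  }
  out <- list(cells = c(a = a, b = b, c = c_, d = d),
              or = or, ci_lo = lo, ci_hi = hi,
              fisher_p = ft$p.value, n_missing = n_missing,
              or_defined = !margin_zero)
  if (conditional_mle) out$or_cmle <- unname(ft$estimate)
  class(out) <- "contingency_result"
  out
}

#' Wilcoxon rank-sum test of a quantitative trait between two groups
#'
#' Two-sided, with tie correction (exact when sample sizes permit and no
#' ties are present; normal approximation otherwise).
#'
#' @param group binary 0/1 vector.
#' @param score numeric vector.
#' @return list: p, statistic (W for the group-1 sample), n1, n0.
#' @export
rank_sum <- function(group, score) {
  keep <- !is.na(group) & !is.na(score)
  group <- group[keep]; score <- score[keep]
  x <- score[group == 1]; y <- score[group == 0]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  wt <- stats::wilcox.test(x, y)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n1 = length(x), n0 = length(y))
}

#' Spearman rank correlation between two quantitative traits
#'
#' Midrank tie handling; p from the large-sample t approximation. A
#' constant input leaves rho undefined (flagged, with a warning).
#'
#' @param x,y numeric vectors.
#' @return list: rho, p, n, defined.
#' @export
rank_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Overlap battery over phenotype pairs
#'
#' Runs [contingency()] for binary pairs, [rank_sum()] for binary vs
#' quantitative, and [rank_correlation()] for quantitative pairs, per
#' cohort stratum.
#'
#' @param cohort cohort data.frame.
#' @param pairs list of character pairs `c(col1, col2)`.
#' @param by optional stratification column (e.g. "ancestry"); an "All"
#'   stratum is always included.
#' @return data.frame, one row per pair x stratum.
#' @export
overlap_battery <- function(cohort, pairs, by = NULL) {
  strata <- list(All = rep(TRUE, nrow(cohort)))
  if (!is.null(by))
    for (g in unique(cohort[[by]])) strata[[g]] <- cohort[[by]] == g
  rows <- list()
  for (s in names(strata)) {
    sub <- cohort[strata[[s]], , drop = FALSE]
    for (pr in pairs) {
      x <- sub[[pr[1]]]; y <- sub[[pr[2]]]
      binx <- all(stats::na.omit(x) %in% 0:1)
      biny <- all(stats::na.omit(y) %in% 0:1)
      if (binx && biny) {
        ct <- contingency(y, x)  # exposure = second member, outcome = first
        rows[[length(rows) + 1]] <-
          data.frame(stratum = s, trait1 = pr[1], trait2 = pr[2],
                     test = "fisher", estimate = ct$or,
                     ci_lo = ct$ci_lo, ci_hi = ct$ci_hi, p = ct$fisher_p)
      } else if (xor(binx, biny)) {
        g <- if (binx) x else y
        q <- if (binx) y else x
        rs <- rank_sum(g, q)
        rows[[length(rows) + 1]] <-
          data.frame(stratum = s, trait1 = pr[1], trait2 = pr[2],
                     test = "ranksum", estimate = rs$statistic,
                     ci_lo = NA_real_, ci_hi = NA_real_, p = rs$p)
      } else {
        rc <- rank_correlation(x, y)
        rows[[length(rows) + 1]] <-
          data.frame(stratum = s, trait1 = pr[1], trait2 = pr[2],
                     test = "spearman", estimate = rc$rho,
                     ci_lo = NA_real_, ci_hi = NA_real_, p = rc$p)
      }
    }
  }
  do.call(rbind, rows)
}
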