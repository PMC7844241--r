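#' Standard covariate set: age, age-squared, sex
#'
#' Age is centred before squaring to reduce collinearity (coefficients of
#' the score are unchanged by this reparameterization).
#'
#' @param cohort data.frame with `age` and `sex` columns.
#' @return data.frame with age_c, age_c2, sexM.
#' @export
make_covars <- function(cohort) {
  age_c <- cohort$age - mean(cohort$age)
  data.frame(age_c = age_c, age_c2 = age_c^2,
             sexM = as.integer(cohort$sex == "M"))
}

#' Univariate logistic association of a PGS with a binary outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the
#' (standardized) score plus covariates; the effect is reported as the odds
#' ratio per SD of score with a Wald 95% CI and two-sided Wald p. The
#' reduction in Nagelkerke R-squared relative to the covariates-only model
#' is attached. Perfect separation is flagged and the result marked
#' non-Wald (a small ridge penalty supplies the point estimate only).
#'
#' @param score numeric score (SD approximately 1; not rescaled here).
#' @param outcome binary 0/1 vector.
#' @param covars data.frame/matrix of covariates or NULL.
#' @param trait,cohort_label labels carried into the result row.
#' @return one-row data.frame of class `assoc_result`: trait, cohort, n,
#'   pct_outcome, or_per_sd, ci_lo, ci_hi, p, nagelkerke_delta_r2, notes.
#' @export
fit_univariate <- function(score, outcome, covars = NULL,
                           trait = "score", cohort_label = "All") {
  keep <- stats::complete.cases(score, outcome,
                                if (is.null(covars)) rep(0, length(score)) else covars)
  score <- score[keep]; outcome <- outcome[keep]
  if (!is.null(covars)) covars <- as.data.frame(covars)[keep, , drop = FALSE]
  if (length(unique(outcome)) < 2) stop("outcome has a single class")
  df <- data.frame(.y = outcome, .s = score)
  if (!is.null(covars)) df <- cbind(df, covars)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  null_fit <- stats::glm(.y ~ . - .s, data = df, family = stats::binomial())
  d_r2 <- nagelkerke_delta_r2(fit, null_fit)
  sm <- summary(fit)$coefficients
  b <- sm[".s", "Estimate"]; se <- sm[".s", "Std. Error"]
  notes <- ""
  if (sep) {
    # separation: Wald inference invalid; ridge-penalized point estimate
    Xm <- stats::model.matrix(fit)[, -1, drop = FALSE]
    rf <- glmnet::glmnet(Xm, outcome, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    b <- as.numeric(stats::coef(rf))[match(".s", colnames(Xm)) + 1]
    se <- NA_real_
    notes <- "separation: penalized estimate, non-Wald"
  }
  data.frame(trait = trait, cohort = cohort_label,
             n = length(outcome), pct_outcome = 100 * mean(outcome),
             or_per_sd = exp(b),
             ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
             p = if (sep) NA_real_ else 2 * stats::pnorm(-abs(b / se)),
             nagelkerke_delta_r2 = d_r2, notes = notes,
             stringsAsFactors = FALSE)
}

#' Bonferroni threshold for the univariate battery
#'
#' alpha divided by (number of scores x number of cohorts). The reported
#' value is rounded to one significant digit, the raw value retained.
#'
#' @param n_scores,n_cohorts test-grid dimensions.
#' @param alpha family-wise level (default 0.05).
#' @return list: raw, reported.
#' @export
bonferroni_threshold <- function(n_scores, n_cohorts, alpha = 0.05) {
  if (n_scores < 1 || n_cohorts < 1) stop("counts must be at least 1")
  raw <- alpha / (n_scores * n_cohorts)
  list(raw = raw, reported = signif(raw, 1))
}

#' PGS-by-modifier interaction and per-bin odds ratios
#'
#' Adds score x modifier to the full model and reports the Wald p of the
#' interaction term. For an age modifier, ORs are also reported within the
#' developmental bins [8,12), [12,16), [16,22] (half-open; the upper bin
#' closed).
#'
#' @param score,outcome,covars as in [fit_univariate()].
#' @param modifier numeric (age) or binary (sex indicator) vector.
#' @param bins numeric breakpoints for stratified ORs (default
#'   `c(8, 12, 16, 22)`); NULL to skip.
#' @return list: interaction_p, interaction_coef, bin_results (data.frame
#'   of per-bin [fit_univariate()] rows; empty bins omitted with warning).
#' @export
test_interaction <- function(score, outcome, modifier, covars = NULL,
                             bins = c(8, 12, 16, 22)) {
  df <- data.frame(.y = outcome, .s = score, .m = modifier)
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars))
  fit <- stats::glm(.y ~ .s * .m + ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  row <- grep("^\\.s:\\.m|^\\.m:\\.s", rownames(sm))
  out <- list(interaction_p = sm[row, "Pr(>|z|)"],
              interaction_coef = sm[row, "Estimate"])
  if (!is.null(bins)) {
    res <- list()
    for (b in seq_len(length(bins) - 1)) {
      hi_closed <- b == length(bins) - 1
      sel <- modifier >= bins[b] &
        (if (hi_closed) modifier <= bins[b + 1] else modifier < bins[b + 1])
      lab <- paste0("[", bins[b], ",", bins[b + 1], if (hi_closed) "]" else ")")
      if (sum(sel) == 0 || length(unique(outcome[sel])) < 2) {
        warning("bin ", lab, " empty or single-class; omitted")
        next
      }
      res[[lab]] <- fit_univariate(score[sel], outcome[sel],
                                   if (is.null(covars)) NULL else
                                     as.data.frame(covars)[sel, , drop = FALSE],
                                   cohort_label = lab)
    }
    out$bin_results <- do.call(rbind, res)
  }
  out
}

#' Decile contrast of PGS risk
#'
#' Subjects are binned into score deciles by empirical quantiles within the
#' analysis cohort (ties assigned to the lower decile); the top decile is
#' contrasted against the bottom decile by logistic regression.
#'
#' @param score,outcome,covars as in [fit_univariate()].
#' @return list: decile_props (case proportion per decile),
#'   top_vs_bottom (one-row data.frame: or, ci_lo, ci_hi, p).
#' @export
decile_contrast <- function(score, outcome, covars = NULL) {
  n <- length(score)
  if (length(unique(score)) < 10) stop("degenerate score: fewer than 10 distinct values")
  dec <- ceiling(10 * rank(score, ties.method = "min") / n)
  dec[dec < 1] <- 1
  props <- tapply(outcome, dec, mean)
  sel <- dec %in% c(1, 10)
  df <- data.frame(.y = outcome[sel], .top = as.integer(dec[sel] == 10))
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars)[sel, , drop = FALSE])
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  b <- sm[".top", "Estimate"]; se <- sm[".top", "Std. Error"]
  list(decile_props = props,
       top_vs_bottom = data.frame(or = exp(b), ci_lo = exp(b - 1.96 * se),
                                  ci_hi = exp(b + 1.96 * se),
                                  p = 2 * stats::pnorm(-abs(b / se))))
}

#' Nagelkerke pseudo-R-squared difference between nested logistic models
#'
#' R2 = (1 - exp(2(l0 - l1)/n)) / (1 - exp(2 l0 / n)) with l0 the
#' intercept-only log-likelihood; the delta is R2(full) - R2(reduced),
#' nonnegative up to numerical tolerance for nested fits.
#'
#' @param model_with_score,model_without nested `glm` fits on identical
#'   subjects.
#' @return numeric proportion.
#' @export
nagelkerke_delta_r2 <- function(model_with_score, model_without) {
  n1 <- stats::nobs(model_with_score); n0 <- stats::nobs(model_without)
  if (n1 != n0) stop("models must be fit on identical subjects")
  .nag <- function(fit) {
    ll1 <- as.numeric(stats::logLik(fit))
    y <- fit$y
    pbar <- mean(y)
    ll0 <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
    n <- stats::nobs(fit)
    (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  }
  .nag(model_with_score) - .nag(model_without)
}

#' Sensitivity refit under row exclusions and extra covariates
#'
#' Applies the exclusion mask, optionally appends covariates (complete-case:
#' rows with missing extra covariates are dropped and the analysis n
#' reported), and refits [fit_univariate()].
#'
#' @param score,outcome,covars as in [fit_univariate()].
#' @param exclude logical vector, TRUE = drop the subject.
#' @param extra_covars data.frame of additional covariates or NULL.
#' @param ... labels passed to [fit_univariate()].
#' @return `assoc_result` row with a notes field describing the refit.
#' @export
sensitivity_refit <- function(score, outcome, covars = NULL, exclude = NULL,
                              extra_covars = NULL, ...) {
  n <- length(score)
  keep <- if (is.null(exclude)) rep(TRUE, n) else !exclude
  if (!is.null(extra_covars)) {
    extra_covars <- as.data.frame(extra_covars)
    keep <- keep & stats::complete.cases(extra_covars)
  }
  if (length(unique(outcome[keep])) < 2)
    stop("exclusion removed all subjects of one outcome class")
  cv <- if (is.null(covars)) NULL else as.data.frame(covars)[keep, , drop = FALSE]
  if (!is.null(extra_covars)) {
    ec <- extra_covars[keep, , drop = FALSE]
    cv <- if (is.null(cv)) ec else cbind(cv, ec)
  }
  res <- fit_univariate(score[keep], outcome[keep], cv, ...)
  res$notes <- paste0("excluded ", n - sum(keep), "/", n, " subjects",
                      if (!is.null(extra_covars))
                        paste0("; +", ncol(extra_covars), " covariate(s)") else "")
  res
}

#' Linear association of a PGS with a quantitative scale
#'
#' Least squares of the outcome on the score (standardized internally, so
#' beta is per SD) plus covariates; Wald p on the score term. Adding a
#' constant to the outcome leaves beta unchanged.
#'
#' @param score,covars as in [fit_univariate()].
#' @param outcome numeric scale (e.g. PRIME or SOPS severity).
#' @return list: beta, se, p, n.
#' @export
fit_quantitative <- function(score, outcome, covars = NULL) {
  if (stats::sd(outcome) == 0) stop("constant outcome")
  df <- data.frame(.y = outcome, .s = as.numeric(scale(score)))
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars))
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(beta = sm[".s", "Estimate"], se = sm[".s", "Std. Error"],
       p = sm[".s", "Pr(>|t|)"], n = length(outcome))
}
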