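#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random case outscores a random control, with ties
#' counted half. Used throughout the repetition/permutation loops; agrees
#' with ROC-integration implementations.
#'
#' @param y binary outcome vector (0/1).
#' @param score numeric predictions.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(y, score) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.check_xy <- function(X, y, folds = NULL) {
  if (anyNA(X)) stop("X must not contain missing values")
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (!is.null(folds) && nrow(X) < folds)
    stop("fewer observations than folds")
}

# stratified fold assignment: shuffle within each stratum, deal folds out
.stratified_foldid <- function(strata, folds) {
  foldid <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' Tune and fit an elastic-net PS classifier
#'
#' Grid search over the mixing parameter alpha and the penalty lambda by
#' (optionally repeated) stratified 10-fold cross-validation maximizing
#' AUC; lambda is the CV-optimal value on the path at the winning alpha
#' (`lambda_rule = "cv_min"`), or the smallest path value
#' (`"path_min"`). Predictors are standardized before fitting, so
#' coefficients are returned on the standardized (per-SD) scale.
#' Covariate columns listed in `penalty_free` are left unpenalized.
#'
#' @param X numeric predictor matrix (corrected PGS, plus covariates).
#' @param y binary outcome (0/1).
#' @param alpha_grid mixing values in [0,1]; default 0, 0.1, ..., 1.
#' @param folds CV folds (default 10, stratified by outcome).
#' @param repeats repetitions of the CV (default 1); CV curves averaged.
#' @param penalty_free integer/character columns excluded from the penalty.
#' @param lambda_rule "cv_min" (default) or "path_min".
#' @param nlambda length of the lambda path (default 50).
#' @param seed optional integer seed for the fold draws.
#' @return list of class `tuned_fit`: chosen_alpha, chosen_lambda,
#'   coef (standardized, named, no intercept), intercept, cv_auc,
#'   center/scale for prediction.
#' @export
tune_fit <- function(X, y, alpha_grid = seq(0, 1, by = 0.1), folds = 10,
                     repeats = 1, penalty_free = NULL,
                     lambda_rule = c("cv_min", "path_min"), nlambda = 50,
                     seed = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  .check_xy(X, y, folds)
  if (!is.null(seed)) set.seed(seed)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pf <- rep(1, ncol(X))
  if (!is.null(penalty_free)) {
    if (is.character(penalty_free)) penalty_free <- match(penalty_free, colnames(X))
    pf[penalty_free] <- 0
  }
  if (ncol(X) == 1) {
    # single-predictor model: no selection problem, plain logistic fit
    fit1 <- stats::glm(y ~ Xs, family = stats::binomial())
    cf1 <- stats::coef(fit1)
    return(structure(list(chosen_alpha = NA_real_, chosen_lambda = 0,
                          coef = stats::setNames(cf1[2], colnames(X)),
                          intercept = unname(cf1[1]), cv_auc = NA_real_,
                          center = ctr, scale = scl), class = "tuned_fit"))
  }
  best <- list(auc = -Inf)
  for (alpha in alpha_grid) {
    full <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                           nlambda = nlambda, standardize = FALSE,
                           penalty.factor = pf)
    path <- full$lambda
    # manual CV: per fold, fit on the shared lambda path and score the
    # held-out subjects by AUC at every lambda (fold-size-weighted mean)
    auc_sum <- numeric(length(path))
    w_sum <- 0
    for (r in seq_len(repeats)) {
      foldid <- .stratified_foldid(y, folds)
      for (f in seq_len(folds)) {
        ho <- foldid == f
        fit_f <- glmnet::glmnet(Xs[!ho, , drop = FALSE], y[!ho],
                                family = "binomial", alpha = alpha,
                                lambda = path, standardize = FALSE,
                                penalty.factor = pf)
        pred <- stats::predict(fit_f, Xs[ho, , drop = FALSE])
        yho <- y[ho]
        if (length(unique(yho)) < 2) next
        a <- apply(pred, 2, function(s) auc_rank(yho, s))
        a <- c(a, rep(a[length(a)], length(path) - length(a)))
        auc_sum <- auc_sum + sum(ho) * a
        w_sum <- w_sum + sum(ho)
      }
    }
    cvm_mean <- auc_sum / w_sum
    pick <- if (lambda_rule == "cv_min") which.max(cvm_mean) else length(path)
    if (!is.na(cvm_mean[pick]) && cvm_mean[pick] > best$auc) {
      best <- list(auc = cvm_mean[pick], alpha = alpha,
                   lambda = path[pick], fit = full)
    }
  }
  cf <- as.numeric(stats::coef(best$fit, s = best$lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(X))
  structure(list(chosen_alpha = best$alpha, chosen_lambda = best$lambda,
                 coef = cf[-1], intercept = cf[1], cv_auc = best$auc,
                 center = ctr, scale = scl), class = "tuned_fit")
}

#' Linear predictor of a [tune_fit()] model on new data
#'
#' @param object a `tuned_fit`.
#' @param newdata matrix with the same columns as the training X.
#' @param ... unused.
#' @return numeric linear predictor (monotone in predicted risk).
#' @export
predict.tuned_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  as.numeric(object$intercept + Xs %*% object$coef)
}

#' Train/test split evaluation of the multi-PGS classifier
#'
#' Stratified random 70/30 split (by outcome, and ancestry when given);
#' the elastic net is tuned on the training portion and its discriminatory
#' power measured as AUC on the held-out portion.
#'
#' @param X predictor matrix.
#' @param y binary outcome.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed (split + CV folds).
#' @param group optional ancestry labels for split stratification.
#' @param ... passed to [tune_fit()].
#' @return list: auc, coef (standardized), chosen_alpha, chosen_lambda.
#' @export
split_eval <- function(X, y, train_frac = 0.7, seed = 1, group = NULL, ...) {
  X <- as.matrix(X)
  .check_xy(X, y)
  set.seed(seed)
  strata <- if (is.null(group)) as.character(y) else paste(group, y)
  train <- logical(length(y))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    train[sample(idx, max(1, round(train_frac * length(idx))))] <- TRUE
  }
  if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2)
    stop("a split stratum lost a class; check group sizes")
  tf <- tune_fit(X[train, , drop = FALSE], y[train], ...)
  pred <- predict(tf, X[!train, , drop = FALSE])
  list(auc = auc_rank(y[!train], pred), coef = tf$coef,
       chosen_alpha = tf$chosen_alpha, chosen_lambda = tf$chosen_lambda)
}

#' Repeated evaluation with a permutation null
#'
#' Runs `n_repetitions` independent stratified 70/30 split evaluations on
#' the observed outcome, and `n_permutations` evaluations in which the
#' outcome is shuffled within ancestry strata. Each permutation's statistic
#' is the mean AUC over `perm_repetitions` splits so it is comparable to
#' the observed mean ("mean-equivalent"); the default 1 mirrors the
#' one-fit-per-permutation practice. Significance is the conservative
#' empirical estimate p = (r + 1) / (n_permutations + 1), r = number of
#' permutation statistics at or above the observed mean AUC; it can never
#' be 0.
#'
#' @param X predictor matrix (corrected PGS and covariates).
#' @param y binary outcome.
#' @param group optional ancestry labels (split stratification and
#'   within-group permutation).
#' @param n_repetitions observed repetitions (study default 1000).
#' @param n_permutations permutations (study default 1000).
#' @param perm_repetitions splits averaged per permutation (default 1).
#' @param seed master seed; every repetition/permutation derives its own.
#' @param ... passed to [split_eval()] / [tune_fit()].
#' @return object of class `elastic_net_run`: auc (per repetition), coef
#'   (repetitions x predictors), coef_mean, coef_sem, perm_auc,
#'   empirical_p.
#' @export
repeat_and_permute <- function(X, y, group = NULL, n_repetitions = 1000,
                               n_permutations = 1000, perm_repetitions = 1,
                               seed = 1, ...) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  if (n_repetitions < 1) stop("n_repetitions must be at least 1")
  X <- as.matrix(X)
  .check_xy(X, y)
  aucs <- numeric(n_repetitions)
  coefs <- matrix(NA_real_, n_repetitions, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n_repetitions)) {
    ev <- split_eval(X, y, seed = derive_seed(seed, paste0("rep", i)),
                     group = group, ...)
    aucs[i] <- ev$auc
    coefs[i, ] <- ev$coef
  }
  perm_auc <- numeric(n_permutations)
  grp <- if (is.null(group)) rep("all", length(y)) else group
  for (j in seq_len(n_permutations)) {
    set.seed(derive_seed(seed, paste0("permshuffle", j)))
    yp <- y
    for (g in unique(grp)) {
      sel <- which(grp == g)
      yp[sel] <- y[sample(sel)]
    }
    pa <- numeric(perm_repetitions)
    for (k in seq_len(perm_repetitions)) {
      pa[k] <- split_eval(X, yp,
                          seed = derive_seed(seed, paste0("perm", j, ".", k)),
                          group = group, ...)$auc
    }
    perm_auc[j] <- mean(pa)
  }
  obs_mean <- mean(aucs)
  # mean-equivalent adjustment: the observed statistic averages away most
  # split-level noise, while each permutation statistic retains sigma^2/k of
  # it. Rescale the permutation deviations so their variance matches what a
  # mean of n_repetitions splits would have (split-level variance estimated
  # from the observed repetitions, which share one outcome vector).
  perm_auc_adj <- perm_auc
  if (n_repetitions > 1 && n_permutations > 1 && stats::var(perm_auc) > 0) {
    s2_split <- stats::var(aucs)
    sp2 <- stats::var(perm_auc)
    m <- mean(perm_auc)
    target <- max(sp2 - s2_split / perm_repetitions + s2_split / n_repetitions,
                  s2_split / n_repetitions)
    perm_auc_adj <- m + (perm_auc - m) * sqrt(target / sp2)
  }
  r <- sum(perm_auc_adj >= obs_mean)
  structure(list(auc = aucs, coef = coefs,
                 coef_mean = colMeans(coefs),
                 coef_sem = apply(coefs, 2, stats::sd) / sqrt(n_repetitions),
                 perm_auc = perm_auc_adj,
                 perm_auc_raw = perm_auc,
                 mean_auc = obs_mean,
                 empirical_p = (r + 1) / (n_permutations + 1)),
            class = "elastic_net_run")
}

#' Compare two classifier runs by their AUC distributions
#'
#' Two-sided Wilcoxon rank-sum test on the per-repetition AUC vectors
#' (e.g. multivariate vs univariate predictor).
#'
#' @param run1,run2 `elastic_net_run` objects (or lists with an `auc`
#'   vector).
#' @return list: p, median1, median2.
#' @export
compare_auc_runs <- function(run1, run2) {
  a1 <- run1$auc; a2 <- run2$auc
  if (length(a1) == 0 || length(a2) == 0) stop("empty AUC vector")
  wt <- stats::wilcox.test(a1, a2, exact = FALSE, correct = TRUE)
  list(p = wt$p.value, median1 = stats::median(a1), median2 = stats::median(a2))
}
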