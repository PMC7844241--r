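# logistic cohort simulator on the odds scale: P(y|s) = plogis(a + log(or) s)
sim_logistic <- function(n, or, prev, seed, score = NULL) {
  set.seed(seed)
  s <- if (is.null(score)) stats::rnorm(n) else score
  a <- stats::uniroot(function(a)
    mean(stats::plogis(a + log(or) * s)) - prev, c(-20, 20))$root
  list(s = s, y = stats::rbinom(n, 1, stats::plogis(a + log(or) * s)))
}

test_that("logistic OR on a binary exposure equals the cross-product OR", {
  # Table-2-style cells: (exposed case, exposed control, unexposed case,
  # unexposed control) = (151, 233, 1115, 5220)
  cells <- c(151, 233, 1115, 5220)
  exposure <- rep(c(1, 1, 0, 0), cells)
  outcome <- rep(c(1, 0, 1, 0), cells)
  fit <- fit_univariate(exposure, outcome)
  expect_equal(fit$or_per_sd, (151 * 5220) / (233 * 1115), tolerance = 1e-8)
  expect_equal(round(fit$or_per_sd, 1), 3.0)
  ct <- contingency(exposure, outcome)
  expect_equal(ct$or, fit$or_per_sd, tolerance = 1e-8)
})

test_that("null simulations give nominal CI coverage", {
  cover <- vapply(1:100, function(r) {
    d <- sim_logistic(2000, or = 1, prev = 0.19, seed = 5000 + r)
    set.seed(70000 + r)
    cv <- data.frame(age_c = stats::rnorm(2000), sexM = rbinom(2000, 1, 0.5))
    fit <- fit_univariate(d$s, d$y, cv)
    fit$ci_lo <= 1 && 1 <= fit$ci_hi
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("a configured OR of 1.23 per SD is recovered on average", {
  ors <- vapply(1:100, function(r)
    with(sim_logistic(4800, 1.23, 0.15, 6000 + r),
         fit_univariate(s, y)$or_per_sd), 0)
  expect_equal(mean(ors), 1.23, tolerance = 0.03 / 1.23)
})

test_that("Bonferroni cutoff follows the test-grid arithmetic", {
  bf <- bonferroni_threshold(14, 3)
  expect_equal(bf$raw, 0.05 / 42, tolerance = 1e-12)
  expect_equal(bf$reported, 0.001)
  expect_equal(bonferroni_threshold(1, 1)$raw, 0.05)
  expect_equal(bonferroni_threshold(10, 2)$raw, 0.0025)
  expect_error(bonferroni_threshold(0, 3), "at least 1")
})

test_that("interaction test is calibrated under the null and detects decline", {
  # null: no interaction simulated; Wald p uniform
  rej <- vapply(1:200, function(r) {
    d <- sim_logistic(800, 1.3, 0.2, 7000 + r)
    set.seed(90000 + r)
    age <- stats::runif(800, 8, 22)
    test_interaction(d$s, d$y, age, bins = NULL)$interaction_p < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.02 / 0.05)

  # log-OR declining in age at -0.03/yr: negative estimated slope
  neg <- vapply(1:100, function(r) {
    set.seed(8000 + r)
    n <- 4800
    s <- stats::rnorm(n)
    age <- stats::runif(n, 8, 22)
    b <- log(1.23) - 0.03 * (age - 15)
    a <- stats::uniroot(function(a)
      mean(stats::plogis(a + b * s)) - 0.15, c(-20, 20))$root
    y <- stats::rbinom(n, 1, stats::plogis(a + b * s))
    ti <- test_interaction(s, y, age, bins = NULL)
    ti$interaction_coef < 0
  }, logical(1))
  expect_gte(mean(neg), 0.90)

  # age-bin ORs are reported for the three developmental bins
  d <- sim_logistic(3000, 1.3, 0.2, 8999)
  set.seed(91000)
  age <- stats::runif(3000, 8, 22)
  ti <- test_interaction(d$s, d$y, age)
  expect_equal(rownames(ti$bin_results), c("[8,12)", "[12,16)", "[16,22]"))
  expect_true(all(ti$bin_results$n > 0))
})

test_that("sex-symmetric effects yield near-identical stratified ORs", {
  diffs <- vapply(1:40, function(r) {
    d <- sim_logistic(6000, 1.25, 0.17, 9500 + r)
    set.seed(95000 + r)
    sex <- rep(c("M", "F"), 3000)
    or_m <- fit_univariate(d$s[sex == "M"], d$y[sex == "M"])$or_per_sd
    or_f <- fit_univariate(d$s[sex == "F"], d$y[sex == "F"])$or_per_sd
    or_m - or_f
  }, 0)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("decile contrast matches the truncated-normal analytic oracle", {
  # mean of a standard normal above its 90th percentile
  z90 <- stats::qnorm(0.9)
  mu_top <- stats::dnorm(z90) / 0.1
  or_expect <- exp(log(1.23) * 2 * mu_top)   # ~2.07
  expect_equal(or_expect, 2.07, tolerance = 0.005 / 2.07)

  ors <- vapply(1:200, function(r) {
    d <- sim_logistic(5000, 1.23, 0.15, 10000 + r)
    decile_contrast(d$s, d$y)$top_vs_bottom$or
  }, 0)
  expect_lt(abs(mean(ors) - or_expect), 0.15)

  # monotone enrichment across deciles under a positive effect
  mono <- vapply(1:100, function(r) {
    d <- sim_logistic(5000, 1.3, 0.15, 11000 + r)
    dc <- decile_contrast(d$s, d$y)
    stats::cor(seq_len(10), as.numeric(dc$decile_props),
               method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(mono), 0.95)

  # null: CI covers 1 at roughly nominal rate
  cover <- vapply(1:100, function(r) {
    d <- sim_logistic(3000, 1.0, 0.2, 12000 + r)
    tb <- decile_contrast(d$s, d$y)$top_vs_bottom
    tb$ci_lo <= 1 && 1 <= tb$ci_hi
  }, logical(1))
  expect_gte(mean(cover), 0.90)

  expect_error(decile_contrast(rep(1, 100), rbinom(100, 1, 0.5)),
               "degenerate")
})

test_that("Nagelkerke delta R2 matches the likelihood formula", {
  # zero-coefficient score adds nothing
  set.seed(14)
  y <- rbinom(500, 1, 0.3)
  x <- rnorm(500)
  f1 <- stats::glm(y ~ x, family = stats::binomial())
  f0 <- stats::glm(y ~ 1, family = stats::binomial())
  d <- nagelkerke_delta_r2(f1, f0)
  expect_gte(d, 0)
  expect_lt(d, 0.02)

  # near-perfect predictor: R2 approaches 1
  xs <- y + rnorm(500, sd = 0.05)
  fs <- suppressWarnings(stats::glm(y ~ xs, family = stats::binomial()))
  expect_gt(nagelkerke_delta_r2(fs, f0), 0.9)

  # 20-subject fixture against the hand-computed formula
  set.seed(15)
  y20 <- rbinom(20, 1, 0.5)
  x20 <- rnorm(20) + 0.8 * y20
  full <- stats::glm(y20 ~ x20, family = stats::binomial())
  null <- stats::glm(y20 ~ 1, family = stats::binomial())
  ll1 <- as.numeric(stats::logLik(full))
  ll0 <- as.numeric(stats::logLik(null))
  want <- (1 - exp(2 * (ll0 - ll1) / 20)) / (1 - exp(2 * ll0 / 20))
  expect_equal(nagelkerke_delta_r2(full, null), want, tolerance = 1e-8)
  expect_error(nagelkerke_delta_r2(full, stats::glm(y ~ 1, family = stats::binomial())),
               "identical subjects")
})

test_that("sensitivity refits behave as no-ops, mediation and direct effects", {
  d <- sim_logistic(3000, 1.3, 0.2, 16000)
  base <- fit_univariate(d$s, d$y)
  noop <- sensitivity_refit(d$s, d$y, exclude = rep(FALSE, 3000))
  expect_equal(noop$or_per_sd, base$or_per_sd, tolerance = 1e-12)

  # mediation: score -> mediator flag -> outcome, no direct path.
  # excluding flag-endorsers must pull the estimate towards 1
  closer <- vapply(1:20, function(r) {
    set.seed(17000 + r)
    n <- 4000
    s <- stats::rnorm(n)
    med <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * s))
    y <- stats::rbinom(n, 1, stats::plogis(-2 + 1.2 * med))
    b0 <- fit_univariate(s, y)$or_per_sd
    b1 <- sensitivity_refit(s, y, exclude = med == 1)$or_per_sd
    abs(log(b1)) < abs(log(b0))
  }, logical(1))
  expect_gte(mean(closer), 0.90)

  # direct effect with outcome-driven comorbidity: stable after exclusion
  base_ors <- numeric(20); excl_ors <- numeric(20)
  for (r in 1:20) {
    set.seed(18000 + r)
    n <- 4000
    d <- sim_logistic(n, 1.23, 0.15, 18000 + r)
    flag <- stats::rbinom(n, 1, stats::plogis(-0.3 + log(4.7) * d$y))
    base_ors[r] <- fit_univariate(d$s, d$y)$or_per_sd
    excl_ors[r] <- sensitivity_refit(d$s, d$y, exclude = flag == 1)$or_per_sd
  }
  expect_lt(abs(mean(base_ors) - mean(excl_ors)), 0.05)

  # appending extra covariates drops incomplete rows, reports n
  d <- sim_logistic(3000, 1.3, 0.2, 16000)
  extra <- data.frame(subst = c(rep(NA, 1500), rbinom(1500, 1, 0.2)))
  sr <- sensitivity_refit(d$s, d$y, extra_covars = extra)
  expect_equal(sr$n, 1500)
  expect_match(sr$notes, "covariate")
  expect_error(sensitivity_refit(d$s, d$y, exclude = d$y == 1),
               "outcome class")
})

test_that("quantitative scale association recovers effects per SD", {
  betas5 <- vapply(1:5, function(r) {
    set.seed(19 + r)
    s <- rnorm(5000)
    fit_quantitative(s, 0.5 * s + rnorm(5000))$beta
  }, 0)
  expect_equal(mean(betas5), 0.5, tolerance = 0.02 / 0.5)
  set.seed(19)
  s <- rnorm(5000)
  out <- 0.5 * s + rnorm(5000)
  fq <- fit_quantitative(s, out)
  # location invariance
  fq2 <- fit_quantitative(s, out + 100)
  expect_equal(fq$beta, fq2$beta, tolerance = 1e-10)
  # null: beta centred at 0
  betas <- vapply(1:50, function(r) {
    set.seed(20000 + r)
    fit_quantitative(rnorm(800), rnorm(800))$beta
  }, 0)
  expect_lt(abs(mean(betas)), 0.01)
  expect_error(fit_quantitative(s, rep(2, 5000)), "constant")
})

test_that("estimates are invariant to subject ordering", {
  d <- sim_logistic(1000, 1.4, 0.2, 21000)
  set.seed(22000)
  perm <- sample(1000)
  f1 <- fit_univariate(d$s, d$y)
  f2 <- fit_univariate(d$s[perm], d$y[perm])
  expect_equal(f1$or_per_sd, f2$or_per_sd, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})
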