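test_that("the unrelated limit reproduces OLS to six decimals", {
  set.seed(21)
  n <- 120
  x <- rnorm(n)
  covars <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 50, 80))
  y <- 0.4 * x + 0.2 * covars$sex + rnorm(n)
  ols <- summary(lm(y ~ x + sex + age, data = covars))$coefficients

  # singleton families (identity grouping covariance)
  f1 <- fit_feature_lmm(y, x, covars, family = seq_len(n))
  expect_equal(f1$beta, ols["x", "Estimate"], tolerance = 1e-9)
  expect_equal(f1$se, ols["x", "Std. Error"], tolerance = 1e-9)

  # forced-OLS flag with real families present
  fam <- sample(rep(1:30, 4))
  f2 <- fit_feature_lmm(y, x, covars, family = fam, force_ols = TRUE)
  expect_equal(f2$beta, ols["x", "Estimate"], tolerance = 1e-9)
  expect_equal(f2$se, ols["x", "Std. Error"], tolerance = 1e-9)
})

test_that("REML estimates agree with lme4 on clustered data", {
  skip_if_not_installed("lme4")
  set.seed(22)
  n <- 240
  fam <- sample(rep(1:60, 4))
  u <- rnorm(60, 0, 1)[fam]
  x <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.3 * x + 0.5 * sex + u + rnorm(n)
  ours <- fit_feature_lmm(y, x, data.frame(sex = sex), family = fam)
  ref <- lme4::lmer(y ~ x + sex + (1 | fam), REML = TRUE)
  s <- summary(ref)$coefficients
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(ours$beta, s["x", "Estimate"], tolerance = 1e-6)
  expect_equal(ours$se, s["x", "Std. Error"], tolerance = 1e-6)
  expect_equal(ours$sigma2_g, vc$vcov[1], tolerance = 1e-4)
  expect_equal(ours$sigma2_e, vc$vcov[2], tolerance = 1e-4)
})

test_that("a block kinship matrix reproduces the family-id fit", {
  set.seed(23)
  n <- 150
  fam <- sample(rep(1:50, 3))
  y <- rnorm(50, 0, 0.8)[fam] + rnorm(n)
  x <- rnorm(n)
  f_fam <- fit_feature_lmm(y, x, family = fam)
  K <- outer(fam, fam, "==") * 1.0
  f_kin <- fit_feature_lmm(y, x, kinship = K)
  expect_equal(f_kin$beta, f_fam$beta, tolerance = 1e-8)
  expect_equal(f_kin$se, f_fam$se, tolerance = 1e-8)
})

test_that("null features yield uniform p-values under family clustering", {
  set.seed(24)
  n <- 200
  fam <- sample(rep(1:50, 4))
  u <- rnorm(50)[fam]
  x <- rnorm(n)
  Y <- matrix(rnorm(1000 * n), 1000, n) + matrix(u, 1000, n, byrow = TRUE)
  res <- inflammage:::lmm_scan(Y, cbind(1, delta = x), family = fam)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("a planted effect is recovered without bias", {
  set.seed(25)
  b <- 0.3
  reps <- 60
  n <- 300
  est <- vapply(seq_len(reps), function(i) {
    fam <- sample(rep(1:100, 3))
    u <- rnorm(100, 0, 0.7)[fam]
    x <- rnorm(n)
    y <- b * x + u + rnorm(n)
    f <- fit_feature_lmm(y, x, family = fam)
    c(f$beta, f$se)
  }, numeric(2))
  mc_se <- sd(est[1, ]) / sqrt(reps)
  expect_lt(abs(mean(est[1, ]) - b), 3 * mc_se)
  # reported SE tracks the Monte-Carlo spread (REML Wald SEs ignore
  # variance-component uncertainty, so only rough agreement is expected)
  expect_lt(abs(mean(est[2, ]) / sd(est[1, ]) - 1), 0.5)
})

test_that("ignoring real family structure inflates null z-scores", {
  set.seed(26)
  n <- 200
  fam <- sample(rep(1:40, 5))
  u <- rnorm(40, 0, 1.5)[fam]
  x <- rnorm(40)[fam]   # exposure shared within family, as kinship confounds
  Y <- matrix(rnorm(400 * n), 400, n) + matrix(u, 400, n, byrow = TRUE)
  X <- cbind(1, delta = x)
  z_lmm <- inflammage:::lmm_scan(Y, X, family = fam)$z
  z_ols <- inflammage:::lmm_scan(Y, X, family = fam, force_ols = TRUE)$z
  expect_gt(var(z_ols), 2 * var(z_lmm))
})

test_that("run_scan aligns subjects, applies Bonferroni and keeps sign bookkeeping", {
  study <- small_study(seed = 27)
  est <- kd_estimates(study$cohort)
  scan <- run_scan(study$expression, est, study$cohort,
                   covariate_names = scan_covars)
  expect_equal(scan$alpha_bonferroni, 0.05 / nrow(study$expression))
  expect_equal(scan$n_positive + scan$n_negative, scan$n_significant)
  expect_identical(nrow(scan$results), nrow(study$expression))

  # shuffled subject columns give identical results
  shuf <- study$expression[, sample(ncol(study$expression))]
  scan2 <- run_scan(shuf, est, study$cohort, covariate_names = scan_covars)
  expect_equal(scan2$results$beta, scan$results$beta, tolerance = 1e-6)

  # empty feature set
  scan0 <- run_scan(study$expression[0, , drop = FALSE], est, study$cohort)
  expect_equal(scan0$n_features, 0L)
  expect_equal(nrow(scan0$results), 0L)

  # disjoint subjects error
  renamed <- study$expression
  colnames(renamed) <- paste0("X", colnames(renamed))
  expect_error(run_scan(renamed, est, study$cohort), "overlapping")

  # collinear covariates are named
  cohort_bad <- study$cohort
  cohort_bad$sex2 <- cohort_bad$sex
  expect_error(
    run_scan(study$expression[1:2, ], est, cohort_bad,
             covariate_names = c("sex", "sex2")),
    "collinear"
  )
})

test_that("volcano coordinates are monotone with the threshold on the line", {
  study <- small_study(seed = 28)
  est <- kd_estimates(study$cohort)
  scan <- run_scan(study$expression[1:50, ], est, study$cohort)
  vt <- volcano_table(scan)
  o <- order(scan$results$p)
  expect_true(all(diff(vt$neg_log10_p[o]) <= 1e-12))
  # p exactly at alpha sits on the dashed line and is not flagged
  vt2 <- volcano_table(tibble::tibble(feature = "f", gene = "f", beta = 1,
                                      p = scan$alpha_bonferroni),
                       alpha = scan$alpha_bonferroni)
  expect_equal(vt2$neg_log10_p, attr(vt2, "threshold"))
  expect_false(vt2$significant)
  vt3 <- volcano_table(tibble::tibble(feature = "f", gene = "f", beta = 1, p = 1),
                       alpha = 0.05)
  expect_equal(vt3$neg_log10_p, 0)
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
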