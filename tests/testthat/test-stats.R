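test_that("linear_regression recovers an exact fit", {
  x <- 1:10
  fit <- linear_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("reported R^2 equals the squared Pearson correlation", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    fit <- linear_regression(x, y)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("slope p-value is calibrated under the null", {
  set.seed(13)
  p <- vapply(1:400, function(i)
    linear_regression(rnorm(50), rnorm(50))$p_value, 0)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("mann_whitney matches the printed exact cases", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_identical(mw$method, "exact")
  # identical samples: maximal overlap, p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact p equals full enumeration on random tie-free samples", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1 + n2)   # distinct values, no ties
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    mw <- mann_whitney(a, b)
    orc <- oracle_mw_exact(a, b)
    expect_equal(mw$U, orc$U)
    expect_equal(mw$p_value, orc$p_value, tolerance = 1e-12)
  }
})

test_that("mann_whitney detects a 2-SD shift most of the time", {
  set.seed(5)
  rej <- mean(vapply(1:300, function(i)
    mann_whitney(rnorm(10), rnorm(10) + 2)$p_value < 0.05, TRUE))
  expect_gt(rej, 0.75)
})

test_that("slope homogeneity test has calibrated size and detects 3-SD slope gaps", {
  set.seed(17)
  type1 <- vapply(1:300, function(i) {
    g <- rep(c("a", "b"), each = 50)
    x <- rnorm(100)
    y <- 1 + 0.5 * x + rnorm(100)   # identical slopes
    d <- data.frame(y = y, g = g, x = x)
    !check_slope_homogeneity(d, "y", "g", "x")$homogeneous
  }, TRUE)
  expect_gt(mean(type1), 0.02)
  expect_lt(mean(type1), 0.09)

  power <- vapply(1:100, function(i) {
    g <- rep(c("a", "b"), each = 100)
    x <- rnorm(200)
    y <- 1 + ifelse(g == "a", 0, 3) * x + rnorm(200)  # slopes differ by 3 SD
    d <- data.frame(y = y, g = g, x = x)
    !check_slope_homogeneity(d, "y", "g", "x")$homogeneous
  }, TRUE)
  expect_gt(mean(power), 0.9)
})

test_that("a constant covariate raises a rank-deficiency error", {
  d <- data.frame(y = rnorm(20), g = rep(c("a", "b"), 10), x = 1)
  expect_error(check_slope_homogeneity(d, "y", "g", "x"), "rank-deficient")
  expect_error(ancova(d, "y", "g", "x", check_slopes = FALSE),
               "rank-deficient")
})

test_that("ancova matches the normal-equations oracle on a hand-built dataset", {
  d <- data.frame(
    y = c(12.1, 14.3, 9.8, 11.0, 13.5, 10.2, 17.9, 16.4, 19.1, 15.2, 18.0, 20.3),
    g = rep(c("a", "b"), each = 6),
    x = c(3.2, 4.1, 2.5, 2.9, 3.8, 2.7, 4.4, 3.9, 5.1, 3.6, 4.7, 5.3))
  res <- ancova(d, "y", "g", "x", check_slopes = FALSE)
  orc <- oracle_ancova(d$y, d$g, list(x = d$x))
  expect_equal(unname(coef(res$model)), unname(orc$beta[c(1, 2, 3)]),
               tolerance = 1e-8)
  expect_equal(res$F_stat, orc$F_stat, tolerance = 1e-8)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-8)
  expect_equal(res$adjusted_means$adjusted_mean, unname(orc$adjusted_means),
               tolerance = 1e-8)
  expect_equal(res$adjusted_means$se, unname(orc$adjusted_se),
               tolerance = 1e-8)
  expect_equal(res$df, c(1, 9))
})

test_that("ancova without covariates reduces exactly to one-way ANOVA", {
  set.seed(3)
  d <- data.frame(y = rnorm(24), g = rep(c("a", "b"), each = 12))
  res <- ancova(d, "y", "g", check_slopes = FALSE)
  aov_tab <- anova(lm(y ~ g, d))
  expect_equal(res$F_stat, aov_tab$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, aov_tab$`Pr(>F)`[1], tolerance = 1e-12)
  # adjusted means collapse to raw group means
  expect_equal(res$adjusted_means$adjusted_mean,
               as.numeric(tapply(d$y, d$g, mean)), tolerance = 1e-12)
})

test_that("adjusted means agree with emmeans under proportional weighting", {
  skip_if_not_installed("emmeans")
  set.seed(23)
  d <- data.frame(y = rnorm(40, 10), g = rep(c("a", "b"), each = 20),
                  x = rnorm(40, 5), s = sample(c("f", "m"), 40, TRUE))
  res <- ancova(d, "y", "g", c("x", "s"), check_slopes = FALSE)
  fit <- lm(y ~ g + x + s, data = transform(d, s = factor(s)))
  em <- as.data.frame(emmeans::emmeans(fit, "g", weights = "proportional"))
  expect_equal(res$adjusted_means$adjusted_mean, em$emmean, tolerance = 1e-8)
  expect_equal(res$adjusted_means$se, em$SE, tolerance = 1e-8)
})

test_that("adjusted means are invariant to affine covariate rescaling", {
  set.seed(29)
  d <- data.frame(y = rnorm(30, 50, 10), g = rep(c("a", "b"), 15),
                  x = rnorm(30, 500, 100))
  r1 <- ancova(d, "y", "g", "x", check_slopes = FALSE)
  d2 <- transform(d, x = (x - 480) / 37)
  r2 <- ancova(d2, "y", "g", "x", check_slopes = FALSE)
  expect_equal(r1$adjusted_means$adjusted_mean,
               r2$adjusted_means$adjusted_mean, tolerance = 1e-9)
  expect_equal(r1$F_stat, r2$F_stat, tolerance = 1e-9)
})

test_that("listwise deletion drives n_used and the denominator df", {
  set.seed(41)
  d <- data.frame(y = rnorm(20), g = rep(c("a", "b"), each = 10),
                  x = c(rnorm(16), rep(NA, 4)))
  res <- ancova(d, "y", "g", "x", check_slopes = FALSE)
  expect_equal(sum(res$n_used), 16)
  expect_equal(res$df[2], 16 - 3)
})

test_that("run_study_analysis executes the full plan on a synthetic cohort", {
  coh <- simulate_cohort(simulation_config(), seed = 19)
  rep <- run_study_analysis(coh)
  expect_s3_class(rep, "study_report")
  expect_named(rep$ancovas, c("stiffness", "yield", "ultimate"))
  for (a in rep$ancovas) {
    expect_equal(a$df[1], 1)
    expect_equal(a$df[2], sum(a$n_used) - 7)  # 2 group + 5 covariate params
    expect_true(all(is.finite(a$adjusted_means$se)))
  }
  expect_equal(nrow(rep$regressions), 18)   # 3 predictors x 6 outcome-states
  expect_gt(rep$yield_vs_ultimate$intact_pooled$r_squared, 0.5)
  expect_false(is.null(rep$failure_subgroup))
  expect_output(print(rep), "ANCOVA")
})

test_that("a cohort with vBMD never measured still gets analysed", {
  coh <- simulate_cohort(simulation_config(), seed = 19)
  tb <- tibble::as_tibble(coh)
  tb$vbmd <- NA_real_
  coh2 <- cohort_table(tb, provenance = "synthetic")
  expect_message(rep <- run_study_analysis(coh2), "vbmd")
  expect_false("vbmd" %in% names(coef(rep$ancovas$stiffness$model)))
  expect_gt(sum(rep$ancovas$stiffness$n_used), 0)
})
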