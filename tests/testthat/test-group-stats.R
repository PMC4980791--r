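test_that("group tests report per-group summaries and match base R", {
  set.seed(71)
  d <- data.frame(y = c(rnorm(30), rnorm(25, 1), rnorm(20, 2)),
                  g = rep(c("a", "b", "c"), c(30, 25, 20)))
  gt <- group_test(d, "y", "g", method = "anova")
  expect_identical(sum(gt$summary$n), nrow(d))
  expect_equal(gt$summary$mean, as.numeric(tapply(d$y, d$g, mean)))
  # two-group ANOVA equals the squared pooled t statistic
  d2 <- d[d$g != "c", ]
  gt2 <- group_test(d2, "y", "g")
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(gt2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(gt2$p_value, tt$p.value, tolerance = 1e-12)
  # permuting input order changes nothing
  perm <- d[sample(nrow(d)), ]
  expect_equal(group_test(perm, "y", "g")$statistic, gt$statistic)
  # Kruskal-Wallis agrees with stats::kruskal.test, including ties
  d$y[1:10] <- round(d$y[1:10])
  gk <- group_test(d, "y", "g", method = "kruskal")
  kw <- kruskal.test(d$y, factor(d$g))
  expect_equal(gk$statistic, unname(kw$statistic))
  expect_equal(gk$p_value, kw$p.value)
  expect_error(group_test(d[d$g == "a", ], "y", "g"), "2 groups")
})

test_that("strongly separated groups are detected decisively", {
  set.seed(72)
  d <- data.frame(y = c(rnorm(50, 0), rnorm(50, 10)),
                  g = rep(c("a", "b"), each = 50))
  expect_lt(group_test(d, "y", "g")$p_value, 1e-6)
  expect_lt(group_test(d, "y", "g", method = "kruskal")$p_value, 1e-6)
})

test_that("Stouffer combination matches its closed forms", {
  expect_equal(stouffer_meta(1.96)$z, 1.96)
  z <- 0.83
  expect_equal(stouffer_meta(c(z, z))$z, z * sqrt(2), tolerance = 1e-12)
  m <- stouffer_meta(rep(1.2816, 3))
  expect_equal(m$z, 1.2816 * sqrt(3), tolerance = 1e-12)
  expect_equal(m$p_value, 2 * pnorm(-1.2816 * sqrt(3)), tolerance = 1e-12)
  # weighted form
  mw <- stouffer_meta(c(1, 2), weights = c(1, 3))
  expect_equal(mw$z, (1 + 6) / sqrt(10), tolerance = 1e-12)
  # sqrt(n) default weights
  mn <- stouffer_meta(c(1, 2), n = c(100, 400))
  expect_equal(mn$z, (10 * 1 + 20 * 2) / sqrt(100 + 400), tolerance = 1e-12)
  # monotone in study count for equal inputs
  zs <- vapply(1:5, function(k) stouffer_meta(rep(1, k))$z, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(stouffer_meta(numeric()), "study")
})

test_that("fixed-effects pooling matches closed forms and metafor", {
  m1 <- fixed_effects_meta(2.5, 0.7)
  expect_equal(m1$estimate, 2.5)
  expect_equal(m1$se, 0.7)
  mk <- fixed_effects_meta(rep(1.3, 4), rep(0.5, 4))
  expect_equal(mk$estimate, 1.3, tolerance = 1e-12)
  expect_equal(mk$se, 0.5 / 2, tolerance = 1e-12)
  m2 <- fixed_effects_meta(c(1, 3), c(1, 1))
  expect_equal(m2$estimate, 2, tolerance = 1e-12)
  expect_equal(m2$se, 1 / sqrt(2), tolerance = 1e-12)
  # pooled estimate lies inside the study range
  set.seed(74)
  d <- rnorm(6); se <- runif(6, 0.2, 2)
  mr <- fixed_effects_meta(d, se)
  expect_gte(mr$estimate, min(d))
  expect_lte(mr$estimate, max(d))
  expect_true(mr$ci_low <= mr$estimate && mr$estimate <= mr$ci_high)
  or <- metafor::rma(yi = d, sei = se, method = "FE")
  expect_equal(mr$estimate, as.numeric(or$beta), tolerance = 1e-10)
  expect_equal(mr$se, or$se, tolerance = 1e-10)
  expect_equal(mr$p_value, or$pval, tolerance = 1e-10)
})

test_that("covariate models recover known effects and drop degenerate columns", {
  set.seed(75)
  n <- 500
  x <- rnorm(n)
  sexf <- factor(rep(c("female", "male"), length.out = n))
  y <- 2 * x + 0.5 * (sexf == "male") + rnorm(n, 0, 0.1)
  fit <- fit_accel_covariate_model(y, data.frame(x = x, sex = sexf))
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_gt(est, 1.95); expect_lt(est, 2.05)
  expect_identical(unname(fit$reference_levels["sex"]), "female")
  # an all-zero covariate changes nothing for the others
  fit2 <- suppressWarnings(
    fit_accel_covariate_model(y, data.frame(x = x, sex = sexf, zero = 0)))
  expect_equal(fit2$coefficients$estimate[fit2$coefficients$term == "x"],
               est)
  expect_warning(
    fit_accel_covariate_model(y, data.frame(x = x, zero = 0)), "constant")
})

test_that("group tests and covariate models hold their nominal type-I error", {
  alpha_hits <- function(pvals) mean(pvals < 0.05)
  p_anova <- vapply(1:1000, function(s) {
    with_seed(s, {
      d <- data.frame(y = rnorm(60), g = rep(c("a", "b"), 30))
      group_test(d, "y", "g")$p_value
    })
  }, numeric(1))
  expect_gte(alpha_hits(p_anova), 0.03)
  expect_lte(alpha_hits(p_anova), 0.07)
  p_kw <- vapply(1:1000, function(s) {
    with_seed(2000 + s, {
      d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), 20))
      group_test(d, "y", "g", method = "kruskal")$p_value
    })
  }, numeric(1))
  expect_gte(alpha_hits(p_kw), 0.03)
  expect_lte(alpha_hits(p_kw), 0.07)
  p_cov <- vapply(1:1000, function(s) {
    with_seed(4000 + s, {
      y <- rnorm(80)
      cov <- data.frame(x = rnorm(80), z = rnorm(80))
      tab <- fit_accel_covariate_model(y, cov)$coefficients
      tab$p_value[tab$term == "x"]
    })
  }, numeric(1))
  expect_gte(alpha_hits(p_cov), 0.03)
  expect_lte(alpha_hits(p_cov), 0.07)
})

test_that("logistic outcome models recover log-odds and respect symmetry", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x))
  fit <- fit_outcome_model(y, x)
  est <- fit$coefficients$estimate[fit$coefficients$term == "accel"]
  expect_gt(est, 0.4); expect_lt(est, 0.6)
  # flipping the outcome negates every coefficient
  flip <- fit_outcome_model(1 - y, x)
  expect_equal(flip$coefficients$estimate, -fit$coefficients$estimate,
               tolerance = 1e-6)
  # Wald z = estimate / SE
  expect_equal(fit$coefficients$statistic,
               fit$coefficients$estimate / fit$coefficients$std_error)
  # null simulations center on zero
  est0 <- vapply(1:200, function(s) {
    with_seed(6000 + s, {
      x0 <- rnorm(300)
      y0 <- rbinom(300, 1, 0.4)
      f <- fit_outcome_model(y0, x0)
      f$coefficients$estimate[f$coefficients$term == "accel"]
    })
  }, numeric(1))
  expect_lt(abs(mean(est0)), 0.05)
  # complete separation is an error, single-class outcomes too
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_outcome_model(ys, xs), "separation")
  expect_error(fit_outcome_model(rep(1, 30), rnorm(30)), "classes")
})

test_that("contrast direction follows the stated group order", {
  set.seed(79)
  d <- data.frame(y = c(rnorm(40, 2), rnorm(40, 0)),
                  g = rep(c("hi", "lo"), each = 40))
  cz <- contrast_z(d, "y", "g", "hi", "lo")
  expect_gt(cz$z, 0)
  cz_flip <- contrast_z(d, "y", "g", "lo", "hi")
  expect_equal(cz_flip$z, -cz$z)
})
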