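test_that("IEAA residuals are orthogonal to age and every cell covariate", {
  set.seed(21)
  n <- 200
  age <- runif(n, 40, 90)
  cells <- data.frame(naiveCD8T = rnorm(n, 0.05, 0.01),
                      exhCD8T = rnorm(n, 2, 0.5),
                      plasmablast = rnorm(n, 0.01, 0.002),
                      CD4T = rnorm(n, 0.15, 0.03),
                      NK = rnorm(n, 0.05, 0.01),
                      mono = rnorm(n, 0.08, 0.02),
                      gran = rnorm(n, 0.55, 0.05))
  dnam <- age + 2 * cells$exhCD8T + rnorm(n, 0, 3)
  fit <- compute_ieaa(dnam, age, cells)
  expect_equal(mean(fit$ieaa), 0, tolerance = 1e-9)
  expect_lt(abs(cor(fit$ieaa, age)), 1e-8)
  for (nm in names(cells)) expect_lt(abs(cor(fit$ieaa, cells[[nm]])), 1e-8)
  # exact linear combinations leave no residual
  exact <- 10 + 0.9 * age + 3 * cells$gran
  expect_equal(compute_ieaa(exact, age, cells)$ieaa, rep(0, n),
               tolerance = 1e-8)
  # intercept absorbs constant shifts
  expect_equal(compute_ieaa(dnam + 11, age, cells)$ieaa, fit$ieaa)
  # constant covariates are dropped with a warning
  cells2 <- cells
  cells2$flat <- 1
  expect_warning(compute_ieaa(dnam, age, cells2), "constant")
})

test_that("Klemera-Doubal calibration estimates per-marker slope, intercept and residual SD", {
  set.seed(33)
  n <- 500
  age <- runif(n, 30, 90)
  markers <- data.frame(m1 = 2 * age + 5 + rnorm(n, 0, 1),
                        m2 = -0.5 * age + 40 + rnorm(n, 0, 4))
  kd <- fit_kd_model(markers, age)
  expect_equal(kd$k[kd$marker == "m1"], 2, tolerance = 0.1)
  expect_equal(kd$q[kd$marker == "m1"], 5, tolerance = 2)
  expect_equal(kd$s[kd$marker == "m1"], 1, tolerance = 0.15)
  expect_equal(kd$k[kd$marker == "m2"], -0.5, tolerance = 0.05)
  # residual SD uses the n - 2 denominator
  fit <- lm(markers$m1 ~ age)
  expect_equal(kd$s[kd$marker == "m1"],
               sqrt(sum(residuals(fit)^2) / (n - 2)))
  # refitting the same data gives identical parameters
  expect_identical(fit_kd_model(markers, age), kd)
  expect_error(fit_kd_model(data.frame(m = rep(1, n)), age), "constant")
})

test_that("age-uninformative markers are screened out", {
  dropped <- vapply(1:20, function(s) {
    with_seed(400 + s, {
      n <- 200
      age <- runif(n, 30, 90)
      markers <- data.frame(good = age + rnorm(n, 0, 2),
                            null = rnorm(n))
      kd <- suppressWarnings(fit_kd_model(markers, age))
      !("null" %in% kd$marker)
    })
  }, logical(1))
  expect_gte(sum(dropped), 18)
})

test_that("KD composite age reduces to closed forms", {
  # single marker with k = 1, q = 0: BA = x
  kd1 <- structure(tibble::tibble(marker = "m", k = 1, q = 0, s = 2),
                   class = c("kd_model", "tbl_df", "tbl", "data.frame"))
  expect_equal(kd_composite_age(kd1, data.frame(m = c(50, 61.5))),
               c(50, 61.5))
  # equal k and s: BA is the mean of per-marker inverse estimates
  kd2 <- structure(tibble::tibble(marker = c("a", "b"), k = c(2, 2),
                                  q = c(1, 3), s = c(1.5, 1.5)),
                   class = c("kd_model", "tbl_df", "tbl", "data.frame"))
  mk <- data.frame(a = c(11, 21), b = c(13, 23))
  expect_equal(kd_composite_age(kd2, mk),
               ((mk$a - 1) / 2 + (mk$b - 3) / 2) / 2)
  expect_error(kd_composite_age(kd2, data.frame(a = 1)), "missing marker")
})

test_that("a noiseless linear marker panel gives back age exactly", {
  age <- seq(35, 85, length.out = 60)
  markers <- data.frame(m1 = 1.2 * age + 3, m2 = -0.4 * age + 50,
                        m3 = 0.05 * age)
  kd <- fit_kd_model(markers, age)
  expect_gt(min(kd$s), 0)  # floored, not zero
  expect_equal(kd_composite_age(kd, markers), age, tolerance = 1e-9)
})

test_that("EEAA is the mean-zero age-orthogonal residual of the composite", {
  set.seed(61)
  n <- 300
  age <- runif(n, 40, 90)
  ba <- 0.9 * age + rnorm(n, 0, 4)
  fit <- compute_eeaa(ba, age)
  expect_equal(mean(fit$eeaa), 0, tolerance = 1e-9)
  expect_lt(abs(cor(fit$eeaa, age)), 1e-8)
  expect_equal(sum(fit$eeaa), 0, tolerance = 1e-9)
  # an exactly linear composite leaves nothing
  expect_equal(compute_eeaa(2 * age + 1, age)$eeaa, rep(0, n),
               tolerance = 1e-9)
})

test_that("full acceleration result satisfies the definitional invariants", {
  res <- run_pipeline(two_group_config("intrinsic", n_per_group = 150,
                                       seed = 3))
  s <- res$samples
  expect_equal(mean(s$age_accel[s$group == res$reference_group &
                                  s$dataset == "dataset1"]), 0,
               tolerance = 1e-6)
  for (d in unique(s$dataset)) {
    sd_ <- s[s$dataset == d, ]
    expect_lt(abs(cor(sd_$ieaa, sd_$age)), 1e-6)
    expect_lt(abs(cor(sd_$eeaa, sd_$age)), 1e-6)
    expect_equal(sum(sd_$ieaa), 0, tolerance = 1e-9 * nrow(sd_))
    expect_equal(sum(sd_$eeaa), 0, tolerance = 1e-9 * nrow(sd_))
    for (cv in c("naiveCD8T_score", "exhCD8T_score", "plasmablast_score",
                 "CD4T", "NK", "mono", "gran")) {
      expect_lt(abs(cor(sd_$ieaa, sd_[[cv]])), 1e-6)
    }
  }
  # tidy/glance surfaces
  g <- glance(res$accel$dataset1)
  expect_lt(abs(g$cor_ieaa_age), 1e-6)
  expect_s3_class(tidy(res$accel$dataset1), "tbl_df")
  expect_s3_class(tidy(res$accel$dataset1$kd_model), "tbl_df")
})
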