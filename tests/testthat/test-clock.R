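test_that("age transform is continuous, monotone, and exactly invertible", {
  A <- 20
  expect_equal(transform_age(A, A), 0)
  expect_equal(transform_age(41, A), 1)  # (41 - 20) / 21
  ages <- c(0, 1, 19, 20, 21, 80)
  expect_equal(inverse_transform_age(transform_age(ages, A), A), ages,
               tolerance = 1e-12)
  grid <- seq(-0.99, 120, by = 0.37)
  f <- transform_age(grid, A)
  expect_true(all(diff(f) > 0))
  # continuity at the adult age
  eps <- 1e-9
  expect_equal(transform_age(A - eps, A), transform_age(A + eps, A),
               tolerance = 1e-6)
  expect_error(transform_age(-1.5), "age")
  # a different adult-age constant round-trips too
  expect_equal(inverse_transform_age(transform_age(ages, 35), 35), ages)
})

test_that("the clock recovers age almost perfectly on a noiseless cohort", {
  sp <- split_cohort(n_train = 300, n_test = 100, seed = 5,
                     measurement_sd = 0, intrinsic_sd_years = 0)
  model <- train_clock(sp$train_beta, sp$train_age, seed = 1)
  pred <- predict_dnam_age(model, sp$test_beta)
  expect_gte(cor(pred, sp$test_age), 0.99)
})

test_that("held-out accuracy at default noise stays high", {
  sp <- split_cohort(n_train = 300, n_test = 100, seed = 6)
  model <- train_clock(sp$train_beta, sp$train_age, seed = 1)
  pred <- predict_dnam_age(model, sp$test_beta)
  expect_gte(cor(pred, sp$test_age), 0.9)
})

test_that("training is deterministic and zero-variance probes get zero weight", {
  sp <- split_cohort(n_train = 120, n_test = 10, seed = 8)
  beta <- sp$train_beta
  beta["cg000001", ] <- 0.42  # constant probe
  m1 <- train_clock(beta, sp$train_age, seed = 4)
  m2 <- train_clock(beta, sp$train_age, seed = 4)
  expect_identical(m1$coef, m2$coef)
  expect_false("cg000001" %in% names(m1$coef))
  # degenerate inputs are rejected
  expect_error(train_clock(beta[, 1:10], sp$train_age[1:10]), "50")
  expect_error(train_clock(beta, rep(50, ncol(beta))), "constant")
})

test_that("prediction is a deterministic linear read-out of the model probes", {
  sp <- split_cohort(n_train = 120, n_test = 40, seed = 9)
  model <- train_clock(sp$train_beta, sp$train_age, seed = 1)
  # all probes at their training means -> one constant prediction
  const <- matrix(model$training_means,
                  nrow = length(model$training_means), ncol = 3,
                  dimnames = list(names(model$training_means),
                                  paste0("s", 1:3)))
  pred <- predict_dnam_age(model, const)
  manual <- inverse_transform_age(
    model$intercept + sum(model$coef *
                            model$training_means[names(model$coef)]),
    model$adult_age)
  expect_equal(unname(pred), rep(manual, 3))
  # removing probes the model does not use leaves predictions unchanged
  unused <- setdiff(rownames(sp$test_beta), names(model$coef))
  expect_equal(predict_dnam_age(model, sp$test_beta),
               predict_dnam_age(model,
                                drop_probes(sp$test_beta, unused[1:20])))
  # missing model probes are an error until imputed
  expect_error(
    predict_dnam_age(model, drop_probes(sp$test_beta,
                                        names(model$coef)[1])),
    "impute")
})

test_that("universal age acceleration is a reference-anchored spline residual", {
  co <- simulate_cohort(sim_config(
    n_samples = 400, seed = 12,
    groups = list(sim_group("ref", 0.6),
                  sim_group("other", 0.4, intrinsic_offset = 4))))
  d <- co$samples
  d$dnam_age <- co$truth$samples$true_intrinsic_age
  fit <- universal_age_accel(d, "ref")
  acc <- fit$data$age_accel
  expect_equal(mean(acc[d$group == "ref"]), 0, tolerance = 1e-6)
  # residual linearity: +5 years on one non-reference sample raises only
  # its own acceleration by exactly 5
  i <- which(d$group == "other")[1]
  d2 <- d
  d2$dnam_age[i] <- d2$dnam_age[i] + 5
  fit2 <- universal_age_accel(d2, "ref")
  expect_equal(fit2$data$age_accel[i], fit$data$age_accel[i] + 5)
  expect_equal(fit2$data$age_accel[-i], fit$data$age_accel[-i])
  # samples exactly on the fitted line have zero acceleration
  d3 <- d
  d3$dnam_age <- unname(predict(fit$fit, newdata = d))
  fit3 <- universal_age_accel(d3, "ref")
  expect_equal(fit3$data$age_accel, rep(0, nrow(d)), tolerance = 1e-9)
  expect_error(universal_age_accel(d, "nonexistent"), "absent")
})

test_that("a constant shift of all DNAm ages moves the spline, not the residuals", {
  co <- simulate_cohort(sim_config(
    n_samples = 300, seed = 13,
    groups = list(sim_group("ref", 0.5), sim_group("other", 0.5))))
  d <- co$samples
  d$dnam_age <- co$truth$samples$true_intrinsic_age + rnorm(300, 0, 2)
  base <- universal_age_accel(d, "ref")$data$age_accel
  d$dnam_age <- d$dnam_age + 7
  shifted <- universal_age_accel(d, "ref")$data$age_accel
  expect_equal(shifted, base, tolerance = 1e-8)
})

test_that("small reference groups fall back to a linear fit", {
  d <- tibble::tibble(
    sample_id = paste0("s", 1:60),
    age = seq(40, 80, length.out = 60),
    dnam_age = seq(40, 80, length.out = 60) + rnorm(60),
    group = rep(c("ref", "other"), c(20, 40)))
  fit <- universal_age_accel(d, "ref")
  expect_false(fit$spline)
  expect_equal(mean(fit$data$age_accel[d$group == "ref"]), 0,
               tolerance = 1e-9)
})
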