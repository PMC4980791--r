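test_that("noise-free cohort equals the pure composition mixture", {
  cfg <- sim_config(n_samples = 30, measurement_sd = 0,
                    intrinsic_sd_years = 0, sex_effect_years = 0, seed = 3)
  co <- simulate_cohort(cfg)
  tr <- co$truth$samples
  probes <- co$truth$probes
  ref <- make_reference_matrix(co)
  W <- as.matrix(tr[, paste0("w_", cfg$cell_types)])
  # signature probes: observed beta must be exactly R %*% w
  sig <- probes$probe_id[probes$class == "signature"]
  expect_equal(co$beta[sig, ], ref %*% t(W), ignore_attr = TRUE,
               tolerance = 1e-12)
  # clock probes: exactly alpha + slope * F(true intrinsic age), clamped
  cl <- probes[probes$class == "clock", ]
  expected <- pmin(pmax(cl$alpha + outer(cl$slope,
    transform_age(tr$true_intrinsic_age, cfg$adult_age)), 0), 1)
  expect_equal(unname(co$beta[cl$probe_id, ]), unname(expected),
               tolerance = 1e-12)
  # with all offsets zero, intrinsic age equals chronological age
  expect_equal(tr$true_intrinsic_age, co$samples$age)
})

test_that("simulation is bit-identical for a fixed seed and master-seed substreams are stable", {
  cfg <- sim_config(n_samples = 40, seed = 17)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  co1 <- simulate_cohort(sim_config(n_samples = 40, seed = 17))
  co2 <- simulate_cohort(sim_config(n_samples = 40, seed = 18))
  expect_false(identical(co1$beta, co2$beta))
})

test_that("cell proportions lie on the simplex and follow configured age trajectories", {
  cfg <- sim_config(n_samples = 500, seed = 11,
                    age_slopes = c(naiveCD8T = -0.03, exhCD8T = 0.05,
                                   CD4T = 0, NK = 0, B = 0, plasmablast = 0,
                                   mono = 0, gran = 0))
  co <- simulate_cohort(cfg)
  W <- as.matrix(co$truth$samples[, paste0("w_", cfg$cell_types)])
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
  expect_lt(cor(co$samples$age, W[, "w_naiveCD8T"]), -0.5)
  expect_gt(cor(co$samples$age, W[, "w_exhCD8T"]), 0.4)
})

test_that("higher Dirichlet concentration tightens composition around its age trend", {
  sds <- vapply(c(150, 15000), function(kappa) {
    co <- simulate_cohort(sim_config(n_samples = 400, seed = 5,
                                     dirichlet_concentration = kappa))
    w <- co$truth$samples$w_gran
    sd(residuals(lm(w ~ co$samples$age)))
  }, numeric(1))
  expect_lt(sds[2], sds[1] / 3)
})

test_that("group intrinsic offsets shift true intrinsic age; zero offsets leave groups exchangeable", {
  cfg <- sim_config(
    n_samples = 600, sex_effect_years = 0, seed = 23,
    groups = list(sim_group("a", 0.5),
                  sim_group("b", 0.5, intrinsic_offset = 5)))
  co <- simulate_cohort(cfg)
  tr <- co$truth$samples
  dev <- tr$true_intrinsic_age - co$samples$age
  d <- mean(dev[co$samples$group == "b"]) - mean(dev[co$samples$group == "a"])
  expect_equal(d, 5, tolerance = 0.8)

  cfg0 <- sim_config(n_samples = 600, sex_effect_years = 0, seed = 23,
                     groups = list(sim_group("a", 0.5), sim_group("b", 0.5)))
  co0 <- simulate_cohort(cfg0)
  dev0 <- co0$truth$samples$true_intrinsic_age - co0$samples$age
  p <- t.test(dev0[co0$samples$group == "a"],
              dev0[co0$samples$group == "b"])$p.value
  expect_gt(p, 0.01)
})

test_that("reference matrix reads out the pure signature levels with the configured separation", {
  co <- small_cohort()
  ref <- make_reference_matrix(co)
  probes <- co$truth$probes
  sig <- probes[probes$class == "signature", ]
  expect_identical(rownames(ref), sig$probe_id)
  for (i in c(1, 17, nrow(sig))) {
    expect_equal(ref[i, sig$on_cell[i]], sig$on_level[i])
    off <- setdiff(colnames(ref), sig$on_cell[i])
    expect_true(all(ref[i, off] == sig$off_level[i]))
    expect_gte(sig$on_level[i] - sig$off_level[i], 0.6)
  }
  # any two cell-type columns differ by >= 0.6 in at least one probe
  cols <- colnames(ref)
  for (a in seq_along(cols)) {
    for (b in seq_len(a - 1)) {
      expect_gte(max(abs(ref[, a] - ref[, b])), 0.6)
    }
  }
})

test_that("a pure-cell sample simulated without noise matches its reference column", {
  cfg <- sim_config(n_samples = 30, measurement_sd = 0,
                    intrinsic_sd_years = 0, seed = 9)
  co <- simulate_cohort(cfg)
  ref <- make_reference_matrix(co)
  # construct a pure-NK mixture from the emitted generative parameters
  w <- setNames(rep(0, length(cfg$cell_types)), cfg$cell_types)
  w["NK"] <- 1
  pure <- ref %*% w
  expect_equal(drop(pure), ref[, "NK"], ignore_attr = TRUE)
})

test_that("intensity construction inverts the beta formula exactly", {
  b <- matrix(c(0.5, 0, 0.9, 0.123), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  ip <- betas_to_intensities(b, total_intensity = 1000)
  expect_equal(ip$M["cg1", "s1"], 550)
  expect_equal(ip$U["cg1", "s1"], 450)
  expect_equal(compute_beta(ip), b, tolerance = 1e-15)
  # infeasible beta for the given total intensity
  b_bad <- matrix(0.995, 1, 1, dimnames = list("cg1", "s1"))
  expect_error(betas_to_intensities(b_bad, total_intensity = 1000),
               "infeasible")
})

test_that("beta round trip is exact over a dense grid of feasible values", {
  S <- 2000
  g <- seq(0, S / (S + 100), length.out = 10000)
  b <- matrix(g, nrow = 100, ncol = 100,
              dimnames = list(sprintf("cg%03d", 1:100),
                              sprintf("s%03d", 1:100)))
  back <- compute_beta(betas_to_intensities(b, S))
  expect_lt(max(abs(back - b)), 1e-12)
})
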