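# Shared fixtures: small cohorts built in code, cached per test run.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_samples = 80, seed = 101))
    }
    cache
  }
})

# Training + held-out cohort pair on one probe universe.
split_cohort <- function(n_train = 300, n_test = 100, seed = 7, ...) {
  cfg <- sim_config(n_samples = n_train + n_test, seed = seed, ...)
  co <- simulate_cohort(cfg)
  idx <- seq_len(n_train)
  list(cohort = co,
       train_beta = co$beta[, idx, drop = FALSE],
       train_age = co$samples$age[idx],
       test_beta = co$beta[, -idx, drop = FALSE],
       test_age = co$samples$age[-idx],
       test_truth = co$truth$samples[-idx, ])
}

two_group_config <- function(scenario = c("intrinsic", "extrinsic"),
                             n_per_group = 300, seed = 1) {
  scenario <- match.arg(scenario)
  groups <- if (scenario == "intrinsic") {
    list(sim_group("control", 0.5),
         sim_group("case", 0.5, intrinsic_offset = 3))
  } else {
    list(sim_group("control", 0.5),
         sim_group("case", 0.5, extrinsic_shift = c(naiveCD8T = -0.5)))
  }
  pipeline_config(mode = "simulate",
                  sim = sim_config(n_samples = 2 * n_per_group,
                                   groups = groups),
                  seed = seed)
}

group_diff <- function(samples, col, g1 = "case", g2 = "control") {
  mean(samples[[col]][samples$group == g1]) -
    mean(samples[[col]][samples$group == g2])
}
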