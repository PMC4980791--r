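#' Configuration for the end-to-end pipeline
#'
#' Bundles everything [run_pipeline()] needs: where data come from
#' (simulated under a [sim_config()] or loaded from TSV files), clock and
#' spline settings, the statistics plan, and the robustness plan.
#'
#' @param mode `"simulate"` (generate a training cohort and analysis
#'   datasets) or `"load"` (read beta matrix, sample sheet, reference matrix
#'   and serialized clocks from `paths`).
#' @param sim A [sim_config()] describing the analysis cohort (simulate
#'   mode).
#' @param n_train Training-cohort size for fitting the clocks and subset
#'   estimators (simulate mode); the training cohort is simulated on the
#'   same probe universe with a single neutral group.
#' @param paths Named list for load mode: `beta`, `samples`, `reference`,
#'   `clock_stem`, `blood_clock_stem` (see [write_clock_model()]).
#' @param adult_age,alpha,nfolds Clock training settings (see
#'   [train_clock()]).
#' @param spline_df Spline degrees of freedom for the universal measure.
#' @param reference_group Reference group label; defaults to the first
#'   configured group.
#' @param normalize Calibrate analysis samples to the primary clock's
#'   gold-standard profile before prediction (default FALSE; mainly useful
#'   when loading external data).
#' @param test_method `"anova"` or `"kruskal"` for the group comparisons.
#' @param contrast Two group labels defining the signed contrast fed into
#'   the meta-analyses; defaults to the first two configured groups.
#' @param blacklist Probe ids (or a file path, one id per line) for the
#'   robustness re-analysis; NULL lets [run_robustness()] draw a random
#'   subset of clock probes.
#' @param blacklist_fraction Fraction of clock probes blacklisted when
#'   `blacklist` is NULL (default 0.13, the share of SNP-adjacent probes the
#'   robustness analysis removes: 47 of 353).
#' @param seed Master seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            sim = sim_config(),
                            n_train = 300,
                            paths = list(),
                            adult_age = 20, alpha = 0.5, nfolds = 10,
                            spline_df = 4,
                            reference_group = NULL,
                            normalize = FALSE,
                            test_method = c("anova", "kruskal"),
                            contrast = NULL,
                            blacklist = NULL,
                            blacklist_fraction = 47 / 353,
                            seed = 1) {
  mode <- match.arg(mode)
  test_method <- match.arg(test_method)
  if (mode == "load") {
    need <- c("beta", "samples", "reference", "clock_stem",
              "blood_clock_stem")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      abort(sprintf("load mode needs paths: %s", paste(miss, collapse = ", ")))
    }
  }
  structure(list(mode = mode, sim = sim, n_train = n_train, paths = paths,
                 adult_age = adult_age, alpha = alpha, nfolds = nfolds,
                 spline_df = spline_df, reference_group = reference_group,
                 normalize = normalize, test_method = test_method,
                 contrast = contrast, blacklist = blacklist,
                 blacklist_fraction = blacklist_fraction, seed = seed),
            class = "pipeline_config")
}

pipeline_stage_seeds <- function(config) {
  stage_seeds(config$seed, c("train_cohort", "analysis_cohort", "clock",
                             "blood_clock", "subsets", "robustness"))
}

#' Run the full epigenetic-aging pipeline
#'
#' Sequences the analysis end to end: obtain data (simulate or load), train
#' or load the clocks and subset estimators, deconvolve cell composition,
#' predict DNAm age, compute the three acceleration measures per dataset,
#' and run the statistics plan (per-dataset group tests, Stouffer
#' combination of the group contrast across datasets, a fixed-effects
#' inverse-variance meta-analysis of the contrast, and a pooled covariate
#' model of each measure on sex and group).  Deterministic given the master
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, all declared files
#'   are written under `data/`, `models/`, `results/` and `report/`, and the
#'   run report records their md5 digests.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `pipeline_result`.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- pipeline_stage_seeds(config)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[epiaccel] ", fmt), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if (config$mode == "simulate") {
    say("simulating training cohort (n = %d)", config$n_train)
    train_cfg <- config$sim
    train_cfg$n_samples <- config$n_train
    train_cfg$groups <- list(sim_group("training", 1))
    train_cfg$n_datasets <- 1
    train_cfg$seed <- seeds[["train_cohort"]]
    train <- stage("simulate_training", simulate_cohort(train_cfg))
    say("simulating analysis cohort (%d dataset(s) x %d samples)",
        config$sim$n_datasets, config$sim$n_samples)
    ana_cfg <- config$sim
    ana_cfg$seed <- seeds[["analysis_cohort"]]
    cohort <- stage("simulate_analysis",
                    simulate_cohort(ana_cfg, probes = train$truth$probes))
    ref <- make_reference_matrix(train)
    probes <- train$truth$probes
    say("training clocks and subset estimators")
    intrinsic_rows <- probes$probe_id[probes$class %in% c("clock", "noise")]
    clock <- stage("train_clock", train_clock(
      train$beta[intrinsic_rows, , drop = FALSE], train$samples$age,
      adult_age = config$adult_age, alpha = config$alpha,
      nfolds = config$nfolds, seed = seeds[["clock"]]))
    blood_clock <- stage("train_blood_clock", train_clock(
      train$beta, train$samples$age,
      adult_age = config$adult_age, alpha = config$alpha,
      nfolds = config$nfolds, seed = seeds[["blood_clock"]]))
    sub_seeds <- with_seed(seeds[["subsets"]],
                           sample.int(.Machine$integer.max - 1L, 3))
    tr_truth <- train$truth$samples
    subset_models <- stage("train_subsets", list(
      naiveCD8T = train_subset_estimator(train$beta, tr_truth$w_naiveCD8T,
                                         alpha = config$alpha,
                                         seed = sub_seeds[1]),
      exhCD8T = train_subset_estimator(train$beta, 100 * tr_truth$w_exhCD8T,
                                       alpha = config$alpha,
                                       seed = sub_seeds[2]),
      plasmablast = train_subset_estimator(train$beta,
                                           tr_truth$w_plasmablast,
                                           alpha = config$alpha,
                                           seed = sub_seeds[3])))
  } else {
    say("loading data from configured paths")
    beta <- stage("load_beta", read_beta_matrix(config$paths$beta))
    samples <- stage("load_samples", read_sample_sheet(config$paths$samples))
    cohort <- structure(list(beta = beta, samples = samples, truth = NULL),
                        class = "epi_cohort")
    ref <- stage("load_reference",
                 read_reference_matrix(config$paths$reference))
    clock <- stage("load_clock", read_clock_model(config$paths$clock_stem))
    blood_clock <- stage("load_blood_clock",
                         read_clock_model(config$paths$blood_clock_stem))
    subset_models <- stage("load_subsets", {
      if (is.null(config$paths$subset_stems)) {
        abort("load mode needs paths$subset_stems (named list)")
      }
      lapply(config$paths$subset_stems, function(s) {
        m <- read_clock_model(s)
        structure(list(coef = m$coef, intercept = m$intercept,
                       alpha = m$alpha, lambda = m$lambda, seed = m$seed,
                       n_train = m$n_train), class = "subset_model")
      })
    })
    train <- NULL
  }

  beta <- cohort$beta
  if (config$normalize) {
    say("calibrating samples to the clock gold standard")
    beta <- stage("normalize",
                  normalize_to_gold_standard(beta, gold_standard(clock)))
  }

  say("deconvolving cell composition")
  counts <- stage("deconvolution", estimate_cell_proportions(beta, ref))
  subsets <- stage("advanced_subsets",
                   estimate_advanced_subsets(subset_models, beta))

  say("predicting DNAm age and computing acceleration per dataset")
  dnam_age <- stage("predict_clock", predict_dnam_age(clock, beta))
  blood_age <- stage("predict_blood_clock",
                     predict_dnam_age(blood_clock, beta))
  groups_present <- unique(cohort$samples$group)
  default_ref <- if (config$mode == "simulate") {
    vapply(config$sim$groups, `[[`, character(1), "label")[1]
  } else {
    groups_present[1]
  }
  ref_group <- config$reference_group %||% default_ref
  if (!ref_group %in% groups_present) {
    abort(sprintf("reference group '%s' absent from the annotation",
                  ref_group))
  }
  datasets <- unique(cohort$samples$dataset)
  accel <- lapply(datasets, function(d) {
    idx <- cohort$samples$dataset == d
    stage(paste0("acceleration_", d), compute_acceleration(
      cohort$samples[idx, ], dnam_age[idx], blood_age[idx],
      counts[idx, ], subsets[idx, ],
      reference_group = ref_group, spline_df = config$spline_df))
  })
  names(accel) <- datasets
  samples_out <- dplyr::bind_rows(lapply(accel, function(a) a$data))
  samples_out <- dplyr::left_join(
    samples_out, dplyr::select(counts, -dplyr::starts_with("prop_")),
    by = "sample_id")
  samples_out <- dplyr::left_join(
    samples_out,
    dplyr::rename_with(subsets, ~ paste0(.x, "_score"),
                       -dplyr::all_of("sample_id")),
    by = "sample_id")

  say("running the statistics plan")
  group_order <- if (config$mode == "simulate") {
    vapply(config$sim$groups, `[[`, character(1), "label")
  } else {
    groups_present
  }
  stats <- stage("stats",
                 pipeline_stats(samples_out, config, datasets, group_order))

  result <- structure(
    list(samples = samples_out, cohort = cohort, train = train,
         reference = ref, clock = clock, blood_clock = blood_clock,
         subset_models = subset_models, counts = counts, subsets = subsets,
         accel = accel, stats = stats, config = config,
         seeds = seeds, reference_group = ref_group),
    class = "pipeline_result")
  if (!is.null(outdir)) {
    result$report <- write_pipeline_outputs(result, outdir)
  }
  result
}

# Group tests per dataset and measure, plus meta-analyses of the configured
# two-group contrast across datasets and a pooled covariate model.
pipeline_stats <- function(samples, config, datasets,
                           groups = unique(samples$group)) {
  measures <- c("age_accel", "ieaa", "eeaa")
  tests <- NULL
  if (length(groups) >= 2) {
    tests <- dplyr::bind_rows(lapply(datasets, function(d) {
      dplyr::bind_rows(lapply(measures, function(m) {
        gt <- group_test(samples[samples$dataset == d, ], m, "group",
                         method = config$test_method)
        tibble(dataset = d, measure = m, method = gt$method,
               statistic = gt$statistic, p_value = gt$p_value)
      }))
    }))
  }
  meta <- list()
  contrast <- config$contrast %||% groups[seq_len(min(2, length(groups)))]
  if (length(groups) >= 2 && length(contrast) == 2) {
    for (m in measures) {
      per_ds <- dplyr::bind_rows(lapply(datasets, function(d) {
        cz <- contrast_z(samples[samples$dataset == d, ], m, "group",
                         contrast[1], contrast[2])
        cz$dataset <- d
        cz
      }))
      meta[[m]] <- list(
        per_dataset = per_ds,
        stouffer = stouffer_meta(per_ds$z, n = per_ds$n),
        fixed_effects = fixed_effects_meta(per_ds$estimate, per_ds$se,
                                           labels = per_ds$dataset))
    }
  }
  covariates <- samples[, intersect(c("sex", "group", "dataset"),
                                    names(samples)), drop = FALSE]
  keep <- vapply(covariates, function(x) length(unique(x)) > 1, logical(1))
  covariate_models <- lapply(setNames(measures, measures), function(m) {
    fit_accel_covariate_model(samples[[m]],
                              covariates[, keep, drop = FALSE])
  })
  list(group_tests = tests, meta = meta, contrast = contrast,
       covariate_models = covariate_models)
}

#' Robustness re-analysis: drop clock probes, impute, recompute
#'
#' Repeats DNAm age prediction and the acceleration measures after removing
#' a blacklist of probes (e.g. SNP-adjacent clock CpGs) and imputing them
#' with the clocks' training means, then reports the Spearman rank
#' correlation between the base and the robust measures per dataset.  High
#' rank correlation means the findings do not hinge on the removed probes.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param blacklist Probe ids to remove; default: the configured blacklist,
#'   or a random `blacklist_fraction` of the primary clock's probes drawn
#'   under the run's robustness substream.
#' @return Object of class `robustness_result`: `correlations` tibble
#'   (dataset, measure, spearman), `blacklist`, and the robust per-sample
#'   tibble.
#' @export
run_robustness <- function(result, blacklist = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  config <- result$config
  blacklist <- blacklist %||% config$blacklist
  if (is.character(blacklist) && length(blacklist) == 1 &&
      file.exists(blacklist)) {
    blacklist <- read_blacklist(blacklist)
  }
  if (is.null(blacklist)) {
    clock_probes <- names(result$clock$coef)
    n_drop <- max(1, round(config$blacklist_fraction * length(clock_probes)))
    blacklist <- with_seed(result$seeds[["robustness"]],
                           sample(clock_probes, n_drop))
  }
  beta <- result$cohort$beta
  if (config$normalize) {
    beta <- normalize_to_gold_standard(beta, gold_standard(result$clock))
  }
  reduced <- suppressWarnings(drop_probes(beta, blacklist))
  if (!any(rownames(reduced) %in% names(result$clock$coef))) {
    abort("blacklist removes every clock probe")
  }
  b1 <- impute_missing_clock_probes(reduced, result$clock)
  b2 <- impute_missing_clock_probes(b1, result$blood_clock)
  dnam_age <- predict_dnam_age(result$clock, b2)
  blood_age <- predict_dnam_age(result$blood_clock, b2)
  # subset estimators and deconvolution reuse the imputed matrix too
  subs_beta <- b2
  for (m in result$subset_models) {
    miss <- setdiff(names(m$coef), rownames(subs_beta))
    if (length(miss)) {
      add <- matrix(0, length(miss), ncol(subs_beta),
                    dimnames = list(miss, colnames(subs_beta)))
      subs_beta <- rbind(subs_beta, add)
    }
  }
  subsets <- estimate_advanced_subsets(result$subset_models, subs_beta)
  counts <- estimate_cell_proportions(subs_beta, result$reference)
  samples <- result$cohort$samples
  datasets <- unique(samples$dataset)
  accel <- lapply(datasets, function(d) {
    idx <- samples$dataset == d
    compute_acceleration(samples[idx, ], dnam_age[idx], blood_age[idx],
                         counts[idx, ], subsets[idx, ],
                         reference_group = result$reference_group,
                         spline_df = config$spline_df)
  })
  robust <- dplyr::bind_rows(lapply(accel, function(a) a$data))
  base <- result$samples
  measures <- c("age_accel", "ieaa", "eeaa")
  correlations <- dplyr::bind_rows(lapply(datasets, function(d) {
    b <- base[base$dataset == d, ]
    r <- robust[robust$dataset == d, ]
    r <- r[match(b$sample_id, r$sample_id), ]
    dplyr::bind_rows(lapply(measures, function(m) {
      tibble(dataset = d, measure = m,
             spearman = cor(b[[m]], r[[m]], method = "spearman"))
    }))
  }))
  structure(list(correlations = correlations, blacklist = blacklist,
                 samples = robust),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> %d probes blacklisted\n",
              length(x$blacklist)))
  print(x$correlations)
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d samples, %d dataset(s), reference group '%s'\n",
    nrow(x$samples), length(x$accel), x$reference_group))
  invisible(x)
}

# Write every declared output file and assemble the run report.
write_pipeline_outputs <- function(result, outdir) {
  dirs <- file.path(outdir, c("data", "models", "results", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  cohort <- result$cohort
  files <- character()
  for (d in unique(cohort$samples$dataset)) {
    idx <- cohort$samples$dataset == d
    f <- file.path(outdir, "data", sprintf("beta_%s.tsv", d))
    write_beta_matrix(cohort$beta[, idx, drop = FALSE], f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "data", "samples.tsv")
  write_sample_sheet(cohort$samples, f); files <- c(files, f)
  if (!is.null(cohort$truth)) {
    f <- file.path(outdir, "data", "truth_samples.tsv")
    write_sample_sheet(cohort$truth$samples, f); files <- c(files, f)
    f <- file.path(outdir, "data", "truth_probes.tsv")
    readr::write_tsv(cohort$truth$probes, f, progress = FALSE)
    files <- c(files, f)
  }
  f <- file.path(outdir, "data", "reference.tsv")
  write_reference_matrix(result$reference, f); files <- c(files, f)
  write_clock_model(result$clock, file.path(outdir, "models", "clock"))
  write_clock_model(result$blood_clock,
                    file.path(outdir, "models", "blood_clock"))
  files <- c(files,
             file.path(outdir, "models",
                       c("clock.tsv", "clock_header.tsv", "blood_clock.tsv",
                         "blood_clock_header.tsv")))
  for (d in names(result$accel)) {
    f <- file.path(outdir, "models", sprintf("kd_%s.tsv", d))
    write_kd_model(result$accel[[d]]$kd_model, f); files <- c(files, f)
  }
  f <- file.path(outdir, "results", "sample_sheet.tsv")
  write_sample_sheet(result$samples, f); files <- c(files, f)
  if (!is.null(result$stats$group_tests)) {
    f <- file.path(outdir, "results", "group_tests.tsv")
    readr::write_tsv(result$stats$group_tests, f, progress = FALSE)
    files <- c(files, f)
  }
  if (length(result$stats$meta)) {
    meta_tbl <- dplyr::bind_rows(lapply(names(result$stats$meta), function(m) {
      mt <- result$stats$meta[[m]]
      tibble(measure = m,
             stouffer_z = mt$stouffer$z, stouffer_p = mt$stouffer$p_value,
             pooled_estimate = mt$fixed_effects$estimate,
             pooled_se = mt$fixed_effects$se,
             pooled_ci_low = mt$fixed_effects$ci_low,
             pooled_ci_high = mt$fixed_effects$ci_high,
             pooled_p = mt$fixed_effects$p_value)
    }))
    f <- file.path(outdir, "results", "meta.tsv")
    readr::write_tsv(meta_tbl, f, progress = FALSE); files <- c(files, f)
  }
  cov_tbl <- dplyr::bind_rows(lapply(names(result$stats$covariate_models),
                                     function(m) {
    tab <- result$stats$covariate_models[[m]]$coefficients
    tab$measure <- m
    tab
  }))
  f <- file.path(outdir, "results", "covariate_models.tsv")
  readr::write_tsv(cov_tbl, f, progress = FALSE); files <- c(files, f)
  report <- list(
    package = "epiaccel",
    seed = result$config$seed,
    stage_seeds = as.list(result$seeds),
    mode = result$config$mode,
    reference_group = result$reference_group,
    n_samples = nrow(result$samples),
    datasets = unique(result$samples$dataset),
    parameters = list(adult_age = result$config$adult_age,
                      alpha = result$config$alpha,
                      nfolds = result$config$nfolds,
                      spline_df = result$config$spline_df,
                      normalize = result$config$normalize,
                      test_method = result$config$test_method),
    files = as.list(setNames(unname(tools::md5sum(files)), files)))
  jsonlite::write_json(report, file.path(outdir, "report", "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [pipeline_config()] and [sim_config()];
#' a `sim:` section holds the simulator settings, with `groups:` as a list
#' of `{label, fraction, intrinsic_offset, extrinsic_shift}` entries.
#'
#' @param path Path to the YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$groups)) {
    sim_args$groups <- lapply(sim_args$groups, function(g) {
      sim_group(g$label, g$fraction,
                intrinsic_offset = g$intrinsic_offset %||% 0,
                extrinsic_shift = unlist(g$extrinsic_shift) %||% NULL)
    })
  }
  for (nm in c("age_range", "base_logits", "age_slopes",
               "probe_slope_range")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  sim <- do.call(sim_config, sim_args)
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- sim
  do.call(pipeline_config, args)
}
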