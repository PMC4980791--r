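#' Default blood cell types used by the simulator and deconvolution
#'
#' Eight leukocyte compartments: naive and exhausted CD8+ T cells, CD4+ T
#' cells, natural killer cells, B cells, plasmablasts, monocytes and
#' granulocytes.  The first two and the plasmablast compartment are the
#' immunosenescence markers whose abundances change with age.
#'
#' @return Character vector of cell-type labels.
#' @export
cell_types_default <- function() {
  c("naiveCD8T", "exhCD8T", "CD4T", "NK", "B", "plasmablast", "mono", "gran")
}

# Baseline composition logits chosen so that, at the mid-age of the default
# cohort (~65 y), mean proportions are roughly gran .55, CD4T .15, mono .08,
# NK .05, B .05, naiveCD8T .05, exhCD8T .02, plasmablast .01 -- a realistic
# adult whole-blood profile.  Logits are shift-invariant under softmax.
default_base_logits <- function() {
  c(naiveCD8T = log(0.05) + 0.04 * 65,
    exhCD8T = log(0.02) - 0.05 * 65,
    CD4T = log(0.15),
    NK = log(0.05),
    B = log(0.05),
    plasmablast = log(0.01) - 0.02 * 65,
    mono = log(0.08),
    gran = log(0.55))
}

# Immunosenescence trajectories: naive CD8+ T cells fall with age (roughly
# 5% of blood at 40 y to ~1% at 80 y, i.e. about -0.04 logit/y), exhausted
# CD8+ T cells expand markedly, plasmablasts rise modestly; other
# compartments held flat.
default_age_slopes <- function() {
  c(naiveCD8T = -0.04, exhCD8T = 0.05, CD4T = 0, NK = 0,
    B = 0, plasmablast = 0.02, mono = 0, gran = 0)
}

#' Define a simulated sample group
#'
#' A group carries an intrinsic epigenetic age offset (years added to the
#' sample's true intrinsic age, shared across cell types) and/or an extrinsic
#' composition shift (added to the cell-type logits).  These two channels are
#' deliberately separate: intrinsic offsets are what IEAA should detect,
#' extrinsic shifts are what EEAA should detect.
#'
#' @param label Group label.
#' @param fraction Fraction of samples assigned to this group.
#' @param intrinsic_offset Years added to the intrinsic epigenetic age.
#' @param extrinsic_shift Named numeric vector of logit shifts per cell type
#'   (missing cell types default to 0).
#' @return A list describing the group, for use in [sim_config()].
#' @export
sim_group <- function(label, fraction, intrinsic_offset = 0,
                      extrinsic_shift = NULL) {
  list(label = label, fraction = fraction,
       intrinsic_offset = intrinsic_offset,
       extrinsic_shift = extrinsic_shift %||% numeric())
}

#' Configuration for the synthetic methylation cohort generator
#'
#' Defines the generative model for a blood-like methylation cohort with
#' known ground truth: per-sample intrinsic epigenetic ages, cell-type
#' compositions following immunosenescence trajectories, group and sex
#' effects, and three probe classes (age-tracking clock probes shared across
#' cell types, cell-type signature probes, and constant noise probes).
#'
#' @param n_samples Samples per dataset.
#' @param age_range Two-element vector, uniform chronological age range in
#'   years.
#' @param groups List of [sim_group()] definitions; fractions must sum to 1.
#' @param sex_effect_years Years added to the intrinsic age of male samples.
#' @param intrinsic_sd_years SD (years) of the sample-level intrinsic age
#'   deviation around chronological age.
#' @param cell_types Ordered cell-type labels.
#' @param base_logits Named baseline composition logits per cell type.
#' @param age_slopes Named logit-per-year composition slopes per cell type.
#' @param dirichlet_concentration Concentration of the per-sample Dirichlet
#'   draw around the mean composition (larger = tighter).
#' @param n_clock_probes,n_signature_probes,n_noise_probes Probe counts per
#'   class.
#' @param probe_slope_range Absolute clock-probe slope range, beta units per
#'   unit of transformed age.
#' @param signature_separation Minimum beta-unit separation between a
#'   signature probe's "on" cell type and all other cell types.
#' @param measurement_sd SD of the additive beta-scale measurement noise.
#' @param adult_age Adult-age constant of the clock age transform (years).
#' @param n_datasets Number of replicate datasets sharing one probe universe.
#' @param seed Master seed; all randomness derives from it via documented
#'   per-stage substreams.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 300,
                       age_range = c(40, 90),
                       groups = list(sim_group("control", 1)),
                       sex_effect_years = 0.8,
                       intrinsic_sd_years = 3,
                       cell_types = cell_types_default(),
                       base_logits = default_base_logits(),
                       age_slopes = default_age_slopes(),
                       dirichlet_concentration = 150,
                       n_clock_probes = 120,
                       n_signature_probes = 80,
                       n_noise_probes = 100,
                       probe_slope_range = c(0.02, 0.12),
                       signature_separation = 0.6,
                       measurement_sd = 0.02,
                       adult_age = 20,
                       n_datasets = 1,
                       seed = 1) {
  cfg <- list(n_samples = n_samples, age_range = age_range, groups = groups,
              sex_effect_years = sex_effect_years,
              intrinsic_sd_years = intrinsic_sd_years,
              cell_types = cell_types,
              base_logits = base_logits[cell_types],
              age_slopes = age_slopes[cell_types],
              dirichlet_concentration = dirichlet_concentration,
              n_clock_probes = n_clock_probes,
              n_signature_probes = n_signature_probes,
              n_noise_probes = n_noise_probes,
              probe_slope_range = probe_slope_range,
              signature_separation = signature_separation,
              measurement_sd = measurement_sd,
              adult_age = adult_age,
              n_datasets = n_datasets, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- vapply(cfg$groups, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) abort("group fractions must sum to 1")
  if (cfg$age_range[1] < 0 || diff(cfg$age_range) < 0) {
    abort("age_range must be non-negative and increasing")
  }
  if (cfg$measurement_sd < 0) abort("measurement_sd must be >= 0")
  if (cfg$dirichlet_concentration <= 0) {
    abort("dirichlet_concentration must be > 0")
  }
  if (cfg$n_clock_probes < 1 || cfg$n_signature_probes < 1) {
    abort("need at least one clock probe and one signature probe")
  }
  if (anyNA(cfg$base_logits) || anyNA(cfg$age_slopes)) {
    abort("base_logits and age_slopes must cover every cell type")
  }
  invisible(cfg)
}

# Draw the probe universe: ids, classes and generative parameters.  Shared
# across datasets of one cohort so that a clock trained on one dataset
# transfers to the others.
draw_probe_universe <- function(cfg, seed) {
  with_seed(seed, {
    n_tot <- cfg$n_clock_probes + cfg$n_signature_probes + cfg$n_noise_probes
    ids <- sprintf("cg%06d", seq_len(n_tot))
    cls <- rep(c("clock", "signature", "noise"),
               c(cfg$n_clock_probes, cfg$n_signature_probes,
                 cfg$n_noise_probes))
    k <- length(cfg$cell_types)
    sl <- runif(cfg$n_clock_probes, cfg$probe_slope_range[1],
                cfg$probe_slope_range[2]) *
      sample(c(-1, 1), cfg$n_clock_probes, replace = TRUE)
    probes <- tibble(
      probe_id = ids, class = cls,
      alpha = NA_real_, slope = NA_real_,
      on_cell = NA_character_, on_level = NA_real_, off_level = NA_real_)
    probes$alpha[cls == "clock"] <- runif(cfg$n_clock_probes, 0.15, 0.85)
    probes$slope[cls == "clock"] <- sl
    # signature probes: one "on" cell type each, assigned round-robin so
    # every compartment gets probes; levels separated by >= the configured
    # margin
    idx_sig <- which(cls == "signature")
    m <- length(idx_sig)
    probes$on_cell[idx_sig] <- cfg$cell_types[(seq_len(m) - 1) %% k + 1]
    off <- runif(m, 0.05, 0.95 - cfg$signature_separation)
    gap <- cfg$signature_separation +
      runif(m) * (0.95 - off - cfg$signature_separation)
    probes$off_level[idx_sig] <- off
    probes$on_level[idx_sig] <- off + gap
    probes$alpha[cls == "noise"] <- runif(cfg$n_noise_probes, 0.05, 0.95)
    probes
  })
}

# Pure (noise-free) cell-type profile matrix for the signature probes.
signature_profile_matrix <- function(probes, cell_types) {
  sig <- probes[probes$class == "signature", ]
  R <- matrix(rep(sig$off_level, length(cell_types)),
              nrow = nrow(sig), ncol = length(cell_types),
              dimnames = list(sig$probe_id, cell_types))
  for (i in seq_len(nrow(sig))) R[i, sig$on_cell[i]] <- sig$on_level[i]
  R
}

#' Simulate a synthetic methylation cohort with known ground truth
#'
#' Generates one or more blood-like 450K-style datasets under a fully
#' specified generative model: chronological ages are uniform on the
#' configured range; each sample's true intrinsic epigenetic age adds its
#' group offset, a sex effect for males, and Gaussian noise; mean cell
#' composition follows softmax trajectories in age (plus any group extrinsic
#' shift) with a Dirichlet draw around it; clock probes move with the
#' transformed intrinsic age identically in every cell type, signature probes
#' are cell-type-specific constants, noise probes are flat; the observed beta
#' value is the composition-weighted mixture plus clamped Gaussian
#' measurement noise.
#'
#' @param config A [sim_config()].
#' @param probes Optional probe-universe table from a previous cohort (as
#'   found in `$truth$probes`), to simulate new samples on an existing probe
#'   universe (e.g. an external training cohort for the clock).
#' @return A list of class `epi_cohort` with elements `beta` (probe-by-sample
#'   matrix), `samples` (tibble: sample_id, dataset, age, sex, group), and
#'   `truth` (list: `samples` tibble with true intrinsic age and cell
#'   proportions in `w_*` columns, `probes` parameter table, `config`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 50, seed = 7))
#' dim(cohort$beta)
#' @export
simulate_cohort <- function(config, probes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seeds <- stage_seeds(config$seed,
                       c("probes", "datasets", "reserved1", "reserved2"))
  if (is.null(probes)) probes <- draw_probe_universe(config, seeds[["probes"]])
  ds_seeds <- with_seed(seeds[["datasets"]],
                        sample.int(.Machine$integer.max - 1L,
                                   config$n_datasets))
  parts <- lapply(seq_len(config$n_datasets), function(d) {
    simulate_dataset(config, probes, dataset = d, seed = ds_seeds[d])
  })
  beta <- do.call(cbind, lapply(parts, `[[`, "beta"))
  samples <- dplyr::bind_rows(lapply(parts, `[[`, "samples"))
  truth_samples <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  structure(
    list(beta = beta, samples = samples,
         truth = list(samples = truth_samples, probes = probes,
                      config = config)),
    class = "epi_cohort")
}

simulate_dataset <- function(cfg, probes, dataset, seed) {
  n <- cfg$n_samples
  k <- length(cfg$cell_types)
  labels <- vapply(cfg$groups, `[[`, character(1), "label")
  fractions <- vapply(cfg$groups, `[[`, numeric(1), "fraction")
  with_seed(seed, {
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("female", "male"), n, replace = TRUE)
    # deterministic proportional allocation, then shuffle
    n_per <- diff(round(cumsum(c(0, fractions)) * n))
    group <- sample(rep(labels, n_per))
    g_idx <- match(group, labels)
    offs <- vapply(cfg$groups, `[[`, numeric(1), "intrinsic_offset")
    e <- age + offs[g_idx] + cfg$sex_effect_years * (sex == "male") +
      rnorm(n, 0, cfg$intrinsic_sd_years)
    e <- pmax(e, 0)
    # composition logits and Dirichlet draw
    shift_mat <- matrix(0, length(labels), k,
                        dimnames = list(labels, cfg$cell_types))
    for (g in seq_along(cfg$groups)) {
      es <- cfg$groups[[g]]$extrinsic_shift
      if (length(es)) shift_mat[g, names(es)] <- es
    }
    W <- matrix(0, n, k, dimnames = list(NULL, cfg$cell_types))
    for (i in seq_len(n)) {
      m <- softmax(cfg$base_logits + cfg$age_slopes * age[i] +
                     shift_mat[g_idx[i], ])
      W[i, ] <- rdirichlet1(cfg$dirichlet_concentration * m)
    }
    # probe-level mixture
    f_e <- transform_age(e, cfg$adult_age)
    is_clock <- probes$class == "clock"
    is_sig <- probes$class == "signature"
    is_noise <- probes$class == "noise"
    mu <- matrix(0, nrow(probes), n,
                 dimnames = list(probes$probe_id, NULL))
    mu[is_clock, ] <- clamp01(probes$alpha[is_clock] +
                                outer(probes$slope[is_clock], f_e))
    R <- signature_profile_matrix(probes, cfg$cell_types)
    mu[is_sig, ] <- R %*% t(W)
    mu[is_noise, ] <- probes$alpha[is_noise]
    beta <- mu
    if (cfg$measurement_sd > 0) {
      beta <- beta + matrix(rnorm(length(mu), 0, cfg$measurement_sd),
                            nrow(mu), n)
    }
    beta <- clamp01(beta)
    ids <- sprintf("d%d_s%04d", dataset, seq_len(n))
    colnames(beta) <- ids
    samples <- tibble(sample_id = ids, dataset = paste0("dataset", dataset),
                      age = age, sex = sex, group = group)
    truth <- dplyr::bind_cols(
      samples[, c("sample_id", "dataset")],
      tibble(true_intrinsic_age = e),
      as_tibble(W, .name_repair = ~ paste0("w_", cfg$cell_types)))
    list(beta = beta, samples = samples, truth = truth)
  })
}

#' Build the pure cell-type reference matrix from simulation truth
#'
#' Extracts the signature-probe-by-cell-type matrix of pure (unmixed,
#' noise-free) beta levels from a simulated cohort's probe parameters -- the
#' methylation analogue of reference profiles measured on purified leukocyte
#' fractions, as consumed by [estimate_cell_proportions()].
#'
#' @param truth The `truth` element of an `epi_cohort` (or a cohort itself).
#' @return Numeric matrix, signature probes by cell types, values in `[0, 1]`.
#' @export
make_reference_matrix <- function(truth) {
  if (inherits(truth, "epi_cohort")) truth <- truth$truth
  probes <- truth$probes
  if (!any(probes$class == "signature")) {
    abort("no signature probes in this cohort")
  }
  signature_profile_matrix(probes, truth$config$cell_types)
}

#' Convert beta values to synthetic methylated/unmethylated intensities
#'
#' Inverse of the Illumina beta formula: given a total intensity `S` per
#' probe, returns `M = beta * (S + offset)` and `U = S - M`, so that
#' [compute_beta()] recovers the input exactly.  A beta value is feasible
#' only if `beta <= S / (S + offset)`.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param total_intensity Total fluorescence `M + U` per probe (scalar).
#' @param offset The additive constant of the beta formula (default 100).
#' @return List of class `intensity_pair` with matrices `M` and `U`.
#' @export
betas_to_intensities <- function(beta, total_intensity = 2000, offset = 100) {
  if (!is.matrix(beta)) beta <- as.matrix(beta)
  S <- total_intensity
  if (S <= 0) abort("total_intensity must be > 0")
  bmax <- S / (S + offset)
  if (any(beta > bmax + 1e-15, na.rm = TRUE)) {
    abort(sprintf(
      "beta values above %.6f are infeasible at total intensity %g", bmax, S))
  }
  if (any(beta < 0, na.rm = TRUE)) abort("beta values must be >= 0")
  M <- beta * (S + offset)
  U <- S - M
  structure(list(M = M, U = U), class = "intensity_pair")
}
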