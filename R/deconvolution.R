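#' Estimate blood cell proportions by reference-based deconvolution
#'
#' Projects each sample's methylation profile onto purified cell-type
#' reference signatures by non-negative least squares: per sample it solves
#' `min || x - R w ||^2` subject to `w >= 0` over the signature probes shared
#' between the data and the reference.  Raw coefficients are reported as
#' interpretable cell "counts" (they need not sum to 1); sum-normalized
#' proportions are reported alongside.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param ref Signature-probe-by-cell-type reference matrix, e.g. from
#'   [make_reference_matrix()].
#' @return A tibble of class `cell_counts`: `sample_id`, one raw-coefficient
#'   column per cell type, and `prop_<type>` normalized columns.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 60, seed = 3))
#' ref <- make_reference_matrix(cohort)
#' counts <- estimate_cell_proportions(cohort$beta, ref)
#' @export
estimate_cell_proportions <- function(beta, ref) {
  check_beta_matrix(beta)
  shared <- intersect(rownames(beta), rownames(ref))
  types <- colnames(ref)
  if (length(shared) < length(types)) {
    abort("too few signature probes shared with the reference")
  }
  R <- ref[shared, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    warn("reference matrix is rank-deficient on the shared probes; cell-type estimates may not be unique")
  }
  W <- t(apply(beta[shared, , drop = FALSE], 2, function(x) {
    ok <- !is.na(x)
    pracma::lsqnonneg(R[ok, , drop = FALSE], x[ok])$x
  }))
  colnames(W) <- types
  tot <- rowSums(W)
  P <- W / ifelse(tot > 0, tot, 1)
  colnames(P) <- paste0("prop_", types)
  out <- dplyr::bind_cols(tibble(sample_id = colnames(beta)),
                          as_tibble(W), as_tibble(P))
  class(out) <- c("cell_counts", class(out))
  out
}

#' Collapse fine cell types to the six broad leukocyte types
#'
#' Sums naive + exhausted CD8+ T cells into CD8T and B + plasmablast into B,
#' giving the broad six-compartment panel (CD8T, CD4T, NK, B, mono, gran).
#'
#' @param counts A `cell_counts` tibble from [estimate_cell_proportions()].
#' @return Tibble with the broad-type raw coefficients and proportions.
#' @export
collapse_cell_counts <- function(counts) {
  groupings <- list(CD8T = c("naiveCD8T", "exhCD8T"), CD4T = "CD4T",
                    NK = "NK", B = c("B", "plasmablast"),
                    mono = "mono", gran = "gran")
  out <- tibble(sample_id = counts$sample_id)
  for (nm in names(groupings)) {
    src <- intersect(groupings[[nm]], names(counts))
    out[[nm]] <- rowSums(as.matrix(counts[, src, drop = FALSE]))
  }
  raw <- as.matrix(out[, names(groupings)])
  tot <- rowSums(raw)
  prop <- raw / ifelse(tot > 0, tot, 1)
  colnames(prop) <- paste0("prop_", names(groupings))
  dplyr::bind_cols(out, as_tibble(prop))
}

#' Train a penalized estimator for an immune-cell subset abundance
#'
#' Learns a linear predictor of a cell-subset abundance (e.g. the naive CD8+
#' T-cell score or the exhausted CD8+ T-cell percentage) from methylation, by
#' elastic net with cross-validated penalty -- the same construction as the
#' clock but without an age transform.  Used for the "advanced" subset
#' estimates that the broad reference-based deconvolution cannot resolve.
#'
#' @param beta Probe-by-sample training beta matrix.
#' @param truth_values Per-sample subset abundance to learn (any scale; the
#'   predictor output is on the same scale).
#' @param alpha Elastic-net mixing parameter.
#' @param nfolds Cross-validation folds.
#' @param seed Fold-assignment seed.
#' @return An object of class `subset_model`.
#' @export
train_subset_estimator <- function(beta, truth_values, alpha = 0.5,
                                   nfolds = 10, seed = 1) {
  check_beta_matrix(beta)
  n <- ncol(beta)
  if (n < 50) abort("need at least 50 training samples")
  if (length(truth_values) != n) {
    abort("truth_values must have one value per sample")
  }
  if (sd(truth_values) == 0) abort("truth values are constant")
  cv <- with_seed(seed, glmnet::cv.glmnet(t(beta), truth_values,
                                          alpha = alpha, nfolds = nfolds,
                                          family = "gaussian"))
  cf <- as.numeric(coef(cv, s = "lambda.min"))
  names(cf) <- c("(Intercept)", rownames(beta))
  nz <- cf[-1][cf[-1] != 0]
  structure(list(coef = nz, intercept = cf[[1]], alpha = alpha,
                 lambda = cv$lambda.min, seed = seed, n_train = n),
            class = "subset_model")
}

#' @export
print.subset_model <- function(x, ...) {
  cat(sprintf("<subset_model> %d nonzero coefficients, lambda = %.4g\n",
              length(x$coef), x$lambda))
  invisible(x)
}

predict_subset <- function(model, beta) {
  probes <- names(model$coef)
  miss <- setdiff(probes, rownames(beta))
  if (length(miss)) {
    abort(sprintf("%d model probe(s) missing from the data", length(miss)))
  }
  if (length(probes) == 0) {
    return(setNames(rep(model$intercept, ncol(beta)), colnames(beta)))
  }
  drop(crossprod(beta[probes, , drop = FALSE], model$coef)) + model$intercept
}

#' Apply trained subset estimators to a cohort
#'
#' @param models Named list of `subset_model`s (names become output columns,
#'   e.g. naiveCD8T, exhCD8T, plasmablast, naiveCD4T).
#' @param beta Probe-by-sample beta matrix.
#' @return Tibble: `sample_id` plus one score column per subset.
#' @export
estimate_advanced_subsets <- function(models, beta) {
  check_beta_matrix(beta)
  if (!length(models) || is.null(names(models))) {
    abort("`models` must be a named list of subset models")
  }
  out <- tibble(sample_id = colnames(beta))
  for (nm in names(models)) {
    out[[nm]] <- unname(predict_subset(models[[nm]], beta))
  }
  out
}
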