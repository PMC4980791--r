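#' Compute beta values from methylated/unmethylated intensities
#'
#' The standard Illumina 450K summary of per-probe methylation: the ratio of
#' the (floored) methylated signal to total floored signal plus a stabilising
#' offset,
#' `beta = max(M, 0) / (max(M, 0) + max(U, 0) + offset)`.
#' Negative intensities (possible after background correction) are clamped
#' to zero, and the offset keeps low-intensity probes away from extreme
#' ratios, so outputs always lie in `[0, 1)`.
#'
#' @param intensities An `intensity_pair` (list with matrices `M` and `U`),
#'   e.g. from [betas_to_intensities()] or [read_intensities()].
#' @param offset Positive stabilising constant, default 100.
#' @return Probe-by-sample beta matrix.
#' @examples
#' ip <- structure(list(M = matrix(900, 1, 1, dimnames = list("cg1", "s1")),
#'                      U = matrix(0, 1, 1, dimnames = list("cg1", "s1"))),
#'                 class = "intensity_pair")
#' compute_beta(ip)  # 900 / (900 + 0 + 100) = 0.9
#' @export
compute_beta <- function(intensities, offset = 100) {
  M <- intensities$M
  U <- intensities$U
  if (offset <= 0) abort("offset must be > 0")
  if (!identical(dim(M), dim(U))) abort("M and U must have identical shape")
  if (!is.null(dimnames(M)) && !is.null(dimnames(U)) &&
      !identical(dimnames(M), dimnames(U))) {
    abort("M and U must share probe and sample ids")
  }
  Mp <- pmax(M, 0)
  Up <- pmax(U, 0)
  beta <- Mp / (Mp + Up + offset)
  dimnames(beta) <- dimnames(M) %||% dimnames(U)
  beta
}

#' Calibrate each sample's beta distribution to a gold standard
#'
#' Per-sample quantile calibration: over the probes shared with the gold
#' standard, each sample's empirical beta distribution is mapped monotonically
#' onto the gold-standard distribution, so every calibrated sample has the
#' same marginal distribution over those probes.  This plays the role of
#' referencing each array to a stored standard before clock prediction, a
#' guard against platform- or batch-level distribution shifts; probes not in
#' the gold standard pass through unchanged.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param gold Named numeric vector: the gold-standard beta profile (e.g. the
#'   clock's per-probe training means, see [gold_standard()]).
#' @return Calibrated beta matrix, same shape and dimnames as `beta`.
#' @export
normalize_to_gold_standard <- function(beta, gold) {
  check_beta_matrix(beta)
  shared <- intersect(rownames(beta), names(gold))
  if (length(shared) < 10) {
    abort("fewer than 10 probes shared with the gold standard")
  }
  g <- sort(gold[shared])
  n <- length(shared)
  out <- beta
  for (j in seq_len(ncol(beta))) {
    x <- beta[shared, j]
    ok <- which(!is.na(x))
    if (!length(ok)) next
    # rank-preserving assignment of the gold quantiles: the sample's sorted
    # values become the gold's sorted values (stable order for ties), so
    # every calibrated sample carries the gold marginal distribution exactly
    gq <- if (length(ok) == n) g else {
      g[ceiling(seq_along(ok) / length(ok) * n - 1e-9)]
    }
    out[shared[ok][order(x[ok])], j] <- gq
  }
  out
}

#' Drop blacklisted probes from a beta matrix
#'
#' Removes probes on a blacklist (e.g. CpGs whose neighbourhood contains a
#' common SNP, which can produce spurious between-group differences), keeping
#' the order of the remaining probes.  Blacklist ids absent from the matrix
#' are ignored with a warning.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param blacklist Character vector of probe ids to remove.
#' @return Beta matrix without the blacklisted probes.
#' @export
drop_probes <- function(beta, blacklist) {
  check_beta_matrix(beta)
  blacklist <- unique(blacklist)
  absent <- setdiff(blacklist, rownames(beta))
  if (length(absent)) {
    warn(sprintf("%d blacklisted probe(s) not present; ignored",
                 length(absent)))
  }
  keep <- !(rownames(beta) %in% blacklist)
  beta[keep, , drop = FALSE]
}

#' Impute missing clock probes with their training means
#'
#' Any clock-model probe that is absent from the matrix, or NA for some
#' samples, is filled with the constant mean value observed in the clock's
#' training set.  This is the imputation used when re-running the clock after
#' removing SNP-adjacent probes: the dropped probes re-enter as constants, so
#' they shift all predictions equally and cancel in the acceleration
#' residuals.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param model A `clock_model` carrying per-probe training means.
#' @return Beta matrix covering every clock probe, missing entries filled.
#' @export
impute_missing_clock_probes <- function(beta, model) {
  stopifnot(inherits(model, "clock_model"))
  means <- model$training_means
  if (is.null(means)) abort("clock model lacks training means")
  probes <- names(model$coef)
  if (!all(probes %in% names(means))) {
    abort("clock model training means do not cover all model probes")
  }
  missing_rows <- setdiff(probes, rownames(beta))
  if (length(missing_rows)) {
    add <- matrix(rep(means[missing_rows], ncol(beta)),
                  nrow = length(missing_rows),
                  dimnames = list(missing_rows, colnames(beta)))
    beta <- rbind(beta, add)
  }
  present <- intersect(probes, rownames(beta))
  na_idx <- which(is.na(beta[present, , drop = FALSE]), arr.ind = TRUE)
  if (nrow(na_idx)) {
    beta[present, ][na_idx] <- means[present][na_idx[, "row"]]
  }
  beta
}
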