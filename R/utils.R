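# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive named per-stage substream seeds from one master seed.  Seeds are
# drawn once under the master stream, so adding stages at the end does not
# change earlier stages' seeds.  All values stay below 2^31.
stage_seeds <- function(master_seed, stages) {
  with_seed(master_seed, {
    setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# One Dirichlet draw with parameter vector `alpha` via gamma variates.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1  # guard vs extreme underflow
  g / sum(g)
}

# Validate a probe-by-sample beta matrix (rownames = probe ids,
# colnames = sample ids).  NA entries allowed (explicit missing mask).
check_beta_matrix <- function(beta, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric probe-by-sample matrix", arg))
  }
  if (is.null(rownames(beta)) || anyDuplicated(rownames(beta))) {
    abort(sprintf("`%s` must have unique probe ids as rownames", arg))
  }
  if (is.null(colnames(beta)) || anyDuplicated(colnames(beta))) {
    abort(sprintf("`%s` must have unique sample ids as colnames", arg))
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
    abort(sprintf("`%s` has values outside [0, 1]", arg))
  }
  invisible(beta)
}
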