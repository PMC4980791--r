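#' Calibrated age transform of the epigenetic clock
#'
#' The clock regresses a transformed age on methylation: logarithmic below
#' the adult age `A` (fast developmental methylation change) and linear above
#' it,
#' `F(age) = log(age + 1) - log(A + 1)` for `age <= A`, and
#' `F(age) = (age - A) / (A + 1)` otherwise.
#' `F` is continuous, strictly increasing, zero at `A`, and has the exact
#' inverse [inverse_transform_age()].
#'
#' @param age Ages in years (must be `> -1`).
#' @param adult_age Adult-age constant `A` in years, default 20.
#' @return Transformed ages.
#' @export
transform_age <- function(age, adult_age = 20) {
  if (adult_age <= 0) abort("adult_age must be > 0")
  if (any(age <= -1, na.rm = TRUE)) abort("age must be > -1")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @param x Transformed ages.
#' @export
inverse_transform_age <- function(x, adult_age = 20) {
  if (adult_age <= 0) abort("adult_age must be > 0")
  ifelse(x <= 0,
         exp(x) * (adult_age + 1) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Train a penalized-regression DNAm age clock
#'
#' Fits an elastic-net regression of transformed age on CpG beta values
#' (mixing parameter `alpha`, penalty chosen by k-fold cross-validation
#' minimising mean-squared error), the construction used by published
#' methylation clocks.  The returned model stores the nonzero probe
#' coefficients, the intercept, the age transform constant, and the per-probe
#' training means of the whole training universe, which later serve both as
#' the constant-imputation values for missing clock probes and as the
#' gold-standard profile for sample calibration.
#'
#' @param beta Probe-by-sample training beta matrix.
#' @param age Chronological (or known intrinsic) ages, one per sample.
#' @param adult_age Age-transform constant in years.
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param nfolds Cross-validation folds.
#' @param seed Seed fixing the cross-validation fold assignment.
#' @return An object of class `clock_model`.
#' @seealso [predict_dnam_age()], [impute_missing_clock_probes()]
#' @export
train_clock <- function(beta, age, adult_age = 20, alpha = 0.5,
                        nfolds = 10, seed = 1) {
  check_beta_matrix(beta)
  n <- ncol(beta)
  if (n < 50) abort("need at least 50 training samples")
  if (length(age) != n) abort("age must have one value per sample")
  if (!all(is.finite(age))) abort("ages must be finite")
  if (sd(age) == 0) abort("training ages are constant")
  if (n < nfolds) abort("fewer samples than cross-validation folds")
  y <- transform_age(age, adult_age)
  X <- t(beta)
  cv <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = alpha,
                                          nfolds = nfolds,
                                          family = "gaussian"))
  cf <- as.numeric(coef(cv, s = "lambda.min"))
  names(cf) <- c("(Intercept)", rownames(beta))
  nz <- cf[-1][cf[-1] != 0]
  structure(
    list(coef = nz, intercept = cf[[1]], adult_age = adult_age,
         training_means = rowMeans(beta, na.rm = TRUE),
         alpha = alpha, lambda = cv$lambda.min, nfolds = nfolds,
         seed = seed, n_train = n),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "<clock_model> %d probes with nonzero coefficients (of %d trained), %s",
    length(x$coef), length(x$training_means),
    sprintf("adult_age = %g, lambda = %.4g, n_train = %d\n",
            x$adult_age, x$lambda, x$n_train)))
  invisible(x)
}

#' Gold-standard beta profile of a clock model
#'
#' The per-probe training-set mean profile stored in a fitted clock, used as
#' the reference distribution for [normalize_to_gold_standard()].
#'
#' @param model A `clock_model`.
#' @param probes `"model"` restricts to probes with nonzero coefficients,
#'   `"all"` returns the full training universe.
#' @return Named numeric vector of mean beta values.
#' @export
gold_standard <- function(model, probes = c("all", "model")) {
  stopifnot(inherits(model, "clock_model"))
  probes <- match.arg(probes)
  if (probes == "model") model$training_means[names(model$coef)]
  else model$training_means
}

#' Predict DNAm age
#'
#' Applies a fitted clock: the linear predictor over the model's probes is
#' inverted through the age transform to give DNAm (epigenetic) age in years.
#'
#' @param model A `clock_model` from [train_clock()].
#' @param beta Probe-by-sample beta matrix covering the model probes (after
#'   [impute_missing_clock_probes()] if any are missing).
#' @return Named numeric vector of DNAm ages (years), one per sample.
#' @export
predict_dnam_age <- function(model, beta) {
  stopifnot(inherits(model, "clock_model"))
  probes <- names(model$coef)
  miss <- setdiff(probes, rownames(beta))
  if (length(miss)) {
    abort(sprintf(
      "%d clock probe(s) missing from the data; run impute_missing_clock_probes() first",
      length(miss)))
  }
  X <- beta[probes, , drop = FALSE]
  if (anyNA(X)) {
    abort("NA beta values at clock probes; impute before prediction")
  }
  lp <- drop(crossprod(X, model$coef)) + model$intercept
  setNames(inverse_transform_age(lp, model$adult_age), colnames(beta))
}

#' Universal epigenetic age acceleration
#'
#' The universal age-acceleration measure: the vertical distance between a
#' sample's DNAm age and a spline regression line of DNAm age on
#' chronological age fitted in a designated reference group only.  By
#' construction the reference group's mean acceleration is zero, so other
#' groups' means read as offsets relative to the reference.  A natural cubic
#' spline with `df` degrees of freedom is used when the reference group has
#' at least 30 samples; otherwise a simple linear fit.
#'
#' @param data Data frame with one row per sample.
#' @param reference_group Label of the reference group.
#' @param dnam_age,age,group Column names in `data`.
#' @param df Spline degrees of freedom (default 4).
#' @return Object of class `age_accel_fit`: `data` (input tibble plus an
#'   `age_accel` column), `fit` (the reference-group regression),
#'   `reference_group`, `spline` (logical: spline or linear fallback).
#' @export
universal_age_accel <- function(data, reference_group, dnam_age = "dnam_age",
                                age = "age", group = "group", df = 4) {
  data <- as_tibble(data)
  for (col in c(dnam_age, age, group)) {
    if (!col %in% names(data)) abort(sprintf("column '%s' not in data", col))
  }
  ref <- data[data[[group]] == reference_group, ]
  if (nrow(ref) == 0) {
    abort(sprintf("reference group '%s' absent", reference_group))
  }
  if (nrow(ref) < 10) abort("need >= 10 reference-group samples")
  use_spline <- nrow(ref) >= 30
  fml <- if (use_spline) {
    as.formula(sprintf("%s ~ splines::ns(%s, df = %d)", dnam_age, age, df))
  } else {
    as.formula(sprintf("%s ~ %s", dnam_age, age))
  }
  fit <- lm(fml, data = ref)
  data$age_accel <- data[[dnam_age]] - unname(predict(fit, newdata = data))
  structure(list(data = data, fit = fit, reference_group = reference_group,
                 spline = use_spline, df = if (use_spline) df else 1L),
            class = "age_accel_fit")
}

#' @export
print.age_accel_fit <- function(x, ...) {
  cat(sprintf(
    "<age_accel_fit> %d samples; reference group '%s' (%s fit)\n",
    nrow(x$data), x$reference_group,
    if (x$spline) sprintf("natural spline, df = %d", x$df) else "linear"))
  invisible(x)
}
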