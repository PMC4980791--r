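#' Compare a measure across groups
#'
#' One-way group comparison of an age-acceleration (or any) measure:
#' parametric one-way ANOVA F-test or the rank-based Kruskal-Wallis test
#' (midrank ties with the standard tie-correction).  Alongside the test it
#' reports each group's n, mean and standard error -- the quantities shown in
#' the bar-plot panels such comparisons are usually displayed as.
#'
#' @param data Data frame with one row per sample.
#' @param value,group Column names of the measure and the group label.
#' @param method `"anova"` or `"kruskal"`.
#' @return Object of class `group_comparison`: per-group summary tibble,
#'   test statistic, degrees of freedom, p-value, method.
#' @examples
#' d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), 20))
#' group_test(d, "y", "g")
#' @export
group_test <- function(data, value = "value", group = "group",
                       method = c("anova", "kruskal")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 samples")
  summary_tbl <- tibble(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    se = as.numeric(tapply(y, g, function(v) sd(v) / sqrt(length(v)))))
  if (method == "anova") {
    if (all(tapply(y, g, sd) == 0)) {
      abort("zero within-group variance; ANOVA undefined")
    }
    a <- anova(lm(y ~ g))
    statistic <- a$`F value`[1]
    df <- c(a$Df[1], a$Df[2])
    p <- a$`Pr(>F)`[1]
  } else {
    k <- kruskal.test(y, g)
    statistic <- unname(k$statistic)
    df <- unname(k$parameter)
    p <- k$p.value
  }
  structure(list(summary = summary_tbl, statistic = statistic, df = df,
                 p_value = p, method = method, value = value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s of '%s': statistic = %.4g, p = %.3g\n",
              if (x$method == "anova") "ANOVA" else "Kruskal-Wallis",
              x$value, x$statistic, x$p_value))
  print(x$summary)
  invisible(x)
}

#' Signed z-score for a two-group contrast
#'
#' Converts a two-group mean comparison into a signed standard-normal score
#' (Welch t re-expressed as z), with the sign fixed by the stated group
#' order: positive when `group1`'s mean exceeds `group2`'s.  These per-study
#' z-scores are the inputs to [stouffer_meta()].
#'
#' @param data Data frame with one row per sample.
#' @param value,group Column names.
#' @param group1,group2 The two group labels defining the contrast direction.
#' @return One row tibble: estimate (mean difference), se, z, p_value, n.
#' @export
contrast_z <- function(data, value, group, group1, group2) {
  data <- as.data.frame(data)
  y1 <- data[data[[group]] == group1, value]
  y2 <- data[data[[group]] == group2, value]
  y1 <- y1[!is.na(y1)]; y2 <- y2[!is.na(y2)]
  if (length(y1) < 2 || length(y2) < 2) {
    abort("both groups need at least 2 samples")
  }
  se <- sqrt(var(y1) / length(y1) + var(y2) / length(y2))
  est <- mean(y1) - mean(y2)
  z <- est / se
  tibble(estimate = est, se = se, z = z,
         p_value = 2 * pnorm(-abs(z)), n = length(y1) + length(y2))
}

#' Stouffer's z-score meta-analysis
#'
#' Combines per-study signed z-scores into one test:
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`, with a two-sided p-value from the
#' standard normal.  Default weights are `sqrt(n_i)` when study sizes are
#' given, equal otherwise.
#'
#' @param z Per-study signed z-scores.
#' @param n Optional per-study sample sizes (used for default weights).
#' @param weights Optional positive per-study weights (overrides `n`).
#' @return Object of class `meta_result` (method `"stouffer"`), with the
#'   per-study table, combined z and two-sided p-value.
#' @export
stouffer_meta <- function(z, n = NULL, weights = NULL) {
  if (length(z) < 1) abort("need at least one study")
  if (is.null(weights)) {
    weights <- if (is.null(n)) rep(1, length(z)) else sqrt(n)
  }
  if (length(weights) != length(z) || any(weights <= 0)) {
    abort("weights must be positive, one per study")
  }
  zc <- sum(weights * z) / sqrt(sum(weights^2))
  structure(list(
    studies = tibble(study = seq_along(z), z = z, weight = weights),
    z = zc, p_value = 2 * pnorm(-abs(zc)), method = "stouffer"),
    class = "meta_result")
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study mean differences weighting each study by the inverse of
#' its squared standard error: `w_i = 1 / se_i^2`,
#' `pooled = sum(w_i d_i) / sum(w_i)`, `SE = 1 / sqrt(sum(w_i))`, with a
#' normal 95% confidence interval and two-sided p-value -- the forest-plot
#' model for combining a group effect estimated in several datasets.
#'
#' @param d Per-study effect estimates (e.g. mean differences).
#' @param se Per-study standard errors (positive).
#' @param labels Optional study labels.
#' @return Object of class `meta_result` (method `"fixed_effects"`):
#'   per-study table, pooled estimate, SE, 95% CI, z, p-value.
#' @export
fixed_effects_meta <- function(d, se, labels = NULL) {
  if (length(d) < 1) abort("need at least one study")
  if (length(se) != length(d) || any(se <= 0)) {
    abort("standard errors must be positive, one per study")
  }
  w <- 1 / se^2
  pooled <- sum(w * d) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  structure(list(
    studies = tibble(study = labels %||% paste0("study", seq_along(d)),
                     estimate = d, se = se, weight = w / sum(w)),
    estimate = pooled, se = pse,
    ci_low = pooled - qnorm(0.975) * pse,
    ci_high = pooled + qnorm(0.975) * pse,
    z = z, p_value = 2 * pnorm(-abs(z)), method = "fixed_effects"),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$method == "stouffer") {
    cat(sprintf("<meta_result> Stouffer: %d studies, Z = %.4g, p = %.3g\n",
                nrow(x$studies), x$z, x$p_value))
  } else {
    cat(sprintf(
      "<meta_result> fixed effects: %d studies, estimate = %.4g [%.4g, %.4g], p = %.3g\n",
      nrow(x$studies), x$estimate, x$ci_low, x$ci_high, x$p_value))
  }
  invisible(x)
}

#' Plain-text forest table of a meta-analysis
#'
#' @param x A `meta_result`.
#' @return Character vector (one line per study plus the pooled row),
#'   invisibly also printed.
#' @export
forest_table <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  if (x$method == "fixed_effects") {
    lines <- c(
      sprintf("%-12s %10s %10s %8s", "study", "estimate", "se", "weight"),
      sprintf("%-12s %10.3f %10.3f %7.1f%%", x$studies$study,
              x$studies$estimate, x$studies$se, 100 * x$studies$weight),
      sprintf("%-12s %10.3f [%.3f, %.3f]  p = %.3g", "pooled",
              x$estimate, x$ci_low, x$ci_high, x$p_value))
  } else {
    lines <- c(
      sprintf("%-12s %10s %10s", "study", "z", "weight"),
      sprintf("%-12s %10.3f %10.3f", paste0("study", x$studies$study),
              x$studies$z, x$studies$weight),
      sprintf("%-12s Z = %.3f, p = %.3g", "combined", x$z, x$p_value))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Regress an age-acceleration measure on participant characteristics
#'
#' OLS of a measure (AgeAccel, IEAA or EEAA) on covariates, with categorical
#' covariates expanded against their first (reference) level.  All-constant
#' covariates are dropped with a warning; exactly collinear terms are dropped
#' by the fit with a warning.
#'
#' @param accel The measure, one value per sample.
#' @param covariates Data frame of covariates.
#' @return Object of class `covariate_model`: coefficient tibble (term,
#'   estimate, std_error, statistic, p_value), `r_squared`, `n`, and the
#'   reference level of each factor covariate.
#' @export
fit_accel_covariate_model <- function(accel, covariates) {
  covariates <- as.data.frame(covariates)
  covariates <- covariates[, setdiff(names(covariates), "sample_id"),
                           drop = FALSE]
  n <- length(accel)
  if (nrow(covariates) != n) {
    abort("accel and covariates must describe the same samples")
  }
  is_cat <- vapply(covariates, function(x) is.character(x) || is.factor(x),
                   logical(1))
  for (nm in names(covariates)[is_cat]) {
    covariates[[nm]] <- factor(covariates[[nm]])
  }
  const <- vapply(covariates, function(x) {
    length(unique(x[!is.na(x)])) < 2
  }, logical(1))
  if (any(const)) {
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(names(covariates)[const], collapse = ", ")))
    covariates <- covariates[, !const, drop = FALSE]
  }
  if (n <= ncol(covariates) + 2) abort("too few samples")
  df <- data.frame(.accel = accel, covariates)
  fit <- lm(.accel ~ ., data = df)
  if (anyNA(coef(fit))) warn("collinear covariate(s) dropped")
  refs <- vapply(covariates[vapply(covariates, is.factor, logical(1))],
                 function(x) levels(x)[1], character(1))
  structure(list(coefficients = lm_coef_table(fit),
                 r_squared = summary(fit)$r.squared,
                 n = n, reference_levels = refs, fit = fit),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat(sprintf("<covariate_model> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Logistic regression of a binary outcome on age acceleration
#'
#' Maximum-likelihood logistic model of a binary outcome (e.g. disease
#' status) on an age-acceleration measure and optional covariates, reporting
#' Wald z-tests.  Complete separation is detected and raised as an error
#' (the ML estimate does not exist there).
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param accel The age-acceleration measure.
#' @param covariates Optional data frame of additional covariates.
#' @return Object of class `outcome_model`: coefficient tibble (term,
#'   estimate, std_error, statistic, p_value), `n`, and the fit.
#' @export
fit_outcome_model <- function(outcome, accel, covariates = NULL) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) abort("outcome must be binary (0/1)")
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  df <- data.frame(.y = y, accel = accel)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates <- covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
    df <- data.frame(df, covariates)
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p_hat <- fitted(fit)
  separated <- sep_warned &&
    min(p_hat[y == 1]) > max(p_hat[y == 0]) &&
    all(p_hat[y == 1] > 1 - 1e-6) && all(p_hat[y == 0] < 1e-6)
  if (separated) abort("complete separation: logistic ML estimate does not exist")
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = tibble(term = rownames(s), estimate = s[, 1],
                          std_error = s[, 2], statistic = s[, 3],
                          p_value = s[, 4]),
    n = length(y), fit = fit),
    class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model> logistic regression, n = %d\n", x$n))
  print(x$coefficients)
  invisible(x)
}
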