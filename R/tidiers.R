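# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted clock model
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble of nonzero probe coefficients with training means.
#' @export
tidy.clock_model <- function(x, ...) {
  tibble(probe_id = names(x$coef), coefficient = unname(x$coef),
         training_mean = unname(x$training_means[names(x$coef)]))
}

#' @rdname tidy.clock_model
#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_probes = length(x$coef), n_train = x$n_train,
         adult_age = x$adult_age, alpha = x$alpha, lambda = x$lambda)
}

#' Tidy an age-acceleration result
#'
#' @param x An `accel_result` (or `age_accel_fit`).
#' @param ... Unused.
#' @return The per-sample tibble with `age_accel`, `ieaa`, `eeaa` columns.
#' @export
tidy.accel_result <- function(x, ...) x$data

#' @rdname tidy.accel_result
#' @export
glance.accel_result <- function(x, ...) {
  d <- x$data
  tibble(n = nrow(d),
         cor_dnam_age_age = cor(d$dnam_age, d$age),
         mean_age_accel_reference =
           mean(d$age_accel[d$group == x$universal$reference_group]),
         cor_ieaa_age = cor(d$ieaa, d$age),
         cor_eeaa_age = cor(d$eeaa, d$age),
         cor_ieaa_eeaa = cor(d$ieaa, d$eeaa))
}

#' @export
tidy.age_accel_fit <- function(x, ...) x$data

#' Tidy an IEAA fit
#'
#' @param x An `ieaa_fit`.
#' @param ... Unused.
#' @return Coefficient tibble of the DNAm-age-on-covariates regression.
#' @export
tidy.ieaa_fit <- function(x, ...) x$coefficients

#' Tidy a Klemera-Doubal calibration
#'
#' @param x A `kd_model`.
#' @param ... Unused.
#' @return Tibble with marker, k (slope), q (intercept), s (residual SD).
#' @export
tidy.kd_model <- function(x, ...) {
  tibble(marker = x$marker, k = x$k, q = x$q, s = x$s,
         t_statistic = x$t_statistic)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Per-group summary tibble (group, n, mean, se).
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value)
}

#' Tidy a meta-analysis result
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return Per-study tibble.
#' @export
tidy.meta_result <- function(x, ...) x$studies

#' @rdname tidy.meta_result
#' @export
glance.meta_result <- function(x, ...) {
  if (x$method == "stouffer") {
    tibble(method = x$method, z = x$z, p_value = x$p_value)
  } else {
    tibble(method = x$method, estimate = x$estimate, se = x$se,
           ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value)
  }
}

#' Tidy a covariate model
#'
#' @param x A `covariate_model` or `outcome_model`.
#' @param ... Unused.
#' @return Coefficient tibble (term, estimate, std_error, statistic,
#'   p_value).
#' @export
tidy.covariate_model <- function(x, ...) x$coefficients

#' @rdname tidy.covariate_model
#' @export
glance.covariate_model <- function(x, ...) {
  tibble(n = x$n, r_squared = x$r_squared)
}

#' @rdname tidy.covariate_model
#' @export
tidy.outcome_model <- function(x, ...) x$coefficients
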