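# ggplot2 visualisations for the main result types.

#' Plot DNAm age against chronological age
#'
#' Scatter of DNAm age versus age, coloured by group, with the
#' reference-group regression line whose residuals define the universal
#' age-acceleration measure.
#'
#' @param object An `accel_result` or `age_accel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accel_result <- function(object, ...) {
  autoplot.age_accel_fit(object$universal, ...)
}

#' @rdname autoplot.accel_result
#' @export
autoplot.age_accel_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(age = seq(min(d$age), max(d$age), length.out = 200))
  grid$dnam_age <- predict(object$fit, newdata = grid)
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$dnam_age)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "grey30", linewidth = 1) +
    ggplot2::labs(x = "chronological age (years)", y = "DNAm age (years)",
                  colour = "group",
                  title = sprintf("reference fit in group '%s'",
                                  object$reference_group)) +
    ggplot2::theme_minimal()
}

#' Bar plot of group means with standard errors
#'
#' The bar-plot rendering of a group comparison: per-group mean of the
#' measure with one-standard-error bars and the test p-value in the title.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se), width = 0.15) +
    ggplot2::labs(
      x = NULL, y = object$value,
      title = sprintf("%s p = %.2g",
                      if (object$method == "anova") "ANOVA"
                      else "Kruskal-Wallis", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a fixed-effects meta-analysis
#'
#' Per-study estimates with 95% intervals and the pooled estimate.
#'
#' @param object A `meta_result` with method `"fixed_effects"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_result <- function(object, ...) {
  if (object$method != "fixed_effects") {
    abort("forest plots are defined for fixed-effects results")
  }
  s <- object$studies
  d <- tibble(study = c(s$study, "pooled"),
              estimate = c(s$estimate, object$estimate),
              low = c(s$estimate - qnorm(0.975) * s$se, object$ci_low),
              high = c(s$estimate + qnorm(0.975) * s$se, object$ci_high),
              pooled = c(rep(FALSE, nrow(s)), TRUE))
  d$study <- factor(d$study, levels = rev(d$study))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$study,
                                  colour = .data$pooled)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled), size = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low,
                                         xmax = .data$high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "black",
                                            "TRUE" = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c("FALSE" = 15, "TRUE" = 18),
                                guide = "none") +
    ggplot2::labs(x = "effect estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated versus true cell proportions
#'
#' Diagnostic scatter for simulated cohorts where the truth is known.
#'
#' @param counts `cell_counts` tibble from [estimate_cell_proportions()].
#' @param truth_samples Truth tibble with `w_*` columns (from
#'   `cohort$truth$samples`).
#' @return A ggplot object, faceted by cell type.
#' @export
plot_deconvolution_fit <- function(counts, truth_samples) {
  types <- sub("^w_", "", grep("^w_", names(truth_samples), value = TRUE))
  types <- intersect(types, names(counts))
  truth_samples <- as_tibble(truth_samples)[
    match(counts$sample_id, truth_samples$sample_id), ]
  long <- dplyr::bind_rows(lapply(types, function(ct) {
    tibble(cell_type = ct, truth = truth_samples[[paste0("w_", ct)]],
           estimate = counts[[paste0("prop_", ct)]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$truth, .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "true proportion", y = "estimated proportion") +
    ggplot2::theme_minimal()
}
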