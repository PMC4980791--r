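#' Intrinsic epigenetic age acceleration (IEAA)
#'
#' IEAA is the residual from a multivariate OLS regression of DNAm age on
#' chronological age and blood immune-cell abundances (naive CD8+ T cells,
#' exhausted CD8+ T cells, plasmablasts, CD4+ T cells, natural killer cells,
#' monocytes, granulocytes).  Because blood-composition variation is
#' projected out, IEAA measures cell-intrinsic epigenetic aging: by OLS
#' construction it has mean zero and is exactly uncorrelated with age and
#' with every cell covariate on the fitting cohort.
#'
#' @param dnam_age DNAm ages (years).
#' @param age Chronological ages (years).
#' @param cells Data frame of cell-abundance covariates (one row per sample);
#'   constant columns are dropped with a warning, collinear columns are
#'   dropped by the OLS fit with a warning.
#' @return Object of class `ieaa_fit`: `ieaa` (residual vector, years),
#'   `coefficients` (tibble: term, estimate, std_error, statistic, p_value),
#'   `fit` (the underlying `lm`).
#' @export
compute_ieaa <- function(dnam_age, age, cells) {
  cells <- as.data.frame(cells)
  cells <- cells[, setdiff(names(cells), "sample_id"), drop = FALSE]
  n <- length(dnam_age)
  if (length(age) != n || nrow(cells) != n) {
    abort("dnam_age, age and cells must describe the same samples")
  }
  keep <- vapply(cells, function(x) sd(x) > 0, logical(1))
  if (any(!keep)) {
    warn(sprintf("dropping constant cell covariate(s): %s",
                 paste(names(cells)[!keep], collapse = ", ")))
    cells <- cells[, keep, drop = FALSE]
  }
  if (n <= ncol(cells) + 3) abort("too few samples for the IEAA regression")
  df <- data.frame(.dnam_age = dnam_age, .age = age, cells)
  fit <- lm(.dnam_age ~ ., data = df)
  if (anyNA(coef(fit))) {
    warn("collinear cell covariate(s) dropped from the IEAA regression")
  }
  structure(list(ieaa = unname(residuals(fit)),
                 coefficients = lm_coef_table(fit),
                 fit = fit),
            class = "ieaa_fit")
}

lm_coef_table <- function(fit) {
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' Fit a Klemera-Doubal marker calibration
#'
#' For each aging marker, fits the simple regression `marker = q + k * age`
#' and records the slope `k`, intercept `q` and residual SD `s` (computed
#' with an `n - 2` denominator).  Markers whose age slope is not clearly
#' nonzero (|t| <= 2) carry no age information and are excluded with a
#' warning.  A small floor `1e-6 * |k|` keeps `s` positive for noiseless
#' degenerate markers.
#'
#' @param markers Data frame or matrix, one column per marker (a blood DNAm
#'   age and the naive CD8+ T, exhausted CD8+ T and plasmablast scores in the
#'   standard EEAA panel), one row per sample.
#' @param age Chronological ages (years).
#' @param t_threshold Absolute t-statistic below which a marker is excluded.
#' @return Object of class `kd_model`: tibble with columns marker, k, q, s.
#' @seealso [kd_composite_age()], [compute_eeaa()]
#' @export
fit_kd_model <- function(markers, age, t_threshold = 2) {
  markers <- as.data.frame(markers)
  markers <- markers[, setdiff(names(markers), "sample_id"), drop = FALSE]
  n <- nrow(markers)
  if (n < 20) abort("need at least 20 samples to calibrate markers")
  if (length(age) != n) abort("age must have one value per sample")
  if (sd(age) == 0) abort("ages are constant; cannot calibrate markers")
  rows <- lapply(names(markers), function(nm) {
    x <- markers[[nm]]
    if (sd(x) == 0) abort(sprintf("marker '%s' is constant", nm))
    fit <- lm(x ~ age)
    # noiseless markers trip summary.lm's perfect-fit warning; the s floor
    # below handles that case deliberately
    s2 <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
    tstat <- s2$coefficients["age", "t value"]
    tibble(marker = nm, k = coef(fit)[["age"]],
           q = coef(fit)[["(Intercept)"]],
           s = s2$sigma, t_statistic = tstat)
  })
  tab <- dplyr::bind_rows(rows)
  weak <- abs(tab$t_statistic) <= t_threshold
  if (any(weak)) {
    warn(sprintf("excluding marker(s) with no clear age slope: %s",
                 paste(tab$marker[weak], collapse = ", ")))
    tab <- tab[!weak, ]
  }
  if (nrow(tab) == 0) abort("no marker passed the age-slope screen")
  tab$s <- pmax(tab$s, 1e-6 * abs(tab$k))
  structure(tab, class = c("kd_model", class(tab)))
}

#' Klemera-Doubal composite biological age
#'
#' Combines the calibrated markers into one biological-age estimate: each
#' marker's inverse-regression estimate `(x_j - q_j) / k_j` is weighted by
#' `k_j^2 / s_j^2`, i.e.
#' `BA = sum_j (x_j - q_j) k_j / s_j^2  /  sum_j k_j^2 / s_j^2`.
#' Markers with steep, tight age trajectories dominate; the estimate is
#' invariant to rescaling any marker.  This is the weighted average of a
#' blood DNAm age and immune-cell abundances that underlies EEAA.
#'
#' @param model A `kd_model` from [fit_kd_model()].
#' @param markers Data frame with a column for every model marker.
#' @return Numeric vector of composite biological ages (years).
#' @export
kd_composite_age <- function(model, markers) {
  stopifnot(inherits(model, "kd_model"))
  markers <- as.data.frame(markers)
  miss <- setdiff(model$marker, names(markers))
  if (length(miss)) {
    abort(sprintf("missing marker column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(model) == 0) abort("empty marker set")
  X <- as.matrix(markers[, model$marker, drop = FALSE])
  num <- sweep(X, 2, model$q) %*% (model$k / model$s^2)
  den <- sum(model$k^2 / model$s^2)
  drop(num) / den
}

#' Extrinsic epigenetic age acceleration (EEAA)
#'
#' EEAA is the residual from a univariate regression of the Klemera-Doubal
#' composite biological age on chronological age.  Because the composite
#' blends a blood-trained DNAm age with immunosenescence markers, EEAA tracks
#' both intrinsic epigenetic change and age-related blood-composition
#' remodelling: it correlates positively with exhausted CD8+ T and
#' plasmablast abundance and negatively with naive CD8+ T abundance, while
#' being mean-zero and uncorrelated with age by construction.
#'
#' @param composite Composite biological ages from [kd_composite_age()].
#' @param age Chronological ages (years).
#' @return Object of class `eeaa_fit`: `eeaa` (residual vector, years) and
#'   `fit` (the composite-on-age `lm`).
#' @export
compute_eeaa <- function(composite, age) {
  n <- length(composite)
  if (n < 10) abort("need at least 10 samples")
  if (length(age) != n) abort("composite and age must have equal length")
  if (sd(age) == 0) abort("ages are constant")
  fit <- lm(composite ~ age)
  structure(list(eeaa = unname(residuals(fit)), fit = fit),
            class = "eeaa_fit")
}

#' Compute all three age-acceleration measures for a cohort
#'
#' Convenience wrapper tying the pieces together for one analysis dataset:
#' universal age acceleration (spline residual in the reference group), IEAA
#' (DNAm age residual on age + 7 cell covariates) and EEAA (Klemera-Doubal
#' composite residual on age, combining a blood DNAm age with the naive
#' CD8+ T, exhausted CD8+ T and plasmablast scores).
#'
#' @param samples Sample tibble with columns `sample_id`, `age`, `group`.
#' @param dnam_age DNAm age from the primary clock (years).
#' @param blood_age DNAm age from the blood-trained clock (years).
#' @param cells `cell_counts` tibble (broad types, raw coefficients).
#' @param subsets Advanced-subset tibble with columns `naiveCD8T`,
#'   `exhCD8T`, `plasmablast`.
#' @param reference_group Reference group for the universal measure.
#' @param spline_df Spline degrees of freedom for the universal measure.
#' @return Object of class `accel_result`: `data` (samples plus `dnam_age`,
#'   `blood_age`, `age_accel`, `ieaa`, `eeaa`), plus the component fits
#'   (`universal`, `ieaa_fit`, `kd_model`, `eeaa_fit`).
#' @export
compute_acceleration <- function(samples, dnam_age, blood_age, cells,
                                 subsets, reference_group, spline_df = 4) {
  samples <- as_tibble(samples)
  stopifnot(nrow(samples) == length(dnam_age),
            nrow(samples) == length(blood_age))
  cells <- as_tibble(cells)[match(samples$sample_id, cells$sample_id), ]
  subsets <- as_tibble(subsets)[match(samples$sample_id, subsets$sample_id), ]
  df <- samples
  df$dnam_age <- unname(dnam_age)
  df$blood_age <- unname(blood_age)
  uni <- universal_age_accel(df, reference_group, df = spline_df)
  covars <- dplyr::bind_cols(
    subsets[, c("naiveCD8T", "exhCD8T", "plasmablast")],
    cells[, intersect(c("CD4T", "NK", "mono", "gran"), names(cells))])
  ieaa <- compute_ieaa(df$dnam_age, df$age, covars)
  kd_markers <- dplyr::bind_cols(
    tibble(blood_age = df$blood_age),
    subsets[, c("naiveCD8T", "exhCD8T", "plasmablast")])
  kd <- fit_kd_model(kd_markers, df$age)
  ba <- kd_composite_age(kd, kd_markers)
  eeaa <- compute_eeaa(ba, df$age)
  out <- uni$data
  out$ieaa <- ieaa$ieaa
  out$kd_age <- ba
  out$eeaa <- eeaa$eeaa
  structure(list(data = out, universal = uni, ieaa_fit = ieaa,
                 kd_model = kd, eeaa_fit = eeaa),
            class = "accel_result")
}

#' @export
print.accel_result <- function(x, ...) {
  cat(sprintf(
    "<accel_result> %d samples; reference group '%s'; KD markers: %s\n",
    nrow(x$data), x$universal$reference_group,
    paste(x$kd_model$marker, collapse = ", ")))
  invisible(x)
}
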