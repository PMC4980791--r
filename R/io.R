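# Tab-delimited readers and writers for the pipeline's file formats.
# All files are UTF-8 TSV with headers; beta matrices have a `probe_id`
# first column and one column per sample.

#' Read / write a probe-by-sample beta matrix as TSV
#'
#' @param path File path.
#' @return `read_beta_matrix()`: numeric matrix with probe rownames and
#'   sample colnames; NA entries mark missing values.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_beta_matrix
#' @param beta Probe-by-sample matrix.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- dplyr::bind_cols(tibble(probe_id = rownames(beta)),
                         as_tibble(beta))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample annotation sheet as TSV
#'
#' Columns: `sample_id`, `age`, `sex`, `group`, `dataset`, plus any result
#' columns appended by the pipeline (dnam_age, cell counts, age_accel, ieaa,
#' eeaa).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_sample_sheet
#' @param samples Tibble to write.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a paired intensity file set
#'
#' Two beta-matrix-shaped TSVs holding methylated (M) and unmethylated (U)
#' fluorescence intensities.
#'
#' @param m_path,u_path Paths to the M and U matrices.
#' @return An `intensity_pair`.
#' @export
read_intensities <- function(m_path, u_path) {
  M <- read_beta_matrix_raw(m_path)
  U <- read_beta_matrix_raw(u_path)
  if (!identical(dimnames(M), dimnames(U))) {
    abort("M and U files must share probe and sample ids")
  }
  structure(list(M = M, U = U), class = "intensity_pair")
}

read_beta_matrix_raw <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a probe blacklist (one probe id per line)
#'
#' @param path File path; lines starting with `#` are ignored.
#' @return Character vector of probe ids.
#' @export
read_blacklist <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Serialize / restore a clock model as TSV + header
#'
#' Writes `<stem>.tsv` (probe_id, coefficient, training_mean over the full
#' training universe; zero coefficients for non-model probes) and
#' `<stem>_header.tsv` (intercept, adult_age, alpha, lambda, seed, n_train).
#'
#' @param model A `clock_model`.
#' @param stem Path stem (without extension).
#' @return `write_clock_model()`: the stem, invisibly;
#'   `read_clock_model()`: a `clock_model`.
#' @export
write_clock_model <- function(model, stem) {
  stopifnot(inherits(model, "clock_model"))
  co <- setNames(rep(0, length(model$training_means)),
                 names(model$training_means))
  co[names(model$coef)] <- model$coef
  readr::write_tsv(tibble(probe_id = names(co), coefficient = unname(co),
                          training_mean = unname(model$training_means)),
                   paste0(stem, ".tsv"), progress = FALSE)
  readr::write_tsv(tibble(intercept = model$intercept,
                          adult_age = model$adult_age, alpha = model$alpha,
                          lambda = model$lambda, seed = model$seed,
                          n_train = model$n_train),
                   paste0(stem, "_header.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(stem) {
  tab <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE,
                         progress = FALSE)
  hd <- readr::read_tsv(paste0(stem, "_header.tsv"), show_col_types = FALSE,
                        progress = FALSE)
  co <- setNames(tab$coefficient, tab$probe_id)
  structure(list(coef = co[co != 0], intercept = hd$intercept,
                 adult_age = hd$adult_age,
                 training_means = setNames(tab$training_mean, tab$probe_id),
                 alpha = hd$alpha, lambda = hd$lambda, seed = hd$seed,
                 n_train = hd$n_train),
            class = "clock_model")
}

#' Serialize / restore a Klemera-Doubal calibration as TSV
#'
#' @param model A `kd_model`.
#' @param path File path.
#' @export
write_kd_model <- function(model, path) {
  readr::write_tsv(as_tibble(model), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kd_model
#' @export
read_kd_model <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(tab, class = c("kd_model", class(tab)))
}

#' Write a cell-type reference matrix as TSV
#'
#' @param ref Signature-probe-by-cell-type matrix.
#' @param path File path.
#' @export
write_reference_matrix <- function(ref, path) {
  df <- dplyr::bind_cols(tibble(probe_id = rownames(ref)), as_tibble(ref))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_reference_matrix
#' @export
read_reference_matrix <- function(path) {
  read_beta_matrix_raw(path)
}
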