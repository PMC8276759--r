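# Reading/writing the tabular inputs and the two preprocessing transforms
# defined for the pipeline: background normalization of miRNA arrays against
# non-human probes, and the pseudo-count log transform for sequencing counts.

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated file with one header row and one id column into an
#' expression table (tibble with a `sample` column followed by numeric feature
#' columns). Files may store samples in rows (default) or features in rows.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples-in-rows"` (default) or `"features-in-rows"`.
#' @return tibble with `sample` ids and one numeric column per feature.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples-in-rows",
                                                   "features-in-rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort("expression TSV needs an id column plus data columns.")
  ids <- as.character(raw[[1]])
  vals <- raw[-1]
  num <- lapply(names(vals), function(cn) {
    v <- suppressWarnings(as.numeric(vals[[cn]]))
    bad <- which(is.na(v) & !is.na(vals[[cn]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s.",
                    vals[[cn]][bad[1]], ids[bad[1]], cn, path))
    }
    v
  })
  m <- do.call(cbind, num)
  colnames(m) <- names(vals)
  rownames(m) <- ids
  if (orientation == "features-in-rows") m <- t(m)
  validate_expression(m, path)
  matrix_to_expr(m)
}

#' Write an expression table to TSV
#'
#' Values are written with 17 significant digits so that write-then-read
#' round-trips finite doubles bit-exactly.
#'
#' @param x expression table (tibble with `sample` column or matrix).
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  m <- expr_to_matrix(x)
  df <- data.frame(sample = rownames(m),
                   apply(m, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Expects columns `sample`, `time` (days, strictly positive) and `event`
#' (1 = deceased, 0 = censored).
#'
#' @param path path to a TSV file.
#' @return tibble with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  surv <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_double()
  ), progress = FALSE)
  if (!all(c("sample", "time", "event") %in% names(surv))) {
    abort("survival TSV must have columns sample, time, event.")
  }
  validate_survival(surv)
  as_tibble(surv[c("sample", "time", "event")])
}

#' Background-normalize a miRNA array against non-human probes
#'
#' For each sample, subtracts the median intensity of the non-human (spike-in
#' background) probes from every human probe, then drops the non-human probes.
#'
#' @param x expression table or matrix, samples by probes.
#' @param is_human logical vector, one entry per probe column (may be named by
#'   probe id, in which case it is matched by name).
#' @return expression table containing the human probes only.
#' @export
normalize_mirna_array <- function(x, is_human) {
  m <- expr_to_matrix(x, "mirna array")
  if (!is.null(names(is_human))) {
    miss <- setdiff(colnames(m), names(is_human))
    if (length(miss)) abort(sprintf("`is_human` has no entry for probe '%s'.", miss[1]))
    is_human <- is_human[colnames(m)]
  }
  if (length(is_human) != ncol(m)) {
    abort("`is_human` must have one entry per probe column.")
  }
  is_human <- as.logical(is_human)
  if (!any(!is_human)) abort("no non-human probes: background is undefined.")
  if (!any(is_human)) abort("no human probes left to normalize.")
  bg <- apply(m[, !is_human, drop = FALSE], 1, median)
  out <- m[, is_human, drop = FALSE] - bg
  matrix_to_expr(out)
}

#' Log-transform read counts with a pseudo count
#'
#' Elementwise natural log of `count + pseudo` (default pseudo count 0.5).
#' The log base only rescales coefficients downstream.
#'
#' @param x count table or matrix (non-negative).
#' @param pseudo positive pseudo count added before the log.
#' @return expression table of log counts.
#' @export
log_transform_counts <- function(x, pseudo = 0.5) {
  m <- expr_to_matrix(x, "counts")
  if (pseudo <= 0) abort("`pseudo` must be positive.")
  if (any(m < 0)) abort("counts must be non-negative.")
  matrix_to_expr(log(m + pseudo))
}
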