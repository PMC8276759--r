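# shared validation / coercion helpers (internal)

# expression tables are tibbles with a `sample` id column followed by numeric
# feature columns; matrices with rownames are accepted and coerced
expr_to_matrix <- function(x, arg = "expression") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(sprintf("`%s` matrix must have sample ids as rownames.", arg))
    }
    m <- x
  } else if (is.data.frame(x)) {
    idcol <- if ("sample" %in% names(x)) "sample" else names(x)[1]
    ids <- as.character(x[[idcol]])
    m <- as.matrix(x[setdiff(names(x), idcol)])
    rownames(m) <- ids
  } else {
    abort(sprintf("`%s` must be a data frame or a matrix.", arg))
  }
  storage.mode(m) <- "double"
  validate_expression(m, arg)
  m
}

validate_expression <- function(m, arg = "expression") {
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` contains missing/non-numeric values (first at sample '%s', feature '%s'); missing expression is not imputed.",
      arg, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated feature ids.", arg))
  }
  if (nrow(m) < 2 || ncol(m) < 1) {
    abort(sprintf("`%s` needs at least 2 samples and 1 feature.", arg))
  }
  invisible(m)
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m)
  out <- tibble(sample = rownames(m)) |> dplyr::bind_cols(out)
  out
}

validate_survival <- function(surv) {
  if (!is.data.frame(surv)) abort("`surv` must be a data frame.")
  need <- c("time", "event")
  if (!all(need %in% names(surv))) {
    abort("`surv` must have columns `time` and `event` (and optionally `sample`).")
  }
  if (anyNA(surv$time) || anyNA(surv$event)) abort("`surv` contains missing values.")
  if (any(surv$time <= 0)) abort("survival `time` must be strictly positive.")
  if (!all(surv$event %in% c(0, 1))) abort("`event` must be 0 (censored) or 1 (deceased).")
  invisible(surv)
}

require_events <- function(surv) {
  validate_survival(surv)
  if (sum(surv$event) < 1) abort("at least one observed event is required for fitting.")
  invisible(surv)
}

#' Align samples across expression tables and a survival table
#'
#' Intersects sample ids across the miRNA table, mRNA table and survival
#' table; samples missing from any input are dropped with a warning. All
#' outputs share one sample order.
#'
#' @param mirna,mrna expression tables (tibble with `sample` column, or matrix
#'   with sample rownames).
#' @param surv survival table with columns `sample`, `time`, `event`.
#' @return list with elements `mirna`, `mrna` (numeric matrices, samples in
#'   rows) and `surv` (tibble).
#' @export
align_samples <- function(mirna, mrna, surv) {
  zm <- expr_to_matrix(mirna, "mirna")
  xm <- expr_to_matrix(mrna, "mrna")
  validate_survival(surv)
  if (!"sample" %in% names(surv)) abort("`surv` needs a `sample` column for alignment.")
  ids <- intersect(intersect(rownames(zm), rownames(xm)), as.character(surv$sample))
  n_drop <- max(nrow(zm), nrow(xm), nrow(surv)) - length(ids)
  if (length(ids) < 2) abort("fewer than 2 samples shared across inputs.")
  if (n_drop > 0) {
    warn(sprintf("dropped %d sample(s) absent from at least one input.", n_drop))
  }
  surv <- surv[match(ids, as.character(surv$sample)), , drop = FALSE]
  list(mirna = zm[ids, , drop = FALSE], mrna = xm[ids, , drop = FALSE],
       surv = as_tibble(surv))
}

surv_cols <- function(surv) {
  validate_survival(surv)
  list(time = as.numeric(surv$time), event = as.numeric(surv$event))
}
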