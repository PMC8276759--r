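# Pair filtering: prune a sequence-predicted candidate miRNA -> target-mRNA
# list to pairs with significant negative expression correlation, either with
# the microarray one-sided correlation screen or with the two-step procedure
# for zero-inflated sequencing counts, and assemble integration sets.

validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame.")
  if (!all(c("miRNA", "gene") %in% names(pairs))) {
    abort("`pairs` must have columns `miRNA` and `gene`.")
  }
  if (any(!nzchar(pairs$miRNA)) || any(!nzchar(pairs$gene))) {
    abort("pair ids must be non-empty.")
  }
  if (anyDuplicated(paste(pairs$miRNA, pairs$gene, sep = "\r"))) {
    abort("`pairs` contains duplicate miRNA-gene pairs.")
  }
  invisible(pairs)
}

#' Read a candidate miRNA-target pair list from TSV
#'
#' Expects two columns, `miRNA` and `gene` (TargetScan-style predicted-target
#' flat files should be reduced to these two columns first).
#'
#' @param path path to a TSV file.
#' @return tibble with columns `miRNA`, `gene`.
#' @export
read_pair_list <- function(path) {
  pairs <- readr::read_tsv(path, col_types = readr::cols(
    miRNA = readr::col_character(), gene = readr::col_character()
  ), progress = FALSE)
  validate_pairs(pairs)
  as_tibble(pairs[c("miRNA", "gene")])
}

#' Convert a TargetScan predicted-targets flat file to a pair list
#'
#' Keeps only the miRNA-family and gene-symbol columns of a TargetScan-style
#' tab-separated prediction file and drops duplicate pairs.
#'
#' @param path path to the flat file.
#' @param mirna_col,gene_col column names holding the miRNA family and the
#'   gene symbol.
#' @return tibble with columns `miRNA`, `gene`.
#' @export
read_targetscan <- function(path, mirna_col = "miR Family",
                            gene_col = "Gene Symbol") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c(mirna_col, gene_col) %in% names(raw))) {
    abort(sprintf("columns '%s' and '%s' not found in %s.",
                  mirna_col, gene_col, path))
  }
  pairs <- tibble(miRNA = raw[[mirna_col]], gene = raw[[gene_col]]) |>
    distinct()
  validate_pairs(pairs)
  pairs
}

#' One-sided test for negative correlation
#'
#' Pearson correlation `r` between a target mRNA and its candidate regulator
#' miRNA, with the lower-tail p-value of `t = r * sqrt(n-2) / sqrt(1-r^2)`
#' under a t distribution with `n - 2` degrees of freedom, testing
#' H1: rho < 0.
#'
#' @param x numeric vector of mRNA expression.
#' @param z numeric vector of miRNA expression, same length.
#' @return one-row tibble with columns `r` and `p`.
#' @export
neg_correlation_test <- function(x, z) {
  n <- length(x)
  if (length(z) != n) abort("`x` and `z` must have the same length.")
  if (n < 3) abort("need at least 3 paired observations.")
  if (sd(x) == 0 || sd(z) == 0) {
    abort("zero variance: correlation is undefined.")
  }
  r <- cor(x, z)
  p <- if (r <= -1) 0 else if (r >= 1) 1 else {
    pt(r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2)
  }
  tibble(r = r, p = p)
}

# shared loop over candidate pairs; test_fun(x, z) -> list/tibble(r, p) or NULL
# when the pair cannot be tested (reason recorded in the log)
screen_pairs <- function(pairs, zm, xm, test_fun) {
  validate_pairs(pairs)
  known <- pairs$miRNA %in% colnames(zm) & pairs$gene %in% colnames(xm)
  n_skip <- sum(!known)
  if (n_skip > 0) {
    warn(sprintf("%d pair(s) reference unknown feature ids; skipped.", n_skip))
  }
  kept <- pairs[known, , drop = FALSE]
  res <- purrr::pmap(list(kept$miRNA, kept$gene), function(mi, ge) {
    test_fun(xm[, ge], zm[, mi])
  })
  log <- tibble(
    miRNA = kept$miRNA, gene = kept$gene,
    r = map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$r),
    p = map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$p),
    reason = purrr::map_chr(res, ~ if (is.null(.x)) "degenerate-split" else
      attr(.x, "reason") %||% "tested")
  )
  attr(log, "n_skipped") <- n_skip
  log
}

finish_filter <- function(log, pairs, alpha, n_skipped) {
  log <- log |> mutate(retained = !is.na(.data$p) & .data$p < alpha)
  sets <- log |> filter(.data$retained) |> select("miRNA", "gene", "r", "p")
  structure(sets,
            class = c("mimi_sets", class(sets)),
            filter_log = log |>
              mutate(decision = ifelse(.data$retained, "retained", "dropped")) |>
              select("miRNA", "gene", "r", "p", "reason", "decision"),
            n_skipped = n_skipped, alpha = alpha)
}

#' Filter candidate pairs by negative correlation (microarray screen)
#'
#' Retains the candidate pairs whose one-sided negative-correlation test has
#' `p < alpha`; miRNAs left with no surviving target are excluded from the
#' model entirely. Pairs are screened marginally, with no multiplicity
#' correction.
#'
#' @param pairs candidate pair tibble (`miRNA`, `gene`).
#' @param mirna,mrna expression tables sharing sample order (use
#'   [align_samples()] first if needed).
#' @param alpha one-sided significance level, default 0.05.
#' @return tibble of retained pairs (`miRNA`, `gene`, `r`, `p`) with the full
#'   screen recorded in `attr(, "filter_log")`.
#' @export
filter_pairs_microarray <- function(pairs, mirna, mrna, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  zm <- expr_to_matrix(mirna, "mirna")
  xm <- expr_to_matrix(mrna, "mrna")
  if (nrow(zm) != nrow(xm)) abort("mirna and mrna must share samples; see align_samples().")
  log <- screen_pairs(pairs, zm, xm, function(x, z) {
    if (sd(x) == 0 || sd(z) == 0) return(NULL)
    neg_correlation_test(x, z)
  })
  finish_filter(log, pairs, alpha, attr(log, "n_skipped"))
}

#' Filter candidate pairs for zero-inflated sequencing data
#'
#' Two-step screen for count data with many zero miRNA reads. Step 1: Welch
#' one-sided t-test that mean mRNA expression is larger in samples with zero
#' miRNA counts than in samples with non-zero counts. Step 2: the one-sided
#' negative-correlation test restricted to the non-zero-count samples. A pair
#' is retained only if both steps have `p` below their levels.
#'
#' @param pairs candidate pair tibble.
#' @param mirna_counts raw (pre-log) miRNA count table, so zeros are
#'   identifiable.
#' @param mrna mRNA expression table sharing sample order.
#' @param alpha level for both steps (step 2 level can be overridden with
#'   `alpha2`).
#' @param alpha2 level for the correlation step, default `alpha`.
#' @return tibble of retained pairs, as [filter_pairs_microarray()].
#' @export
filter_pairs_sequencing <- function(pairs, mirna_counts, mrna, alpha = 0.05,
                                    alpha2 = alpha) {
  stopifnot(alpha > 0, alpha < 1, alpha2 > 0, alpha2 < 1)
  zm <- expr_to_matrix(mirna_counts, "mirna_counts")
  xm <- expr_to_matrix(mrna, "mrna")
  if (nrow(zm) != nrow(xm)) abort("inputs must share samples; see align_samples().")
  log <- screen_pairs(pairs, zm, xm, function(x, z) {
    zero <- z == 0
    if (sum(zero) < 2 || sum(!zero) < 2) return(NULL)
    if (sd(x[zero]) == 0 && sd(x[!zero]) == 0) return(NULL)
    t1 <- tryCatch(
      stats::t.test(x[zero], x[!zero], alternative = "greater")$p.value,
      error = function(e) NA_real_)
    if (is.na(t1) || t1 >= alpha) {
      out <- tibble(r = NA_real_, p = 1)
      attr(out, "reason") <- "step1-nonsig"
      return(out)
    }
    if (sd(x[!zero]) == 0 || sd(z[!zero]) == 0) return(NULL)
    neg_correlation_test(x[!zero], z[!zero])
  })
  finish_filter(log, pairs, alpha2, attr(log, "n_skipped"))
}

#' Summarize integration sets
#'
#' One row per retained miRNA with its target count and target list.
#'
#' @param sets retained pair tibble from a `filter_pairs_*` function (any
#'   tibble with `miRNA` and `gene` columns works).
#' @return tibble with columns `miRNA`, `n_mRNAs`, `genes`.
#' @export
integration_sets <- function(sets) {
  validate_pairs(sets)
  sets |>
    group_by(.data$miRNA) |>
    summarise(n_mRNAs = dplyr::n(), genes = paste(.data$gene, collapse = ","),
              .groups = "drop")
}

#' Write integration sets to TSV
#'
#' @param sets retained pair tibble.
#' @param path output path; the per-pair filter log, when present, is written
#'   alongside with suffix `.log.tsv`.
#' @export
write_integration_sets <- function(sets, path) {
  readr::write_tsv(integration_sets(sets), path, progress = FALSE)
  log <- attr(sets, "filter_log")
  if (!is.null(log)) {
    readr::write_tsv(log, paste0(sub("\\.tsv$", "", path), ".log.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
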