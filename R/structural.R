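# Structured-component model pieces: per-pair inhibition coefficients, the
# miRNA-adjusted mRNA expression they imply, and the latent component scores
# that summarize each integration set.
#
# The model, per integration set j (one miRNA z_j and its G_j retained
# targets x_jk):
#   adjusted expression   xhat_ijk = x_ijk - gamma_jk * z_ij
#   latent component      f_ij     = gamma_j0 * z_ij + sum_k xhat_ijk * w_jk
# The component enters a Cox proportional-hazards model with one coefficient
# beta_j per set. gamma_jk is estimated once, by per-pair univariate least
# squares on mean-centered expression, and held fixed during model fitting;
# the least-squares residual is exactly uncorrelated with the miRNA.

#' Estimate per-pair miRNA inhibition coefficients
#'
#' For every retained pair, the slope of the simple least-squares regression
#' of the centered target mRNA on the centered miRNA.
#'
#' @param mirna,mrna expression tables sharing sample order.
#' @param sets retained pair tibble (`miRNA`, `gene`).
#' @return tibble with columns `miRNA`, `gene`, `gamma`.
#' @export
estimate_inhibition_coefficients <- function(mirna, mrna, sets) {
  zm <- expr_to_matrix(mirna, "mirna")
  xm <- expr_to_matrix(mrna, "mrna")
  validate_pairs(sets)
  if (nrow(zm) < 3) abort("need at least 3 samples to estimate inhibition slopes.")
  zc <- scale(zm, scale = FALSE)
  xc <- scale(xm, scale = FALSE)
  vz <- apply(zc, 2, function(v) sum(v^2))
  if (any(vz[unique(sets$miRNA)] == 0)) {
    abort("zero-variance miRNA: inhibition slope is undefined.")
  }
  gamma <- purrr::map2_dbl(sets$miRNA, sets$gene, function(mi, ge) {
    sum(xc[, ge] * zc[, mi]) / vz[[mi]]
  })
  tibble(miRNA = sets$miRNA, gene = sets$gene, gamma = gamma)
}

#' Adjust mRNA expression for miRNA inhibition
#'
#' Computes `xhat_ijk = x_ijk - gamma_jk * z_ij` on centered expression, one
#' adjusted column per retained pair (a gene targeted by several miRNAs gets
#' one column per pair).
#'
#' @param mrna,mirna expression tables sharing sample order.
#' @param adj inhibition coefficients from
#'   [estimate_inhibition_coefficients()].
#' @return tibble with a `sample` column and one column per pair, named
#'   `"<miRNA>:<gene>"`.
#' @export
adjust_mrna <- function(mrna, mirna, adj) {
  zm <- expr_to_matrix(mirna, "mirna")
  xm <- expr_to_matrix(mrna, "mrna")
  if (!all(c("miRNA", "gene", "gamma") %in% names(adj))) {
    abort("`adj` must have columns miRNA, gene, gamma.")
  }
  if (anyNA(adj$gamma)) abort("missing inhibition coefficient.")
  zc <- scale(zm, scale = FALSE)
  xc <- scale(xm, scale = FALSE)
  xhat <- mapply(function(mi, ge, g) xc[, ge] - g * zc[, mi],
                 adj$miRNA, adj$gene, adj$gamma)
  xhat <- matrix(xhat, nrow = nrow(zm))
  colnames(xhat) <- paste(adj$miRNA, adj$gene, sep = ":")
  rownames(xhat) <- rownames(zm)
  matrix_to_expr(xhat)
}

#' Compute latent integration components
#'
#' `f_ij = gamma_j0 * z_ij + sum_k xhat_ijk * w_jk`, each column then rescaled
#' to unit sample variance (the reporting convention for component scores).
#'
#' @param mirna miRNA expression table.
#' @param adjusted adjusted expression from [adjust_mrna()].
#' @param gamma0 tibble (`miRNA`, `gamma0`): direct miRNA weights.
#' @param w tibble (`miRNA`, `gene`, `w`): per-pair mRNA weights.
#' @return tibble with a `sample` column and one standardized component
#'   column per miRNA.
#' @export
compute_latents <- function(mirna, adjusted, gamma0, w) {
  zm <- expr_to_matrix(mirna, "mirna")
  am <- expr_to_matrix(adjusted, "adjusted")
  zc <- scale(zm, scale = FALSE)
  f <- vapply(seq_len(nrow(gamma0)), function(j) {
    mi <- gamma0$miRNA[j]
    fj <- gamma0$gamma0[j] * zc[, mi]
    wj <- w[w$miRNA == mi, , drop = FALSE]
    if (nrow(wj)) {
      cols <- paste(wj$miRNA, wj$gene, sep = ":")
      fj <- fj + as.vector(am[, cols, drop = FALSE] %*% wj$w)
    }
    fj
  }, numeric(nrow(zm)))
  colnames(f) <- gamma0$miRNA
  rownames(f) <- rownames(zm)
  sds <- apply(f, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("degenerate component (zero variance): '%s'.",
                  colnames(f)[which(sds == 0)[1]]))
  }
  matrix_to_expr(sweep(f, 2, sds, "/"))
}

# internal: assemble the aligned numeric pieces the fitters consume
build_model_frame <- function(mirna, mrna, sets, surv) {
  al <- align_samples(mirna, mrna, surv)
  validate_pairs(sets)
  mirnas <- unique(sets$miRNA)
  missing_z <- setdiff(mirnas, colnames(al$mirna))
  missing_x <- setdiff(sets$gene, colnames(al$mrna))
  if (length(missing_z)) abort(sprintf("miRNA '%s' not in expression table.", missing_z[1]))
  if (length(missing_x)) abort(sprintf("gene '%s' not in expression table.", missing_x[1]))
  adj <- estimate_inhibition_coefficients(al$mirna, al$mrna, sets)
  zc <- scale(al$mirna[, mirnas, drop = FALSE], scale = FALSE)
  xh <- expr_to_matrix(adjust_mrna(al$mrna, al$mirna, adj), "adjusted")
  list(
    Z = zc, Xh = xh,
    setidx = match(sets$miRNA, mirnas) - 1L,
    mirnas = mirnas, pairs = sets[c("miRNA", "gene")], adj = adj,
    surv = al$surv, samples = rownames(zc)
  )
}
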