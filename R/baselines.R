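# miRNA-only comparison methods: per-miRNA univariate Cox fits with Wald
# p-values, and one joint penalized Cox fit of all miRNAs with a cross-
# validated tuning parameter. Selection penalties (lasso, Elastic-Net) call a
# miRNA significant when its coefficient is nonzero; ridge never produces
# exact zeros, so its significance comes from a permutation p-value on the
# joint refit.

#' Single-miRNA Cox baseline
#'
#' One unpenalized univariate Cox fit per miRNA, with the Wald p-value from
#' the observed-information standard error. Monotone (separating)
#' likelihoods yield `p = NA` with `flag = "separation"`.
#'
#' @param mirna miRNA expression table.
#' @param surv survival tibble (`time`, `event`; aligned samples).
#' @return tibble with columns `miRNA`, `delta`, `se`, `p`, `flag`.
#' @export
single_mirna_cox <- function(mirna, surv) {
  zm <- expr_to_matrix(mirna, "mirna")
  require_events(surv)
  sc <- surv_cols(surv)
  if (any(apply(zm, 2, sd) == 0)) abort("zero-variance miRNA covariate.")
  rows <- lapply(colnames(zm), function(mi) {
    x <- matrix(zm[, mi] - mean(zm[, mi]), ncol = 1)
    fit <- cpp_cox_fit(x, sc$time, sc$event, 0, 0, 0, 1e-9, 200)
    if (fit$separation) {
      return(tibble(miRNA = mi, delta = as.numeric(fit$coef), se = NA_real_,
                    p = NA_real_, flag = "separation"))
    }
    info <- cpp_cox_info(x, as.numeric(fit$coef), sc$time, sc$event)
    se <- sqrt(1 / info[1, 1])
    zstat <- as.numeric(fit$coef) / se
    tibble(miRNA = mi, delta = as.numeric(fit$coef), se = se,
           p = 2 * stats::pnorm(-abs(zstat)), flag = "ok")
  })
  bind_rows(rows)
}

#' Joint penalized Cox baseline over all miRNAs
#'
#' Fits all miRNAs together in one penalized Cox model, with the tuning
#' parameter selected by K-fold cross-validated partial-likelihood deviance
#' (penalty scaled as `lambda * P(delta)`, without the structured model's
#' leading half). For `"lasso"`/`"en"`, a miRNA is significant when its
#' coefficient is nonzero at the selected penalty; for `"ridge"`, permutation
#' p-values of the refitted coefficients are reported (`B` refits of the
#' joint model with survival rows permuted).
#'
#' @param mirna miRNA expression table.
#' @param surv survival tibble.
#' @param penalty_kind `"ridge"`, `"lasso"` or `"en"`.
#' @param k cross-validation folds (>= 2).
#' @param seed seed for folds and permutations.
#' @param B permutations for the ridge significance path.
#' @param grid optional lambda grid.
#' @param alpha level for the ridge permutation call.
#' @return tibble with columns `miRNA`, `delta`, `p` (ridge only),
#'   `significant`, plus the selected lambda in `attr(, "lambda")`.
#' @export
multi_mirna_penalized_cox <- function(mirna, surv, penalty_kind = "lasso",
                                      k = 10, seed = NULL, B = 200,
                                      grid = NULL, alpha = 0.05) {
  zm <- expr_to_matrix(mirna, "mirna")
  zc <- scale(zm, scale = FALSE)
  require_events(surv)
  sc <- surv_cols(surv)
  lam <- cv_select_lambda(zc, surv, penalty_kind, grid = grid, k = k,
                          seed = seed, half = FALSE)
  pen <- penalty_spec(penalty_kind, as.numeric(lam), half = FALSE)
  fit <- fit_penalized_cox(zc, surv, pen)
  out <- tibble(miRNA = colnames(zm), delta = as.numeric(fit$coef))
  if (penalty_kind %in% c("lasso", "en")) {
    out$p <- NA_real_
    out$significant <- out$delta != 0
  } else {
    if (!is.null(seed)) set.seed(seed + 1L)
    perm <- replicate(B, {
      idx <- sample.int(nrow(zc))
      pf <- fit_penalized_cox(zc, surv[idx, ], pen)
      abs(pf$coef)
    })
    out$p <- vapply(seq_len(nrow(out)), function(j) {
      (1 + sum(perm[j, ] >= abs(out$delta[j]))) / (B + 1)
    }, numeric(1))
    out$significant <- out$p < alpha
  }
  attr(out, "lambda") <- as.numeric(lam)
  attr(out, "fit") <- fit
  out
}
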