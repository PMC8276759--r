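# Penalized Cox proportional-hazards engine: Breslow partial likelihood,
# ridge (Newton-Raphson) and lasso/Elastic-Net (IRLS + coordinate descent
# with soft-thresholding) maximization, and cross-validated penalty
# selection. Used by the structured-model fitter and by the miRNA-only
# baselines.

#' Penalty specification
#'
#' The penalty on a coefficient vector b is `0.5 * lambda * P(b)` with
#' `P(b) = sum(b^2)` (ridge), `sum(|b|)` (lasso) or
#' `0.5 * sum(b^2) + sum(|b|)` (Elastic-Net with fixed 1:1 composition and a
#' single tuning parameter). `kind = "none"` disables the penalty. The
#' miRNA-only baselines use the same functional forms scaled by `lambda`
#' without the leading half (`half = FALSE`).
#'
#' @param kind one of `"ridge"`, `"lasso"`, `"en"`, `"none"`.
#' @param lambda non-negative tuning parameter (ignored for `"none"`).
#' @param half logical; `TRUE` (default) applies the leading factor 1/2 used
#'   in the structured model's objective.
#' @return an object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("ridge", "lasso", "en", "none"), lambda = 1,
                         half = TRUE) {
  kind <- match.arg(kind)
  if (lambda < 0) abort("`lambda` must be non-negative.")
  if (kind == "none") lambda <- 0
  structure(list(kind = kind, lambda = lambda, half = half),
            class = "penalty_spec")
}

# map a penalty_spec to the engine's (l1, l2) scale, where the engine
# objective is loglik - l1*||b||_1 - 0.5*l2*||b||^2
pen_l1l2 <- function(pen) {
  stopifnot(inherits(pen, "penalty_spec"))
  h <- if (pen$half) 0.5 else 1
  la <- pen$lambda
  switch(pen$kind,
    none  = c(l1 = 0, l2 = 0),
    ridge = c(l1 = 0, l2 = 2 * h * la),
    lasso = c(l1 = h * la, l2 = 0),
    en    = c(l1 = h * la, l2 = h * la)
  )
}

#' Cox log partial likelihood
#'
#' Breslow-form log partial likelihood with risk sets
#' `{q : y_q >= y_i}` over the event times.
#'
#' @param design numeric matrix or data frame of covariates (samples in rows).
#' @param coef coefficient vector.
#' @param surv survival tibble with columns `time` and `event` (>= 1 event).
#' @return the log partial likelihood (scalar).
#' @export
partial_loglik <- function(design, coef, surv) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  require_events(surv)
  if (length(coef) != ncol(X)) abort("`coef` length must match design columns.")
  sc <- surv_cols(surv)
  cpp_cox_loglik(X, as.numeric(coef), sc$time, sc$event)
}

#' Fit a penalized Cox proportional-hazards model
#'
#' Maximizes the Breslow log partial likelihood minus the penalty of a
#' [penalty_spec()]: Newton-Raphson with step halving for smooth penalties,
#' IRLS with cyclic coordinate descent and soft-thresholding for penalties
#' with an l1 part. Non-convergence is reported through the `converged` flag
#' (not an error); monotone (separating) likelihoods are flagged when the
#' coefficient norm exceeds 1e3.
#'
#' @param design covariate matrix or data frame.
#' @param surv survival tibble (`time`, `event`).
#' @param penalty a [penalty_spec()].
#' @param init optional initial coefficient vector (default zeros).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `cox_pen_fit` with elements `coef`, `loglik`,
#'   `objective`, `iterations`, `converged`, `separation`.
#' @export
fit_penalized_cox <- function(design, surv, penalty = penalty_spec("ridge", 1),
                              init = NULL, tol = 1e-8, max_iter = 200) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) abort("design must be finite.")
  require_events(surv)
  sc <- surv_cols(surv)
  if (is.null(init)) init <- rep(0, ncol(X))
  ll <- pen_l1l2(penalty)
  r <- cpp_cox_fit(X, sc$time, sc$event, ll[["l1"]], ll[["l2"]],
                   as.numeric(init), tol, as.integer(max_iter))
  coef <- as.numeric(r$coef)
  names(coef) <- colnames(X)
  structure(list(coef = coef, loglik = r$loglik, objective = r$objective,
                 penalty = penalty, iterations = r$iterations,
                 converged = r$converged, separation = r$separation,
                 nobs = nrow(X), nevent = sum(sc$event)),
            class = "cox_pen_fit")
}

#' @export
print.cox_pen_fit <- function(x, ...) {
  cat(sprintf("Penalized Cox fit (%s, lambda = %g): %d coefficients, %s\n",
              x$penalty$kind, x$penalty$lambda, length(x$coef),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  log partial likelihood %.4f (penalized %.4f)\n",
              x$loglik, x$objective))
  invisible(x)
}

#' Lambda grid anchored at the all-zero lasso bound
#'
#' 20 log-spaced values from `lambda_max` down to `lambda_max * 1e-3`, where
#' `lambda_max` is the smallest penalty for which the lasso solution is
#' identically zero (the sup-norm of the null-model score, mapped to the
#' user's lambda scale).
#'
#' @param design covariate matrix.
#' @param surv survival tibble.
#' @param n number of grid points.
#' @param min_ratio ratio of the smallest to the largest grid value.
#' @param half penalty scale convention, see [penalty_spec()].
#' @return decreasing numeric vector of lambda values.
#' @export
lambda_grid <- function(design, surv, n = 20, min_ratio = 1e-3, half = TRUE) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  require_events(surv)
  sc <- surv_cols(surv)
  l1max <- cpp_cox_lambda_max(X, sc$time, sc$event)
  lmax <- l1max / if (half) 0.5 else 1
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n))
}

# event-stratified fold assignment (every fold keeps events)
stratified_folds <- function(event, k) {
  fold <- integer(length(event))
  for (g in c(0, 1)) {
    idx <- which(event == g)
    if (length(idx)) fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Select lambda by cross-validated partial-likelihood deviance
#'
#' K-fold cross-validation with event-stratified folds. The criterion is the
#' Verweij-van Houwelingen cross-validated partial likelihood: for each fold,
#' the full-data log partial likelihood at the training-fold coefficients
#' minus the training-fold log partial likelihood; the selected lambda
#' maximizes the summed criterion (equivalently minimizes the deviance).
#' Ties prefer the larger (more penalized) lambda.
#'
#' @param design covariate matrix.
#' @param surv survival tibble.
#' @param penalty_kind `"ridge"`, `"lasso"` or `"en"`.
#' @param grid lambda values (default [lambda_grid()]).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param half penalty scale convention, see [penalty_spec()].
#' @return the selected lambda, with the cv table in `attr(, "cv")`.
#' @export
cv_select_lambda <- function(design, surv, penalty_kind = "ridge", grid = NULL,
                             k = 10, seed = NULL, half = TRUE) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  require_events(surv)
  if (k < 2) abort("`k` must be at least 2.")
  if (is.null(grid)) grid <- lambda_grid(X, surv, half = half)
  if (!length(grid)) abort("empty lambda grid.")
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(surv$event, k)
  cvl <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(surv$event[tr]) == 0) next
    for (i in seq_along(grid)) {
      fit <- fit_penalized_cox(X[tr, , drop = FALSE], surv[tr, ],
                               penalty_spec(penalty_kind, grid[i], half = half))
      cvl[i, f] <- partial_loglik(X, fit$coef, surv) -
        partial_loglik(X[tr, , drop = FALSE], fit$coef, surv[tr, ])
    }
  }
  crit <- rowSums(cvl, na.rm = TRUE)
  best <- which(crit >= max(crit) - 1e-12)
  sel <- grid[best[which.max(grid[best])]]
  attr(sel, "cv") <- tibble(lambda = grid, cv_loglik = crit,
                            deviance = -2 * crit)
  sel
}
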