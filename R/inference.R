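# Permutation inference for the set effects beta_j: per-penalty permutation
# p-values, the maxT combination across penalties (common permutations), and
# Benjamini-Hochberg q-values. Survival rows (time, event) are permuted
# jointly against the expression rows, the whole model is refitted per
# permutation at fixed penalties, and p-values use the add-one estimator
# p = (1 + #{b : |beta_b| >= |beta_obs|}) / (B + 1). The observed statistic is
# computed by the same engine settings as the permuted ones, preserving
# exchangeability.

# shared permutation engine. pens: list of (penalty_w, penalty_b) pairs.
# Returns list(obs = J x K matrix, perm = B x J x K array)
perm_engine <- function(bundle, pens, B, seed = NULL,
                        control = perm_control()) {
  require_events(bundle$surv)
  if (B < 1) abort("`B` must be at least 1.")
  budget <- getOption("mimisurv.perm_budget", 5e6)
  work <- (B + 1) * length(pens) * ncol(bundle$Z)
  if (work > budget) {
    warn(sprintf(
      "permutation workload (%g set refits) exceeds the configured budget (%g); this may take very long.",
      work, budget))
  }
  sc <- surv_cols(bundle$surv)
  n <- length(sc$time)
  if (!is.null(seed)) set.seed(seed)
  perms <- cbind(seq_len(n),
                 vapply(seq_len(B), function(b) sample.int(n), integer(n))) - 1L
  penmat <- do.call(rbind, lapply(pens, function(p) {
    lw <- pen_l1l2(p[[1]])
    lb <- pen_l1l2(p[[2]])
    c(lw[["l1"]], lw[["l2"]], lb[["l1"]], lb[["l2"]])
  }))
  cube <- cpp_perm_betas(bundle$Z, bundle$Xh, bundle$setidx, sc$time, sc$event,
                         perms, penmat, control$tol,
                         as.integer(control$max_iter), control$inner_iter)
  K <- length(pens)
  J <- ncol(bundle$Z)
  obs <- matrix(NA_real_, K, J)                       # K x J
  for (k in seq_len(K)) obs[k, ] <- cube[1, , k]
  list(obs = obs, perm = cube[-1, , , drop = FALSE], mirnas = bundle$mirnas)
}

add_one_p <- function(obs, perm) {
  # obs scalar, perm vector of permuted statistics
  (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1)
}

#' Permutation p-values for the set effects
#'
#' Jointly permutes the survival rows against the expression rows `B` times,
#' refits the structured model at fixed penalties for each permutation, and
#' returns add-one permutation p-values for each integration set's |beta|.
#'
#' @inheritParams fit_mimi_surv
#' @param B number of permutations.
#' @param seed integer seed (permutations are reproducible bit-exactly).
#' @param control engine settings; defaults to throughput-oriented settings
#'   applied identically to observed and permuted fits.
#' @return tibble with columns `miRNA`, `beta`, `p`.
#' @export
permutation_pvalues <- function(mirna, mrna, sets, surv,
                                penalty_w = penalty_spec("ridge", 1),
                                penalty_b = penalty_w, B = 1000, seed = NULL,
                                control = perm_control()) {
  bundle <- build_model_frame(mirna, mrna, sets, surv)
  eng <- perm_engine(bundle, list(list(penalty_w, penalty_b)), B, seed, control)
  tibble(
    miRNA = eng$mirnas,
    beta = as.numeric(eng$obs[1, ]),
    p = vapply(seq_along(eng$mirnas), function(j) {
      add_one_p(eng$obs[1, j], eng$perm[, j, 1])
    }, numeric(1))
  )
}

#' maxT permutation p-values across several penalties
#'
#' The statistic for set j is `T_j = max over penalties |beta_j|`; the same
#' permutations are reused for every penalty (common random numbers), and the
#' add-one estimator is applied against the permuted T distribution.
#'
#' @inheritParams permutation_pvalues
#' @param penalties list of `(penalty_w, penalty_b)` pairs, or a character
#'   vector of penalty kinds (each then uses `lambda` for both roles).
#' @param lambda default lambda when `penalties` is a character vector.
#' @return tibble with columns `miRNA`, `T` (observed maxT) and `p`.
#' @export
maxT_pvalues <- function(mirna, mrna, sets, surv,
                         penalties = c("ridge", "lasso", "en"), lambda = 1,
                         B = 1000, seed = NULL, control = perm_control()) {
  pens <- as_penalty_pairs(penalties, lambda)
  bundle <- build_model_frame(mirna, mrna, sets, surv)
  eng <- perm_engine(bundle, pens, B, seed, control)
  tobs <- apply(abs(eng$obs), 2, max)                 # J
  tperm <- apply(abs(eng$perm), c(1, 2), max)         # B x J
  tibble(
    miRNA = eng$mirnas,
    T = tobs,
    p = vapply(seq_along(eng$mirnas), function(j) {
      add_one_p(tobs[j], tperm[, j])
    }, numeric(1))
  )
}

as_penalty_pairs <- function(penalties, lambda = 1) {
  if (is.character(penalties)) {
    lapply(penalties, function(k) {
      p <- penalty_spec(k, lambda)
      list(p, p)
    })
  } else {
    penalties
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j`, mapped
#' back to the input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Test integration sets against survival with permutation and maxT p-values
#'
#' Runs the whole inferential pipeline on one dataset: fits the structured
#' model under each requested penalty, computes permutation p-values per
#' penalty (shared permutations), optionally the maxT combination, and
#' Benjamini-Hochberg q-values within each penalty.
#'
#' @inheritParams fit_mimi_surv
#' @param penalties character vector of penalty kinds to fit.
#' @param lambda penalty strength used for both roles of each penalty.
#' @param maxT also report the maxT combination across the penalties.
#' @param B permutations.
#' @param q_threshold FDR threshold used by the `significant` flag.
#' @param seed integer seed.
#' @param control engine settings.
#' @return object of class `mimi_surv_test`; `tidy()` returns one row per
#'   (miRNA, penalty) with columns `miRNA`, `n_mRNAs`, `significant_mRNAs`,
#'   `beta`, `p`, `q`, `penalty`, `significant`.
#' @export
mimi_surv_test <- function(mirna, mrna, sets, surv,
                           penalties = c("ridge", "lasso", "en"), lambda = 1,
                           maxT = TRUE, B = 1000, q_threshold = 0.1,
                           seed = NULL, control = perm_control()) {
  bundle <- build_model_frame(mirna, mrna, sets, surv)
  pens <- as_penalty_pairs(penalties, lambda)
  eng <- perm_engine(bundle, pens, B, seed, control)
  J <- length(eng$mirnas)
  n_m <- bundle$pairs |> count(.data$miRNA, name = "n_mRNAs")
  rows <- list()
  for (k in seq_along(penalties)) {
    p <- vapply(seq_len(J), function(j) add_one_p(eng$obs[k, j], eng$perm[, j, k]),
                numeric(1))
    # significant mRNAs = pairs with nonzero inner weight under selection
    # penalties; undefined (NA) for ridge, which never zeroes weights
    sig_m <- rep(NA_character_, J)
    nz <- sig_w_labels(bundle, eng$mirnas, penalties[k],
                       pens[[k]], eng$obs[k, ], surv_cols(bundle$surv), control)
    if (!is.null(nz)) sig_m <- nz
    rows[[k]] <- tibble(miRNA = eng$mirnas, beta = as.numeric(eng$obs[k, ]),
                        p = p, penalty = penalties[k],
                        significant_mRNAs = sig_m)
  }
  if (maxT) {
    tobs <- apply(abs(eng$obs), 2, max)
    tperm <- apply(abs(eng$perm), c(1, 2), max)
    # signed maxT estimate: the beta whose magnitude attains the max
    kstar <- apply(abs(eng$obs), 2, which.max)
    bmax <- vapply(seq_len(J), function(j) eng$obs[kstar[j], j], numeric(1))
    rows[["maxT"]] <- tibble(
      miRNA = eng$mirnas, beta = bmax,
      p = vapply(seq_len(J), function(j) add_one_p(tobs[j], tperm[, j]),
                 numeric(1)),
      penalty = "maxT", significant_mRNAs = NA_character_)
  }
  res <- bind_rows(rows) |>
    group_by(.data$penalty) |>
    mutate(q = bh_qvalues(.data$p)) |>
    ungroup() |>
    left_join(n_m, by = "miRNA") |>
    mutate(significant = .data$q < q_threshold) |>
    select("miRNA", "n_mRNAs", "significant_mRNAs", "beta", "p", "q",
           "penalty", "significant")
  structure(list(results = res, B = B, q_threshold = q_threshold,
                 penalties = penalties, seed = seed,
                 mirnas = eng$mirnas),
            class = "mimi_surv_test")
}

# names of pairs with nonzero w under a selection penalty, comma-joined
sig_w_labels <- function(bundle, mirnas, kind, pen_pair, beta_obs, sc,
                         control) {
  if (!kind %in% c("lasso", "en")) return(NULL)
  fit <- fit_mimi_surv_bundle(bundle, pen_pair[[1]], pen_pair[[2]], control)
  vapply(mirnas, function(mi) {
    wj <- fit$w[fit$w$miRNA == mi & fit$w$w != 0, , drop = FALSE]
    if (!nrow(wj)) NA_character_ else paste(wj$gene, collapse = ",")
  }, character(1))
}

#' @export
print.mimi_surv_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test of %d integration sets (B = %d, q threshold %g)\n",
    length(x$mirnas), x$B, x$q_threshold))
  print(x$results, ...)
  invisible(x)
}

#' Write a results table to TSV
#'
#' @param x a `mimi_surv_test` object or its tidied tibble.
#' @param path output path.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "mimi_surv_test")) x <- x$results
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
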