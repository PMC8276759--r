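# Simulation engine: synthetic expression with planted negatively correlated
# miRNA-target pairs (optionally zero-inflated miRNA values), survival times
# generated from the structured-component hazard
#
#   h(y | x, z) = h0(y) * exp( sum_{causal j} beta * (gamma * z_j
#                                 + w * sum_k xhat_jk) ),
#
# with a constant baseline hazard h0 = 1 (exponential survival; proportional-
# hazards inference is invariant to this choice) and independent exponential
# censoring whose rate is calibrated numerically so the expected censoring
# fraction equals the target, plus type-I-error and power estimation by
# permutation testing over replicated datasets.

#' Simulation configuration
#'
#' Bundles the study conditions: sample size and expression dimensions, the
#' generative effect sizes (`beta` per causal set, `gamma` for the direct
#' miRNA effect, `w` shared by all target mRNAs of a causal set), the target
#' censoring fraction, the nominal level, replicate and permutation counts,
#' the zero-inflation proportion of the miRNA values, and the fixed penalty
#' strengths used by the testing protocol.
#'
#' @param n_samples samples per replicate.
#' @param n_mirna number of miRNAs (= integration sets).
#' @param targets_per_mirna planted targets per miRNA.
#' @param n_causal number of causal sets used by [estimate_power()].
#' @param beta causal set effect (1 in the power study; 0 under the null).
#' @param gamma direct miRNA effect size.
#' @param w common mRNA effect size.
#' @param censoring expected censoring fraction in \[0, 1).
#' @param alpha nominal significance level.
#' @param replicates number of simulated datasets.
#' @param B permutations per replicate.
#' @param zero_prop fraction of each miRNA's values set to its minimum
#'   (mimicking zero read counts after log transform).
#' @param inhibition_strength planted negative slope of targets on their
#'   miRNA.
#' @param noise_sd target-mRNA residual standard deviation.
#' @param lambdas fixed penalty strengths per penalty kind, used by the
#'   simulation testing protocol (mild values keep the permutation statistic
#'   continuous; see the methods vignette).
#' @param seed integer seed driving all randomness of a simulation run.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 95, n_mirna = 10, targets_per_mirna = 5,
                       n_causal = 2, beta = 1, gamma = 0.3, w = 0.6,
                       censoring = 0.15, alpha = 0.05, replicates = 200,
                       B = 200, zero_prop = 0, inhibition_strength = 1,
                       noise_sd = 1,
                       lambdas = c(ridge = 1, lasso = 0.1, en = 0.1),
                       seed = 1) {
  stopifnot(censoring >= 0, censoring < 1, zero_prop >= 0, zero_prop < 1,
            n_samples >= 3, replicates >= 1, B >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate synthetic expression with planted inhibited targets
#'
#' miRNA values are standard normal (then a `zero_prop` fraction of each
#' column is set to the column minimum, mimicking zero counts); each planted
#' target equals `-inhibition_strength * z` plus independent normal noise, so
#' planted pairs have population correlation
#' `-s / sqrt(s^2 + noise_sd^2)`.
#'
#' @inheritParams sim_config
#' @param seed optional; when `NULL` the current RNG stream is used.
#' @return list of class `mimi_sim_data` with elements `mirna`, `mrna`
#'   (expression tibbles), `pairs` (planted pair map with slopes) and
#'   `mirnas`.
#' @export
generate_expression <- function(n_samples, n_mirna = 10,
                                targets_per_mirna = 5,
                                inhibition_strength = 1, noise_sd = 1,
                                zero_prop = 0, seed = NULL) {
  stopifnot(n_samples >= 3, n_mirna >= 1, targets_per_mirna >= 1,
            zero_prop >= 0, zero_prop < 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  mirnas <- sprintf("mir%02d", seq_len(n_mirna))
  samples <- sprintf("s%04d", seq_len(n_samples))
  Z <- matrix(rnorm(n_samples * n_mirna), n_samples, n_mirna,
              dimnames = list(samples, mirnas))
  if (zero_prop > 0) {
    nz <- ceiling(zero_prop * n_samples)
    for (j in seq_len(n_mirna)) {
      idx <- sample.int(n_samples, nz)
      Z[idx, j] <- min(Z[, j])
    }
  }
  genes <- as.vector(outer(seq_len(targets_per_mirna), mirnas,
                           function(g, m) paste0("g_", m, "_", g)))
  X <- matrix(0, n_samples, n_mirna * targets_per_mirna,
              dimnames = list(samples, genes))
  pairs <- tibble(
    miRNA = rep(mirnas, each = targets_per_mirna),
    gene = genes,
    slope = -inhibition_strength
  )
  for (i in seq_len(nrow(pairs))) {
    X[, pairs$gene[i]] <- pairs$slope[i] * Z[, pairs$miRNA[i]] +
      rnorm(n_samples, sd = noise_sd)
  }
  structure(list(mirna = matrix_to_expr(Z), mrna = matrix_to_expr(X),
                 pairs = pairs, mirnas = mirnas),
            class = "mimi_sim_data")
}

# expected censoring fraction of Exp(rate) censoring against Exp(exp(eta))
# event times is mean(rate / (rate + exp(eta))); solve for rate by bisection
censoring_rate <- function(eta, target) {
  if (target <= 0) return(0)
  lam <- exp(eta)
  frac <- function(rho) mean(rho / (rho + lam))
  lo <- 1e-12
  hi <- 1
  while (frac(hi) < target) hi <- hi * 2
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

#' Simulate survival from causal integration sets
#'
#' Event times are exponential with rate `exp(eta_i)` (constant baseline
#' hazard 1), where `eta_i` sums `beta * (gamma * z_ij + w * sum_k
#' xhat_ijk)` over the causal sets; the adjusted expression uses inhibition
#' slopes estimated from the generated data. Censoring times are independent
#' exponentials whose rate is calibrated by bisection so the expected
#' censoring fraction equals `censoring`.
#'
#' @param data a `mimi_sim_data` from [generate_expression()].
#' @param causal character vector of causal miRNA ids (possibly empty: the
#'   global null).
#' @param beta,gamma,w generative effect sizes.
#' @param censoring target expected censoring fraction in \[0, 1).
#' @param seed optional; when `NULL` the current RNG stream is used.
#' @return survival tibble (`sample`, `time`, `event`).
#' @export
simulate_survival <- function(data, causal = character(), beta = 1,
                              gamma = 0.4, w = 0.7, censoring = 0.15,
                              seed = NULL) {
  stopifnot(inherits(data, "mimi_sim_data"), censoring >= 0, censoring < 1)
  if (!all(causal %in% data$mirnas)) abort("`causal` must name generated miRNAs.")
  if (!is.null(seed)) set.seed(seed)
  zm <- expr_to_matrix(data$mirna, "mirna")
  n <- nrow(zm)
  eta <- rep(0, n)
  if (length(causal) && beta != 0) {
    sets <- data$pairs[data$pairs$miRNA %in% causal, c("miRNA", "gene")]
    adj <- estimate_inhibition_coefficients(data$mirna, data$mrna, sets)
    xh <- expr_to_matrix(adjust_mrna(data$mrna, data$mirna, adj), "adjusted")
    zc <- scale(zm, scale = FALSE)
    for (mi in causal) {
      cols <- paste(mi, sets$gene[sets$miRNA == mi], sep = ":")
      eta <- eta + beta * (gamma * zc[, mi] + w * rowSums(xh[, cols, drop = FALSE]))
    }
  }
  t_event <- rexp(n, rate = exp(eta))
  if (censoring > 0) {
    rho <- censoring_rate(eta, censoring)
    t_cens <- rexp(n, rate = rho)
    tibble(sample = rownames(zm), time = pmin(t_event, t_cens),
           event = as.numeric(t_event <= t_cens))
  } else {
    tibble(sample = rownames(zm), time = t_event, event = 1)
  }
}

sim_penalty_pairs <- function(config, kinds) {
  lapply(kinds, function(k) {
    p <- penalty_spec(k, unname(config$lambdas[[k]]))
    list(p, p)
  })
}

# one replicate's permutation p-values for the requested methods
sim_replicate_pvals <- function(config, causal, methods, control) {
  mimi_kinds <- intersect(c("ridge", "lasso", "en"), methods)
  need_kinds <- if ("maxT" %in% methods) c("ridge", "lasso", "en") else mimi_kinds
  data <- generate_expression(config$n_samples, config$n_mirna,
                              config$targets_per_mirna,
                              config$inhibition_strength, config$noise_sd,
                              config$zero_prop)
  surv <- simulate_survival(data, causal, beta = config$beta,
                            gamma = config$gamma, w = config$w,
                            censoring = config$censoring)
  out <- list()
  if (length(need_kinds)) {
    bundle <- build_model_frame(data$mirna, data$mrna,
                                data$pairs[c("miRNA", "gene")], surv)
    eng <- perm_engine(bundle, sim_penalty_pairs(config, need_kinds),
                       config$B, seed = NULL, control = control)
    for (k in seq_along(need_kinds)) {
      kind <- need_kinds[k]
      if (!kind %in% methods) next
      out[[kind]] <- tibble(
        method = kind, miRNA = eng$mirnas,
        beta = as.numeric(eng$obs[k, ]),
        p = vapply(seq_along(eng$mirnas), function(j) {
          add_one_p(eng$obs[k, j], eng$perm[, j, k])
        }, numeric(1)))
    }
    if ("maxT" %in% methods) {
      tobs <- apply(abs(eng$obs), 2, max)
      tperm <- apply(abs(eng$perm), c(1, 2), max)
      out[["maxT"]] <- tibble(
        method = "maxT", miRNA = eng$mirnas, beta = tobs,
        p = vapply(seq_along(eng$mirnas), function(j) {
          add_one_p(tobs[j], tperm[, j])
        }, numeric(1)))
    }
  }
  if ("single" %in% methods) {
    sg <- single_mirna_cox(data$mirna, surv)
    out[["single"]] <- tibble(method = "single", miRNA = sg$miRNA,
                              beta = sg$delta, p = sg$p)
  }
  bind_rows(out)
}

#' Estimate type-I error under the global null
#'
#' Generates `replicates` datasets in which survival is independent of all
#' expression values (all generative effects zero), runs the permutation
#' test of every requested method at the fixed simulation-protocol penalties,
#' and reports the fraction of null tests with `p <= alpha` (the achievable-grid
#' convention for add-one permutation p-values) together with its
#' binomial Monte-Carlo standard deviation.
#'
#' @param config a [sim_config()] (its `beta` is ignored: the null sets all
#'   effects to zero).
#' @param methods any of `"ridge"`, `"lasso"`, `"en"`, `"maxT"`, `"single"`.
#' @param control permutation engine settings.
#' @param progress print a dot every 10 replicates.
#' @return tibble with columns `method`, `rejections`, `n_tests`, `rate`,
#'   `mc_sd`.
#' @export
estimate_type1_error <- function(config,
                                 methods = c("ridge", "lasso", "en", "maxT"),
                                 control = perm_control(), progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  res <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    res[[r]] <- sim_replicate_pvals(config, character(), methods, control)
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  bind_rows(res) |>
    filter(!is.na(.data$p)) |>
    group_by(.data$method) |>
    summarise(rejections = sum(.data$p <= config$alpha),
              n_tests = dplyr::n(), .groups = "drop") |>
    mutate(rate = .data$rejections / .data$n_tests,
           mc_sd = sqrt(.data$rate * (1 - .data$rate) / .data$n_tests))
}

#' Estimate power for causal integration sets
#'
#' The first `n_causal` miRNAs generate the survival signal with the
#' configured effect sizes. Power for a causal set is the fraction of
#' replicates in which the method both retains the set (nonzero estimate
#' under selection penalties; ridge always retains) and rejects at
#' `alpha`.
#'
#' @inheritParams estimate_type1_error
#' @return tibble with columns `method`, `miRNA`, `power`, `replicates`.
#' @export
estimate_power <- function(config,
                           methods = c("ridge", "lasso", "en", "maxT"),
                           control = perm_control(), progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), config$n_causal >= 1)
  causal <- sprintf("mir%02d", seq_len(config$n_causal))
  set.seed(config$seed)
  res <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    pv <- sim_replicate_pvals(config, causal, methods, control)
    res[[r]] <- pv |>
      filter(.data$miRNA %in% causal) |>
      mutate(reject = .data$beta != 0 & !is.na(.data$p) &
               .data$p <= config$alpha, rep = r)
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  bind_rows(res) |>
    group_by(.data$method, .data$miRNA) |>
    summarise(power = mean(.data$reject), replicates = dplyr::n(),
              .groups = "drop")
}
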