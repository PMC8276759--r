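# Fixture builders and independent oracles used across the suite. The
# oracles re-derive quantities by direct enumeration of their definitions and
# never call the package's numerical path.

# small survival table with optional tied event times
toy_surv <- function(time, event, samples = sprintf("s%02d", seq_along(time))) {
  tibble::tibble(sample = samples, time = time, event = event)
}

# brute-force Breslow log partial likelihood: explicit sum over event times
oracle_breslow_loglik <- function(X, beta, time, event) {
  eta <- as.vector(as.matrix(X) %*% beta)
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    risk <- which(time >= tt)
    dead <- which(time == tt & event == 1)
    ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

# gradient of the Breslow log partial likelihood wrt eta (for the joint
# maximization oracle)
oracle_breslow_grad_eta <- function(eta, time, event) {
  g <- as.numeric(event)
  for (tt in sort(unique(time[event == 1]))) {
    risk <- which(time >= tt)
    dead <- which(time == tt & event == 1)
    w <- exp(eta[risk])
    g[risk] <- g[risk] - length(dead) * w / sum(w)
  }
  g
}

# brute-force Benjamini-Hochberg step-up: literal min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# dataset with planted negative pairs plus independent decoys
toy_panel <- function(n = 60, n_planted = 4, n_null = 6, strength = 1.2,
                      seed = 1) {
  set.seed(seed)
  J <- n_planted + n_null
  Z <- matrix(rnorm(n * J), n, J,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%02d", 1:J)))
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(rownames(Z), sprintf("g%02d", 1:J)))
  for (j in seq_len(n_planted)) X[, j] <- -strength * Z[, j] + rnorm(n, sd = 0.6)
  pairs <- tibble::tibble(miRNA = colnames(Z), gene = colnames(X))
  list(mirna = Z, mrna = X, pairs = pairs,
       planted = pairs[seq_len(n_planted), ])
}

# small structured-model instance for fitter tests
toy_model_data <- function(n = 80, J = 3, G = 2, beta = c(1, 0, 0),
                           gamma = 0.4, w = 0.7, censoring = 0.15,
                           seed = 1) {
  set.seed(seed)
  d <- generate_expression(n, n_mirna = J, targets_per_mirna = G)
  causal <- d$mirnas[which(beta != 0)]
  sv <- simulate_survival(d, causal, beta = max(abs(beta), 1), gamma = gamma,
                          w = w, censoring = censoring)
  list(data = d, surv = sv, sets = d$pairs[c("miRNA", "gene")])
}
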