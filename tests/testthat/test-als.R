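test_that("single-set model with fully explained target collapses to one covariate", {
  # x = 2z exactly, so the adjusted mRNA is identically zero and the
  # component can only be the standardized miRNA. The collapsed problem has
  # a closed penalty form: writing the standardized-scale effect theta,
  # the bilinear ridge/ridge penalty profile is min over factorizations of
  # 0.5*lw*g0^2 + 0.5*lb*beta^2 s.t. g0*beta*sd(z) = theta, which equals
  # sqrt(lw*lb)*|theta|/sd(z). A 1-D search over theta is the oracle.
  set.seed(1)
  n <- 120
  z <- rnorm(n)
  Z <- cbind(m1 = z)
  X <- cbind(g1 = 2 * z)
  rownames(Z) <- rownames(X) <- paste0("s", 1:n)
  sv <- toy_surv(rexp(n, exp(0.8 * scale(z)[, 1])), rbinom(n, 1, 0.9),
                 paste0("s", 1:n))
  sets <- tibble::tibble(miRNA = "m1", gene = "g1")
  lw <- 1; lb <- 1
  fit <- fit_mimi_surv(Z, X, sets, sv, penalty_spec("ridge", lw),
                       penalty_spec("ridge", lb),
                       control = mimi_control(tol = 1e-10, max_iter = 500))
  zc <- z - mean(z)
  zs <- zc / sd(zc)
  obj <- function(theta) {
    oracle_breslow_loglik(cbind(zs), theta, sv$time, sv$event) -
      sqrt(lw * lb) * abs(theta) / sd(zc)
  }
  theta_hat <- optimize(obj, c(-3, 3), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(fit$beta["m1"]), theta_hat, tolerance = 1e-4)
  # component proportional to standardized z
  f <- fit$latents$m1
  expect_equal(abs(cor(f, zs)), 1, tolerance = 1e-10)
})

test_that("a huge lasso penalty on beta empties the active set", {
  md <- toy_model_data(n = 60, J = 3, G = 2, seed = 2)
  fit <- fit_mimi_surv(md$data$mirna, md$data$mrna, md$sets, md$surv,
                       penalty_spec("ridge", 1), penalty_spec("lasso", 1e5))
  expect_equal(unname(fit$beta), rep(0, 3))
  # objective equals the null log partial likelihood (empty model)
  nul <- -sum(log(vapply(md$surv$time[md$surv$event == 1],
                         function(t) sum(md$surv$time >= t), numeric(1))))
  expect_equal(tail(fit$objective_trace, 1), nul, tolerance = 1e-8)
})

test_that("objective trace is non-decreasing across penalties and instances", {
  kinds <- list(c("ridge", "ridge"), c("lasso", "lasso"), c("en", "en"),
                c("ridge", "lasso"))
  for (s in 1:8) {
    md <- toy_model_data(n = 50, J = 3, G = 2, beta = c(1, 0, 0),
                         seed = 100 + s)
    kk <- kinds[[(s %% length(kinds)) + 1]]
    fit <- fit_mimi_surv(md$data$mirna, md$data$mrna, md$sets, md$surv,
                         penalty_spec(kk[1], 0.5), penalty_spec(kk[2], 0.5))
    expect_true(all(diff(fit$objective_trace) >= -1e-10),
                label = sprintf("monotone trace (seed %d, %s/%s)", s, kk[1], kk[2]))
  }
})

test_that("objective_value reproduces the trace tail term by term", {
  md <- toy_model_data(n = 60, J = 3, G = 2, seed = 3)
  fit <- fit_mimi_surv(md$data$mirna, md$data$mrna, md$sets, md$surv,
                       penalty_spec("en", 0.4), penalty_spec("en", 0.6))
  # independent term-by-term evaluation: brute-force loglik + penalties
  b <- fit$bundle
  f <- vapply(seq_along(b$mirnas), function(j) {
    fj <- fit$raw$gamma0[j] * b$Z[, j]
    sel <- b$setidx == (j - 1L)
    fj + as.vector(b$Xh[, sel, drop = FALSE] %*% fit$raw$w[sel])
  }, numeric(nrow(b$Z)))
  a <- c(fit$raw$gamma0, fit$raw$w)
  phi_oracle <- oracle_breslow_loglik(f, fit$raw$beta, md$surv$time,
                                      md$surv$event) -
    0.2 * sum(abs(a)) - 0.5 * 0.2 * sum(a^2) -       # en lambda 0.4, halved
    0.3 * sum(abs(fit$raw$beta)) - 0.5 * 0.3 * sum(fit$raw$beta^2)
  expect_equal(objective_value(fit), phi_oracle, tolerance = 1e-10)
  expect_equal(tail(fit$objective_trace, 1), phi_oracle, tolerance = 1e-8)
})

test_that("estimates are invariant under a joint permutation of sample rows", {
  md <- toy_model_data(n = 50, J = 3, G = 2, seed = 4)
  fit1 <- fit_mimi_surv(md$data$mirna, md$data$mrna, md$sets, md$surv,
                        penalty_spec("ridge", 1))
  set.seed(9)
  perm <- sample.int(50)
  zm <- expr_to_matrix(md$data$mirna)[perm, ]
  xm <- expr_to_matrix(md$data$mrna)[perm, ]
  sv <- md$surv[perm, ]
  fit2 <- fit_mimi_surv(zm, xm, md$sets, sv, penalty_spec("ridge", 1))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$w$w, fit2$w$w, tolerance = 1e-10)
})

test_that("ridge penalties vanishing recovers the unpenalized structured fit", {
  # small well-conditioned instance; the oracle is a joint BFGS maximization
  # of the brute-force partial likelihood over all parameters at once
  md <- toy_model_data(n = 150, J = 2, G = 2, beta = c(1, 0), seed = 5)
  fit <- fit_mimi_surv(md$data$mirna, md$data$mrna, md$sets, md$surv,
                       penalty_spec("ridge", 1e-7),
                       control = mimi_control(tol = 1e-12, max_iter = 2000,
                                              inner_iter = 100))
  b <- fit$bundle
  J <- 2; M <- ncol(b$Xh)
  nll <- function(par) {
    g0 <- par[1:J]; w <- par[J + (1:M)]; beta <- par[J + M + (1:J)]
    f <- vapply(1:J, function(j) {
      g0[j] * b$Z[, j] +
        as.vector(b$Xh[, b$setidx == (j - 1L), drop = FALSE] %*%
                    w[b$setidx == (j - 1L)])
    }, numeric(nrow(b$Z)))
    -oracle_breslow_loglik(f, beta, md$surv$time, md$surv$event)
  }
  grr <- function(par) {
    g0 <- par[1:J]; w <- par[J + (1:M)]; beta <- par[J + M + (1:J)]
    f <- vapply(1:J, function(j) {
      g0[j] * b$Z[, j] +
        as.vector(b$Xh[, b$setidx == (j - 1L), drop = FALSE] %*%
                    w[b$setidx == (j - 1L)])
    }, numeric(nrow(b$Z)))
    eta <- as.vector(f %*% beta)
    ge <- oracle_breslow_grad_eta(eta, md$surv$time, md$surv$event)
    gg0 <- vapply(1:J, function(j) sum(ge * beta[j] * b$Z[, j]), numeric(1))
    gw <- vapply(1:M, function(m) {
      j <- b$setidx[m] + 1L
      sum(ge * beta[j] * b$Xh[, m])
    }, numeric(1))
    gb <- vapply(1:J, function(j) sum(ge * f[, j]), numeric(1))
    -c(gg0, gw, gb)
  }
  init <- c(fit$raw$gamma0, fit$raw$w, fit$raw$beta) * 1.2 + 0.01
  opt <- optim(init, nll, grr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  # normalize both solutions to the unit-variance + sign convention
  norm_par <- function(g0, w, beta) {
    out_b <- numeric(J)
    for (j in 1:J) {
      f <- g0[j] * b$Z[, j] +
        as.vector(b$Xh[, b$setidx == (j - 1L), drop = FALSE] %*%
                    w[b$setidx == (j - 1L)])
      s <- sd(f)
      out_b[j] <- beta[j] * s * sign(g0[j])
      w[b$setidx == (j - 1L)] <- w[b$setidx == (j - 1L)] / s * sign(g0[j])
      g0[j] <- abs(g0[j]) / s
    }
    list(g0 = g0, w = w, beta = out_b)
  }
  o <- norm_par(opt$par[1:J], opt$par[J + (1:M)], opt$par[J + M + (1:J)])
  expect_equal(unname(fit$beta), o$beta, tolerance = 1e-4)
  expect_equal(fit$gamma0$gamma0, o$g0, tolerance = 1e-4)
  expect_equal(fit$w$w, o$w, tolerance = 1e-4)
})

test_that("lambda pair selection returns the grid point on a 1x1 grid", {
  md <- toy_model_data(n = 50, J = 2, G = 2, seed = 6)
  sel <- select_lambdas(md$data$mirna, md$data$mrna, md$sets, md$surv,
                        grid_w = 0.5, grid_b = 2, k = 3, seed = 1)
  expect_equal(sel$lambda_w, 0.5)
  expect_equal(sel$lambda_b, 2)
  expect_equal(nrow(sel$cv), 1)
})

test_that("lambda pair selection prefers heavy penalties on pure noise", {
  wins <- vapply(1:5, function(s) {
    set.seed(200 + s)
    d <- generate_expression(60, n_mirna = 2, targets_per_mirna = 2)
    sv <- simulate_survival(d, character(), censoring = 0.15)
    grid <- c(0.2, 20)
    sel <- select_lambdas(d$mirna, d$mrna, d$pairs[c("miRNA", "gene")], sv,
                          penalty_kind = "lasso", grid_w = grid, grid_b = grid,
                          k = 4, seed = s)
    sel$lambda_b == 20
  }, logical(1))
  expect_gte(sum(wins), 3)
})
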