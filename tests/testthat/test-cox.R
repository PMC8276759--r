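test_that("partial likelihood matches closed forms and the tie oracle", {
  # coef = 0: -sum over events of log(risk-set size)
  sv <- toy_surv(c(3, 1, 4, 2, 5), c(1, 1, 0, 1, 1))
  X <- matrix(rnorm(5), 5, 1)
  risk_sizes <- vapply(sv$time[sv$event == 1],
                       function(t) sum(sv$time >= t), numeric(1))
  expect_equal(partial_loglik(X, 0, sv), -sum(log(risk_sizes)))

  # two-sample closed form at beta = 0: -log 2
  sv2 <- toy_surv(c(1, 2), c(1, 0))
  expect_equal(partial_loglik(matrix(c(1, 0)), 0, sv2), -log(2))

  # tied event times against the brute-force Breslow enumeration
  sv3 <- toy_surv(c(2, 2, 3, 1, 3), c(1, 1, 0, 1, 1))
  X3 <- matrix(c(0.5, -1, 2, 0, 1, 1, -2, 0.3, 0.8, -0.6), 5, 2)
  beta <- c(0.7, -0.4)
  expect_equal(partial_loglik(X3, beta, sv3),
               oracle_breslow_loglik(X3, beta, sv3$time, sv3$event))

  expect_error(partial_loglik(X3, beta, toy_surv(1:5, rep(0, 5))), "event")
})

test_that("partial likelihood is invariant to constant shifts of the linear predictor", {
  set.seed(1)
  n <- 30
  X <- matrix(rnorm(3 * n), n, 3)
  beta <- c(0.5, -1, 0.2)
  sv <- toy_surv(rexp(n), rbinom(n, 1, 0.7), paste0("s", 1:n))
  shift <- X + outer(rep(1, n), c(5, -2, 1))  # adds a constant to eta
  expect_equal(partial_loglik(shift, beta, sv), partial_loglik(X, beta, sv))
})

test_that("unpenalized fit reproduces the coxph maximum likelihood estimate", {
  skip_if_not_installed("survival")
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  eta <- 0.8 * X[, 1] - 0.5 * X[, 2]
  sv <- toy_surv(rexp(n, exp(eta)), rbinom(n, 1, 0.85), paste0("s", 1:n))
  fit <- fit_penalized_cox(X, sv, penalty_spec("none"))
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ X,
                         ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("lasso and elastic-net fits agree with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 100
  X <- scale(matrix(rnorm(5 * n), n, 5))
  eta <- 1 * X[, 1] - 0.7 * X[, 3]
  sv <- toy_surv(rexp(n, exp(eta)), rbinom(n, 1, 0.9), paste0("s", 1:n))
  y <- survival::Surv(sv$time, sv$event)
  for (alpha in c(1, 0.5)) {
    lam_g <- 0.08
    gf <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                         lambda = lam_g, standardize = FALSE, thresh = 1e-12)
    # glmnet: -(1/n) loglik + lambda*(alpha*l1 + (1-alpha)/2*l2)
    ours <- cpp_cox_fit(X, sv$time, sv$event,
                        n * lam_g * alpha, n * lam_g * (1 - alpha),
                        rep(0, 5), 1e-10, 500)
    expect_equal(as.numeric(ours$coef), as.numeric(gf$beta), tolerance = 2e-3)
  }
})

test_that("lasso at or above lambda_max returns the zero solution", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(4 * n), n, 4)
  sv <- toy_surv(rexp(n), rbinom(n, 1, 0.8), paste0("s", 1:n))
  lmax <- lambda_grid(X, sv, n = 1)[1]       # anchored at the all-zero bound
  fit <- fit_penalized_cox(X, sv, penalty_spec("lasso", lmax * 1.0001))
  expect_equal(unname(fit$coef), rep(0, 4))
  fit2 <- fit_penalized_cox(X, sv, penalty_spec("lasso", lmax * 0.5))
  expect_gt(max(abs(fit2$coef)), 0)
})

test_that("ridge solutions shrink monotonically and continuously in lambda", {
  set.seed(5)
  n <- 70
  X <- matrix(rnorm(2 * n), n, 2)
  eta <- X[, 1]
  sv <- toy_surv(rexp(n, exp(eta)), rbinom(n, 1, 0.9), paste0("s", 1:n))
  lambdas <- c(0.01, 0.1, 1, 10, 100)
  norms <- vapply(lambdas, function(l) {
    sqrt(sum(fit_penalized_cox(X, sv, penalty_spec("ridge", l))$coef^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # optimal penalized objective is non-increasing in lambda
  objs <- vapply(lambdas, function(l) {
    fit_penalized_cox(X, sv, penalty_spec("ridge", l))$objective
  }, numeric(1))
  expect_true(all(diff(objs) < 1e-10))

  # path continuity
  b1 <- fit_penalized_cox(X, sv, penalty_spec("ridge", 1))$coef
  b2 <- fit_penalized_cox(X, sv, penalty_spec("ridge", 1.001))$coef
  expect_lt(max(abs(b1 - b2)), 1e-3)
})

test_that("cross-validated lambda selection behaves at the edges", {
  set.seed(6)
  n <- 60
  X <- matrix(rnorm(3 * n), n, 3)
  sv <- toy_surv(rexp(n), rbinom(n, 1, 0.8), paste0("s", 1:n))

  # one-point grid returns that value
  expect_equal(as.numeric(cv_select_lambda(X, sv, "lasso", grid = 0.7, k = 3,
                                           seed = 1)), 0.7)

  # pure noise: the largest grid value wins in the majority of seeds
  wins <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(3 * n), n, 3)
    svn <- toy_surv(rexp(n), rbinom(n, 1, 0.8), paste0("s", 1:n))
    g <- lambda_grid(Xn, svn, n = 6)
    sel <- cv_select_lambda(Xn, svn, "lasso", grid = g, k = 5, seed = s)
    as.numeric(sel) == max(g)
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("leave-one-out cross-validation matches direct enumeration", {
  set.seed(7)
  n <- 14
  X <- matrix(rnorm(n), n, 1)
  sv <- toy_surv(rexp(n, exp(0.6 * X[, 1])), rep(1, n), paste0("s", 1:n))
  grid <- c(0.05, 0.5, 5)
  sel <- cv_select_lambda(X, sv, "ridge", grid = grid, k = n, seed = 9)

  crit <- vapply(grid, function(l) {
    sum(vapply(seq_len(n), function(i) {
      fit <- fit_penalized_cox(X[-i, , drop = FALSE], sv[-i, ],
                               penalty_spec("ridge", l))
      partial_loglik(X, fit$coef, sv) -
        partial_loglik(X[-i, , drop = FALSE], fit$coef, sv[-i, ])
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which(crit >= max(crit) - 1e-12)]
  expect_equal(as.numeric(sel), max(best))
})
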