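test_that("huge penalties shrink every interaction block to exactly zero", {
  d <- random_mixed_data(60L, 3L, c(3L, 4L), seed = 21)
  fit <- fit_mgm(d, penalty_weights(1e6))
  off <- fit$beta; diag(off) <- 0
  expect_true(all(off == 0))
  expect_true(all(fit$rho == 0))
  offs <- c(0L, cumsum(d$levels))
  for (j in 1:2) for (r in seq_len(j - 1))
    expect_true(all(fit$phi[offs[r] + 1:d$levels[r],
                            offs[j] + 1:d$levels[j]] == 0))
  # intercepts and variances survive
  expect_true(all(diag(fit$beta) > 0))
  expect_equal(sum(adjacency_from_parameters(fit)), 0L)
})

test_that("unpenalized Gaussian fit recovers the inverse sample covariance", {
  Sigma <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  ch <- chol(Sigma)
  X <- withr::with_seed(31, matrix(rnorm(10000), 5000, 2) %*% ch)
  d <- mixed_data(X = X)
  fit <- fit_mgm(d, penalty_weights(0), fit_config(tolerance = 1e-10))
  Xs <- scale(X)
  K <- solve(crossprod(Xs) / nrow(Xs))
  expect_lt(max(abs(fit$beta - K) / abs(K)), 0.02)
})

test_that("fit objective matches a derivative-free optimizer on a tiny instance", {
  sim <- small_sim(p = 2L, q = 1L, n = 50L, seed = 41)
  d <- mixed_data(X = sim$data$X, Y = matrix(sim$data$Y[, 1], ncol = 1),
                  levels = sim$data$levels[1])
  pen <- penalty_weights(0.1)
  fit <- fit_mgm(d, pen, fit_config(tolerance = 1e-10))
  # evaluate on the same (standardized) scale the fit used
  ds <- mixed_data(X = scale(d$X), Y = d$Y, levels = d$levels)
  unpack <- function(v) {
    beta <- matrix(c(exp(v[1]), v[3], v[3], exp(v[2])), 2, 2)
    rho <- matrix(v[6:11], 3, 2)
    phi <- diag(v[12:14], 3)
    mgm_params(beta, v[4:5], rho, phi, levels = 3L)
  }
  obj <- function(v) naive_objective(unpack(v), ds, pen)
  fit_obj <- fit$fit$objective
  # cold Nelder-Mead cannot beat the proximal fit by more than the tolerance
  v0 <- c(0, 0, 0, 0, 0, rep(0, 6), rep(0, 3))
  nm <- optim(v0, obj, method = "Nelder-Mead",
              control = list(maxit = 20000, reltol = 1e-12))
  expect_lt(fit_obj, nm$value + 1e-4)
  # restarting Nelder-Mead at the fitted solution finds no real improvement
  vfit <- c(log(diag(fit$beta)), fit$beta[1, 2], fit$alpha,
            as.numeric(fit$rho), diag(fit$phi))
  nm2 <- optim(vfit, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-12))
  expect_lt(fit_obj - nm2$value, 1e-4)
})

test_that("objective trace is non-increasing and termination is reported", {
  sim <- small_sim(p = 3L, q = 3L, n = 80L, seed = 51)
  fit <- fit_mgm(sim$data, penalty_weights(0.08))
  expect_true(all(diff(fit$fit$trace) < 1e-10))
  expect_true(fit$fit$termination %in% c("tolerance", "max_iterations"))
  expect_true(fit$fit$converged)
  capped <- fit_mgm(sim$data, penalty_weights(0.08),
                    fit_config(max_iterations = 2L))
  expect_false(capped$fit$converged)
  expect_equal(capped$fit$termination, "max_iterations")
})

test_that("group sparsity is exact after fitting", {
  sim <- small_sim(p = 4L, q = 4L, n = 120L, seed = 61)
  fit <- fit_mgm(sim$data, penalty_weights(0.25))
  offs <- c(0L, cumsum(fit$levels))
  norms_rho <- unlist(lapply(seq_along(fit$levels), function(j)
    vapply(1:4, function(s)
      sqrt(sum(fit$rho[offs[j] + 1:fit$levels[j], s]^2)), numeric(1))))
  expect_true(all(norms_rho == 0 | norms_rho > 1e-9))
  expect_gt(sum(norms_rho == 0), 0)      # shrinkage really produces zeros
  # every rho group and off-diagonal phi block sums to zero
  for (j in seq_along(fit$levels)) {
    idx <- offs[j] + 1:fit$levels[j]
    expect_lt(max(abs(colSums(fit$rho[idx, , drop = FALSE]))), 1e-10)
    for (r in seq_len(j - 1)) {
      B <- fit$phi[offs[r] + 1:fit$levels[r], idx]
      expect_lt(max(abs(rowSums(B))), 1e-10)
      expect_lt(max(abs(colSums(B))), 1e-10)
    }
  }
  expect_true(all(fit$beta == t(fit$beta)))
})

test_that("fitted parameters satisfy the subgradient optimality conditions", {
  sim <- small_sim(p = 3L, q = 3L, n = 100L, seed = 71)
  pen <- penalty_weights(0.1, 0.15, 0.2)
  fit <- fit_mgm(sim$data, pen, fit_config(tolerance = 1e-12))
  ds <- mixed_data(X = scale(sim$data$X), Y = sim$data$Y,
                   levels = sim$data$levels)
  fit2 <- fit; fit2$scaling <- NULL
  g <- nlpl_gradient(fit2, ds)
  n <- ds$n
  tol <- 1e-3
  # beta: off-diagonal entries
  for (s in 1:3) for (t in 1:3) {
    if (s == t) next
    gpair <- g$beta[s, t] / n
    if (fit$beta[s, t] != 0)
      expect_lt(abs(gpair + pen$lambda_cc * sign(fit$beta[s, t])), tol)
    else expect_lt(abs(gpair), pen$lambda_cc + tol)
  }
  # rho groups: centered gradient vs group subdifferential
  offs <- c(0L, cumsum(fit$levels))
  for (j in 1:3) for (s in 1:3) {
    idx <- offs[j] + 1:fit$levels[j]
    gg <- g$rho[idx, s] / n; gg <- gg - mean(gg)
    rr <- fit$rho[idx, s]
    if (any(rr != 0))
      expect_lt(max(abs(gg + pen$lambda_cd * rr / sqrt(sum(rr^2)))), tol)
    else expect_lt(sqrt(sum(gg^2)), pen$lambda_cd + tol)
  }
  # phi blocks: doubly centered gradient
  for (j in 2:3) for (r in 1:(j - 1)) {
    ri <- offs[r] + 1:fit$levels[r]; ci <- offs[j] + 1:fit$levels[j]
    gg <- g$phi[ri, ci] / n
    gg <- gg - rowMeans(gg)
    gg <- sweep(gg, 2, colMeans(gg))
    B <- fit$phi[ri, ci]
    if (any(B != 0))
      expect_lt(max(abs(gg + pen$lambda_dd * B / sqrt(sum(B^2)))), tol)
    else expect_lt(sqrt(sum(gg^2)), pen$lambda_dd + tol)
  }
})

test_that("proximal step thresholds groups and scalars as specified", {
  pars <- mgm_params_init(2L, c(4L, 4L))
  zero_grad <- list(beta = matrix(0, 2, 2), alpha = c(0, 0),
                    rho = matrix(0, 8, 2), phi = matrix(0, 8, 8))
  # group with norm 0.3 under threshold 0.5 vanishes exactly
  pars$rho[1:4, 1] <- 0.3 * c(1, -1, 1, -1) / 2
  out <- proximal_step(pars, zero_grad, step = 1, penalty_weights(0, 0.5, 0))
  expect_true(all(out$rho == 0))
  # scalar beta soft threshold: 1.0 at 0.4 -> 0.6
  pars <- mgm_params_init(2L, c(4L, 4L))
  pars$beta[1, 2] <- pars$beta[2, 1] <- 1.0
  out <- proximal_step(pars, zero_grad, step = 1, penalty_weights(0.4, 0, 0))
  expect_equal(out$beta[1, 2], 0.6)
  expect_equal(out$beta[2, 1], 0.6)
  expect_error(proximal_step(pars, zero_grad, step = 0, penalty_weights(1)),
               "positive")
})

test_that("the fitted model is a fixed point of the proximal step", {
  sim <- small_sim(p = 3L, q = 2L, n = 90L, seed = 81)
  pen <- penalty_weights(0.12)
  fit <- fit_mgm(sim$data, pen, fit_config(tolerance = 1e-12))
  ds <- mixed_data(X = scale(sim$data$X), Y = sim$data$Y,
                   levels = sim$data$levels)
  fit2 <- fit; fit2$scaling <- NULL
  g <- nlpl_gradient(fit2, ds)
  n <- ds$n
  grad <- list(beta = g$beta / n, alpha = g$alpha / n, rho = g$rho / n,
               phi = g$phi / n)
  step <- 1e-3
  out <- proximal_step(fit2, grad, step, pen)
  expect_lt(max(abs(out$beta - fit$beta)), 5e-5)
  expect_lt(max(abs(out$rho - fit$rho)), 5e-5)
  expect_lt(max(abs(out$phi - fit$phi)), 5e-5)
})

test_that("fit objective is invariant to sample order and consistent with the R evaluator", {
  sim <- small_sim(p = 3L, q = 3L, n = 70L, seed = 91)
  pen <- penalty_weights(0.1)
  fit <- fit_mgm(sim$data, pen)
  # the C++ objective equals the R pseudolikelihood + penalty
  expect_equal(negative_log_pseudolikelihood(fit, sim$data) / sim$data$n +
                 penalty_value(fit, pen),
               fit$fit$objective, tolerance = 1e-10)
  perm <- withr::with_seed(9, sample(sim$data$n))
  fit2 <- fit_mgm(sim$data[perm], pen)
  expect_equal(fit2$fit$objective, fit$fit$objective, tolerance = 1e-8)
})
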