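test_that("log unnormalized density matches direct substitution", {
  # empty exponent
  expect_equal(log_unnormalized_density(mgm_params_init(0L, c(2L)),
                                        numeric(0), 1L), 0)
  # p=1, q=0: -1/2 * 1 * 9 + 2 * 3 = 1.5
  one <- mgm_params(beta = matrix(1, 1, 1), alpha = 2,
                    rho = matrix(0, 0, 1), phi = matrix(0, 0, 0),
                    levels = integer(0))
  expect_equal(log_unnormalized_density(one, 3, integer(0)), 1.5)
})

test_that("log unnormalized density matches term-by-term enumeration oracle", {
  for (seed in 1:5) {
    pars <- random_params(2L, c(3L, 2L), seed)
    x <- withr::with_seed(seed + 100, rnorm(2))
    y <- withr::with_seed(seed + 200, c(sample(3, 1), sample(2, 1)))
    expect_equal(log_unnormalized_density(pars, x, y),
                 naive_log_density(pars, x, y))
  }
})

test_that("density errors on dimension mismatch and bad levels", {
  pars <- random_params(2L, c(3L, 2L), 1)
  expect_error(log_unnormalized_density(pars, 1, c(1L, 1L)), "length")
  expect_error(log_unnormalized_density(pars, c(1, 2), c(4L, 1L)),
               "out of range")
})

test_that("continuous conditional has the derived Gaussian form", {
  iso <- mgm_params(beta = diag(2), alpha = c(0, 0),
                    rho = matrix(0, 0, 2), phi = matrix(0, 0, 0),
                    levels = integer(0))
  cc <- continuous_conditional(iso, 1, c(0, 5), integer(0))
  expect_equal(cc$mean, 0)
  expect_equal(cc$variance, 1)

  two <- mgm_params(beta = diag(c(2, 1)), alpha = c(4, 0),
                    rho = matrix(0, 0, 2), phi = matrix(0, 0, 0),
                    levels = integer(0))
  cc <- continuous_conditional(two, 1, c(0, 0), integer(0))
  expect_equal(cc$mean, 2)
  expect_equal(cc$variance, 0.5)
})

test_that("continuous conditional matches 1-D quadrature of the joint", {
  # 3-node chain: x1 - x2 - y1
  pars <- random_params(2L, 3L, seed = 9)
  x <- c(0.4, -0.7); y <- 2L
  cc <- continuous_conditional(pars, 1, x, y)
  grid <- seq(cc$mean - 8 * sqrt(cc$variance),
              cc$mean + 8 * sqrt(cc$variance), length.out = 4001)
  h <- diff(grid[1:2])
  lp <- vapply(grid, function(g)
    naive_log_density(pars, c(g, x[2]), y), numeric(1))
  w <- exp(lp - max(lp)); w <- w / (sum(w) * h)
  expect_equal(sum(w) * h, 1, tolerance = 1e-8)           # integrates to 1
  dens <- dnorm(grid, cc$mean, sqrt(cc$variance))
  expect_lt(max(abs(w - dens)), 1e-6)
})

test_that("categorical conditional is the softmax renormalization of the joint", {
  # all-zero parameters: uniform over 4 levels
  pars0 <- mgm_params_init(1L, 4L)
  expect_equal(categorical_conditional(pars0, 1, 0, 1L), rep(0.25, 4))
  # dominant level potential
  pars1 <- mgm_params_init(0L, 4L)
  pars1$phi <- diag(c(10, 0, 0, 0))
  expect_gt(categorical_conditional(pars1, 1, numeric(0), 1L)[1], 0.999)
  # random parameters vs enumeration oracle
  for (seed in 1:5) {
    pars <- random_params(2L, c(4L, 3L), seed)
    x <- withr::with_seed(seed, rnorm(2))
    y <- c(1L, 3L)
    pr <- categorical_conditional(pars, 1, x, y)
    expect_equal(sum(pr), 1)
    expect_equal(pr, naive_cat_conditional(pars, 1, x, y))
  }
})

test_that("negative log-pseudolikelihood reproduces textbook constants", {
  # q=1, binary, zero parameters, one sample: log 2
  bin <- mgm_params_init(0L, 2L)
  d <- mixed_data(Y = matrix(1L, 1, 1), levels = 2L)
  expect_equal(negative_log_pseudolikelihood(bin, d), log(2))
  # p=1, beta=1, alpha=0, x=0: standard normal at its mode
  std <- mgm_params(matrix(1, 1, 1), 0, matrix(0, 0, 1), matrix(0, 0, 0),
                    integer(0))
  d2 <- mixed_data(X = matrix(0, 1, 1))
  expect_equal(negative_log_pseudolikelihood(std, d2), 0.5 * log(2 * pi))
})

test_that("pseudolikelihood equals the sum of per-conditional oracle terms", {
  pars <- random_params(2L, c(3L, 2L), seed = 3)
  d <- random_mixed_data(5L, 2L, c(3L, 2L), seed = 4)
  expect_equal(negative_log_pseudolikelihood(pars, d), naive_nlpl(pars, d))
  ps <- negative_log_pseudolikelihood(pars, d, per_sample = TRUE)
  expect_length(ps, 5L)
  expect_equal(sum(ps), naive_nlpl(pars, d))
})

test_that("pseudolikelihood is invariant to sample order and level relabeling", {
  pars <- random_params(2L, c(3L, 2L), seed = 5)
  d <- random_mixed_data(20L, 2L, c(3L, 2L), seed = 6)
  perm <- withr::with_seed(8, sample(20))
  expect_equal(negative_log_pseudolikelihood(pars, d[perm]),
               negative_log_pseudolikelihood(pars, d))
  # relabel the levels of variable 1 and permute its parameter rows to match
  relab <- c(2L, 3L, 1L)
  d2 <- d; d2$Y[, 1] <- relab[d$Y[, 1]]
  pars2 <- pars
  inv <- order(relab)                       # row k of new = row inv[k] of old
  pars2$rho[1:3, ] <- pars$rho[order(relab), ]
  pars2$phi[1:3, ] <- pars$phi[order(relab), ]
  pars2$phi[, 1:3] <- pars2$phi[, order(relab)]
  expect_equal(negative_log_pseudolikelihood(pars2, d2),
               negative_log_pseudolikelihood(pars, d))
})

test_that("penalty value follows the three-term formula", {
  pars <- mgm_params_init(2L, c(4L, 4L))
  expect_equal(penalty_value(pars, penalty_weights(1)), 0)
  pars$beta[1, 2] <- pars$beta[2, 1] <- -0.5
  expect_equal(penalty_value(pars, penalty_weights(2, 0, 0)), 1.0)
  pars$beta[1, 2] <- pars$beta[2, 1] <- 0
  pars$rho[1:4, 1] <- c(1, -1, 1, -1)
  expect_equal(penalty_value(pars, penalty_weights(0, 1, 0)), 2.0)
  # dd block and the diagonal are not double counted
  pars$rho[1:4, 1] <- 0
  pars$phi[1:4, 5:8] <- 0.5
  pars$phi[5:8, 1:4] <- 0.5
  expect_equal(penalty_value(pars, penalty_weights(0, 0, 1)),
               sqrt(16 * 0.25))
  diag(pars$beta) <- 100   # never penalized
  expect_equal(penalty_value(pars, penalty_weights(1, 0, 0)), 0)
})
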