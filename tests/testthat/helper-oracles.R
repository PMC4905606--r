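# Independent brute-force oracles used across the test files.  These are
# deliberately naive (scalar loops, direct formula transcription) and do not
# reuse the package's vectorized internals.

# exponent of the joint density, term-by-term:
#   sum_{s,t} -1/2 beta_st x_s x_t + sum_s alpha_s x_s
# + sum_{s,j} rho_sj(y_j) x_s + sum_{r<=j} phi_rj(y_r, y_j)
naive_log_density <- function(params, x, y) {
  p <- length(params$alpha); q <- length(params$levels)
  offs <- c(0L, cumsum(params$levels))
  val <- 0
  for (s in seq_len(p)) for (t in seq_len(p))
    val <- val - 0.5 * params$beta[s, t] * x[s] * x[t]
  for (s in seq_len(p)) val <- val + params$alpha[s] * x[s]
  for (s in seq_len(p)) for (j in seq_len(q))
    val <- val + params$rho[offs[j] + y[j], s] * x[s]
  for (j in seq_len(q)) for (r in seq_len(j))
    val <- val + params$phi[offs[r] + y[r], offs[j] + y[j]]
  val
}

# categorical conditional by renormalizing the joint over the levels of r
naive_cat_conditional <- function(params, r, x, y) {
  L <- params$levels[r]
  lp <- vapply(seq_len(L), function(k) {
    yk <- y; yk[r] <- k
    naive_log_density(params, x, yk)
  }, numeric(1))
  e <- exp(lp - max(lp))
  e / sum(e)
}

# negative log-pseudolikelihood, one sample and one conditional at a time
naive_nlpl <- function(params, data) {
  p <- data$p; q <- data$q
  offs <- c(0L, cumsum(params$levels))
  total <- 0
  for (i in seq_len(data$n)) {
    x <- if (p > 0) data$X[i, ] else numeric(0)
    y <- if (q > 0) data$Y[i, ] else integer(0)
    for (s in seq_len(p)) {
      bss <- params$beta[s, s]
      num <- params$alpha[s]
      for (j in seq_len(q)) num <- num + params$rho[offs[j] + y[j], s]
      for (t in seq_len(p)) if (t != s) num <- num - params$beta[s, t] * x[t]
      total <- total - dnorm(x[s], num / bss, sqrt(1 / bss), log = TRUE)
    }
    for (r in seq_len(q)) {
      pr <- naive_cat_conditional(params, r, x, y)
      total <- total - log(pr[y[r]])
    }
  }
  unname(total)
}

# penalized objective on the fitting scale (used as the optim target)
naive_objective <- function(params, data, pen) {
  off <- params$beta; diag(off) <- 0
  penv <- pen$lambda_cc * sum(abs(off[upper.tri(off)]))
  offs <- c(0L, cumsum(params$levels))
  for (j in seq_len(data$q)) for (s in seq_len(data$p))
    penv <- penv + pen$lambda_cd *
      sqrt(sum(params$rho[offs[j] + 1:params$levels[j], s]^2))
  for (j in seq_len(data$q)) for (r in seq_len(j - 1))
    penv <- penv + pen$lambda_dd *
      sqrt(sum(params$phi[offs[r] + 1:params$levels[r],
                          offs[j] + 1:params$levels[j]]^2))
  naive_nlpl(params, data) / data$n + penv
}

# random valid parameters; blocks are left uncentered unless asked
random_params <- function(p, levels, seed, scale = 0.4, centered = FALSE) {
  withr::with_seed(seed, {
    totL <- sum(levels)
    beta <- matrix(rnorm(p * p, sd = scale), p, p)
    beta <- (beta + t(beta)) / 2
    diag(beta) <- abs(diag(beta)) + p * scale + 1
    rho <- matrix(rnorm(totL * p, sd = scale), totL, p)
    phi <- matrix(0, totL, totL)
    offs <- c(0L, cumsum(levels))
    for (j in seq_along(levels)) {
      for (r in seq_len(j - 1)) {
        B <- matrix(rnorm(levels[r] * levels[j], sd = scale),
                    levels[r], levels[j])
        phi[offs[r] + 1:levels[r], offs[j] + 1:levels[j]] <- B
        phi[offs[j] + 1:levels[j], offs[r] + 1:levels[r]] <- t(B)
      }
      d <- rnorm(levels[j], sd = scale)
      phi[offs[j] + 1:levels[j], offs[j] + 1:levels[j]] <- diag(d, levels[j])
    }
    pars <- mgm_params(beta, rnorm(p, sd = scale), rho, phi, levels)
    if (centered) {
      for (j in seq_along(levels)) for (s in seq_len(p)) {
        idx <- offs[j] + 1:levels[j]
        pars$rho[idx, s] <- pars$rho[idx, s] - mean(pars$rho[idx, s])
      }
    }
    pars
  })
}

random_mixed_data <- function(n, p, levels, seed) {
  withr::with_seed(seed, {
    X <- if (p > 0) matrix(rnorm(n * p), n, p) else NULL
    Y <- if (length(levels) > 0)
      sapply(levels, function(L) sample.int(L, n, replace = TRUE)) else NULL
    if (!is.null(Y)) Y <- matrix(Y, n, length(levels))
    mixed_data(X = X, Y = Y, levels = levels)
  })
}

# small simulated network + dataset reused by several selection tests
small_sim <- function(p = 6L, q = 6L, n = 150L, seed = 7L, linear = FALSE) {
  g <- generate_scale_free_network(p + q, seed = seed)
  m <- assign_parameters(g, p, q, levels = 3L, linear = linear,
                         seed = seed + 1L)
  d <- sample_dataset(m, n, burnin = 100L, thin = 5L, seed = seed + 2L)
  list(graph = g, model = m, data = d,
       truth = adjacency_from_parameters(m$params))
}
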