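test_that("two nodes yield the single mandatory edge", {
  g <- generate_scale_free_network(2L, seed = 1L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$degree, c(1L, 1L))
})

test_that("generated graphs are connected-by-degree, simple and loop-free", {
  for (seed in 1:20) {
    g <- generate_scale_free_network(30L, seed = seed)
    expect_true(all(g$degree >= 1L))
    expect_true(all(g$edges[, 1] < g$edges[, 2]))
    keys <- paste(g$edges[, 1], g$edges[, 2])
    expect_equal(anyDuplicated(keys), 0L)
    expect_equal(as.integer(table(factor(c(g$edges), levels = 1:30))),
                 g$degree)
  }
})

test_that("edge counts and degree tails match the growth process", {
  # 98 of 100 nodes start isolated and each addition attaches one with
  # probability 0.7, so the expected number of additions is 98 / 0.7 = 140
  # (plus the seed edge); allow Monte-Carlo slack around that mean
  stats <- t(vapply(1:300, function(seed) {
    g <- generate_scale_free_network(100L, seed = 3000L + seed)
    c(m = nrow(g$edges), max_deg = max(g$degree),
      med_deg = median(g$degree))
  }, numeric(3)))
  expect_gt(mean(stats[, "m"]), 130)
  expect_lt(mean(stats[, "m"]), 152)
  # heavy tail: hubs far above the median degree
  expect_gt(mean(stats[, "max_deg"] / stats[, "med_deg"]), 4)
})

test_that("parameter assignment follows the linear patterns", {
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L))  # cc, cd, dd with p=q=2
  graph <- structure(list(n_nodes = 4L, edges = edges,
                          degree = c(2L, 1L, 2L, 1L)),
                     class = "scale_free_graph")
  m <- assign_parameters(graph, 2L, 2L, levels = 4L, linear = TRUE, seed = 5L)
  w <- m$weights
  expect_equal(w$type, c("cc", "cd", "dd"))
  expect_true(all(w$w >= 0.5 & w$w <= 0.8))
  expect_equal(abs(m$params$beta[1, 2]), w$w[1])
  expect_equal(rho_block(m$params, 1, 1), w$w[2] * c(-1, -0.5, 0.5, 1))
  B <- phi_block(m$params, 1, 2)
  expect_equal(diag(B), rep(w$w[3], 4))
  expect_equal(B[upper.tri(B) | lower.tri(B)], rep(-w$w[3], 12))
  # unconnected pairs carry zeros; connected carry non-zeros
  expect_equal(adjacency_from_parameters(m$params)[upper.tri(diag(4))],
               c(1L, 1L, 0L, 0L, 0L, 1L))
})

test_that("non-linear patterns are permutations with full weight support", {
  edges <- rbind(c(1L, 2L), c(2L, 3L))              # cd, dd with p=1, q=2
  graph <- structure(list(n_nodes = 3L, edges = edges,
                          degree = c(1L, 2L, 1L)),
                     class = "scale_free_graph")
  m <- assign_parameters(graph, 1L, 2L, levels = 4L, linear = FALSE,
                         seed = 11L)
  w <- m$weights$w
  v <- rho_block(m$params, 1, 1)
  expect_equal(sort(v), sort(w[1] * c(-1, -0.5, 0.5, 1)))
  B <- phi_block(m$params, 1, 2)
  expect_true(all(rowSums(B == w[2]) == 1))         # one +w per row
  expect_true(all(colSums(B == w[2]) == 1))         # ... and per column
  expect_true(all(B %in% c(w[2], -w[2])))
})

test_that("the generating precision matrix is positive definite", {
  for (seed in c(3, 17, 31)) {
    g <- generate_scale_free_network(40L, seed = seed)
    for (rule in c("per_node", "global")) {
      m <- assign_parameters(g, 20L, 20L, seed = seed + 1L, diag_rule = rule)
      ev <- eigen(m$params$beta, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("sampler margins are correct in the independence case", {
  pars <- mgm_params_init(2L, c(4L, 4L))            # no edges at all
  d <- sample_dataset(pars, 2000L, seed = 21L)
  expect_lt(max(abs(colMeans(d$X))), 0.05)
  expect_lt(max(abs(apply(d$X, 2, sd) - 1)), 0.06)
  for (j in 1:2) {
    counts <- tabulate(d$Y[, j], 4L)
    # 3-sigma multinomial band around n/4
    expect_true(all(abs(counts - 500) < 3 * sqrt(2000 * 0.25 * 0.75)))
  }
})

test_that("a two-node Gaussian model reproduces its implied correlation", {
  graph <- structure(list(n_nodes = 2L, edges = rbind(c(1L, 2L)),
                          degree = c(1L, 1L)),
                     class = "scale_free_graph")
  m <- assign_parameters(graph, 2L, 0L, seed = 31L)
  m$params$beta[1, 2] <- m$params$beta[2, 1] <- -0.6
  implied <- 0.6 / sqrt(prod(diag(m$params$beta)))
  d <- sample_dataset(m, 5000L, seed = 32L)
  expect_lt(abs(cor(d$X)[1, 2] - implied), 0.05)
})

test_that("sampling is reproducible from the seed", {
  sim <- small_sim(seed = 171)
  d1 <- sample_dataset(sim$model, 50L, seed = 9L)
  d2 <- sample_dataset(sim$model, 50L, seed = 9L)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$Y, d2$Y)
})

test_that("true parameters beat perturbed ones in pseudolikelihood", {
  sim <- small_sim(p = 4L, q = 4L, n = 400L, seed = 181)
  truth <- sim$model$params
  noisy <- truth
  noisy$rho <- truth$rho + withr::with_seed(5, matrix(
    rnorm(length(truth$rho), sd = 0.3), nrow(truth$rho)))
  expect_lt(negative_log_pseudolikelihood(truth, sim$data),
            negative_log_pseudolikelihood(noisy, sim$data))
})

test_that("the benchmark simulator pairs variants on a shared graph", {
  cfg <- sim_config(networks = 1L, p = 4L, q = 4L, n = 30L, seed = 77L)
  out <- simulate_benchmark(cfg)
  expect_length(out, 2L)
  expect_identical(out[[1]]$truth, out[[2]]$truth)
  expect_true(out[[1]]$linear)
  expect_false(out[[2]]$linear)
  expect_equal(out[[1]]$dataset$n, 30L)
  expect_length(simulate_benchmark(sim_config(networks = 0L)), 0L)
  # deterministic end to end
  out2 <- simulate_benchmark(cfg)
  expect_identical(out[[2]]$dataset$X, out2[[2]]$dataset$X)
})
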