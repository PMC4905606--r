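# construct a synthetic instability profile without any fitting
fake_profile <- function(lambdas, dhat_by_type, p = 4L, q = 4L) {
  dbar <- as.data.frame(lapply(dhat_by_type, cummax))
  structure(list(lambdas = lambdas,
                 dhat = cbind(data.frame(lambda = lambdas),
                              as.data.frame(dhat_by_type)),
                 dbar = cbind(data.frame(lambda = lambdas), dbar),
                 p = p, q = q, N = 20L, b = 10L, n_fits = 0L),
            class = "instability_profile")
}

test_that("subsample draws have the documented size and are reproducible", {
  idx <- draw_subsamples(500L, N = 20L, seed = 1L)
  expect_equal(dim(idx), c(20L, 223L))          # floor(10 * sqrt(500))
  expect_true(all(apply(idx, 1, function(r) !anyDuplicated(r))))
  expect_equal(idx, draw_subsamples(500L, N = 20L, seed = 1L))
  # b = n degenerates to the full index set
  full <- draw_subsamples(100L, N = 2L, b = 100L, seed = 2L)
  expect_equal(sort(full[1, ]), 1:100)
  expect_error(draw_subsamples(10L, N = 2L, b = 11L), "exceeds")
})

test_that("edge frequency and instability follow their formulas", {
  A1 <- matrix(c(0, 1, 1, 0), 2, 2)
  A0 <- matrix(0, 2, 2)
  expect_equal(edge_frequency(rep(list(A1), 5))[1, 2], 1)
  expect_equal(edge_frequency(c(rep(list(A1), 10), rep(list(A0), 10)))[1, 2],
               0.5)
  adjs <- withr::with_seed(3, lapply(1:7, function(i) {
    A <- matrix(rbinom(16, 1, 0.5), 4, 4); A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0; A
  }))
  theta <- edge_frequency(adjs)
  direct <- Reduce(`+`, adjs) / 7
  expect_equal(theta, direct)
  expect_equal(edge_instability(0), 0)
  expect_equal(edge_instability(1), 0)
  expect_equal(edge_instability(0.5), 0.5)
  expect_equal(edge_instability(0.25), 0.375)
})

test_that("total instability uses the edge-class denominators", {
  p <- 2L; q <- 2L
  xi <- matrix(0, 4, 4)
  expect_equal(total_instability(xi, "all", p, q), 0)
  expect_equal(total_instability(xi, "dd", p, q), 0)
  xi[1, 3] <- xi[3, 1] <- 0.5                   # one cd pair
  expect_equal(total_instability(xi, "cd", p, q), 0.125)
  expect_equal(total_instability(xi, "all", p, q), 0.5 / 6)
  expect_error(total_instability(xi, "cc", 1L, 3L), "empty")
  # random xi vs masked-mean oracle
  xi <- withr::with_seed(4, {m <- matrix(runif(16, 0, .5), 4, 4); (m + t(m)) / 2})
  diag(xi) <- 0
  manual <- (xi[1, 3] + xi[1, 4] + xi[2, 3] + xi[2, 4]) / 4
  expect_equal(total_instability(xi, "cd", p, q), manual)
  expect_equal(total_instability(xi, "cc", p, q), xi[1, 2])
})

test_that("monotonization is the running supremum over larger penalties", {
  lam <- c(0.64, 0.32, 0.16)
  expect_equal(monotonize(c(0.01, 0.08, 0.04), lam), c(0.01, 0.08, 0.08))
  expect_equal(monotonize(c(0.01, 0.02, 0.05), lam), c(0.01, 0.02, 0.05))
  expect_equal(monotonize(rep(0.03, 3), lam), rep(0.03, 3))
  expect_error(monotonize(c(0.1, 0.2), c(0.16, 0.32)), "decreasing")
})

test_that("the single-penalty threshold rule picks the smallest stable lambda", {
  lam <- c(0.64, 0.32, 0.16)
  prof <- fake_profile(lam, list(all = c(0, 0, 0), cc = c(0, 0, 0),
                                 cd = c(0, 0, 0), dd = c(0, 0, 0)))
  expect_equal(stars_select(prof, 0.05), 0.16)
  prof <- fake_profile(lam, list(all = c(.01, .04, .06), cc = c(.01, .04, .06),
                                 cd = c(.01, .04, .06), dd = c(.01, .04, .06)))
  expect_equal(stars_select(prof, 0.05), 0.32)
  expect_warning(out <- stars_select(prof, 0), "largest")
  expect_equal(out, 0.64)
})

test_that("edge-type-specific selection separates the three penalties", {
  lam <- c(0.64, 0.32, 0.16)
  # cc stabilizes late (high instability at small lambda), dd early
  prof <- fake_profile(lam, list(all = c(.01, .03, .08),
                                 cc = c(.02, .08, .20),
                                 cd = c(.01, .04, .07),
                                 dd = c(.00, .01, .02)))
  expect_equal(stars_select(prof, 0.05, "cc"), 0.64)
  expect_equal(stars_select(prof, 0.05, "cd"), 0.32)
  expect_equal(stars_select(prof, 0.05, "dd"), 0.16)
  sim <- small_sim(p = 3L, q = 3L, n = 80L, seed = 101)
  sel <- steps_select(sim$data, profile = prof)
  expect_equal(unname(sel$lambda), c(0.64, 0.32, 0.16))
  expect_s3_class(sel$params, "mgm_params")
  # degenerate case: identical profiles per type -> all three equal
  prof2 <- fake_profile(lam, list(all = c(.01, .04, .06), cc = c(.01, .04, .06),
                                  cd = c(.01, .04, .06), dd = c(.01, .04, .06)))
  sel2 <- steps_select(sim$data, profile = prof2)
  expect_true(all(sel2$lambda == 0.32))
})

test_that("the subsampling ensemble performs exactly N x G fits", {
  sim <- small_sim(p = 3L, q = 3L, n = 80L, seed = 111)
  grid <- lambda_grid(c(0.5, 0.25, 0.12))
  prof <- stability_profile(sim$data, grid, N = 4L, seed = 5L)
  expect_equal(prof$n_fits, 4L * 3L)
  expect_true(all(diff(prof$dbar$all) >= 0))     # non-increasing in lambda
  expect_true(all(prof$dhat$all >= 0 & prof$dhat$all <= 0.5))
  sel <- steps_select(sim$data, grid, N = 4L, seed = 5L)
  expect_equal(sel$n_fits, 4L * 3L + 1L)
})

test_that("3-D monotonization equals the brute-force orthant supremum", {
  a <- withr::with_seed(6, array(runif(27), dim = c(3, 3, 3)))
  m <- mgmsteps:::monotonize_3d(a)
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_equal(m[i, j, k], max(a[1:i, 1:j, 1:k, drop = FALSE]))
  # idempotent
  expect_equal(mgmsteps:::monotonize_3d(m), m)
})

test_that("cubic stability search selects feasible settings with most edges", {
  sim <- small_sim(p = 3L, q = 3L, n = 80L, seed = 121)
  g1 <- lambda_grid(0.3, mode = "triple")
  sel1 <- cubic_stability_select(sim$data, g1, N = 3L, seed = 7L)
  expect_equal(unname(sel1$lambda), c(0.3, 0.3, 0.3))
  expect_equal(sel1$n_fits, 3L * 1L + 1L)
  g2 <- lambda_grid(c(0.4, 0.2), mode = "triple")
  sel2 <- cubic_stability_select(sim$data, g2, N = 3L, seed = 8L)
  expect_equal(sel2$n_fits, 3L * 8L + 1L)
  # the returned setting must match an exhaustive scan of the reported arrays
  feas <- sel2$feasible
  if (any(feas)) {
    best <- max(sel2$edge_totals[feas])
    pick <- which(feas & sel2$edge_totals == best)
    expect_true(all(as.numeric(sel2$lambda) ==
                      as.numeric(sel2$candidates[
                        mgmsteps:::best_candidate(
                          sel2$candidates,
                          ifelse(feas, -sel2$edge_totals, Inf)), ])))
    expect_true(any(vapply(pick, function(m)
      all(as.numeric(sel2$candidates[m, ]) == as.numeric(sel2$lambda)),
      logical(1))))
  }
})
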