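#' Simulation settings for the scale-free mixed-network benchmark
#'
#' Defaults reproduce the benchmark conditions: 20 scale-free networks of
#' 100 nodes (50 continuous + 50 four-level categorical), 500 samples per
#' dataset, edge weights drawn uniformly from `[0.5, 0.8]`, and an edge
#' growth process that connects two already-connected nodes with
#' probability 0.3 (otherwise attaching an isolated node), endpoints
#' chosen with probability proportional to degree.
#'
#' @param networks number of networks to generate.
#' @param p,q numbers of continuous and categorical variables.
#' @param levels number of levels per categorical variable.
#' @param n samples per dataset.
#' @param variants which interaction parameterizations to draw per
#'   network: subset of `c("linear", "nonlinear")`.
#' @param attach_prob probability of connecting two non-isolated nodes at
#'   each edge addition (isolated-node attachment has the complementary
#'   probability).
#' @param weight_range range of the uniform edge-weight draw.
#' @param burnin,thin Gibbs sampler settings (sweeps).
#' @param seed master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(networks = 20L, p = 50L, q = 50L, levels = 4L,
                       n = 500L, variants = c("linear", "nonlinear"),
                       attach_prob = 0.3, weight_range = c(0.5, 0.8),
                       burnin = 200L, thin = 10L, seed = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (attach_prob < 0 || attach_prob > 1) stop("attach_prob must be in [0, 1]")
  if (diff(weight_range) < 0 || any(weight_range <= 0))
    stop("invalid weight range")
  structure(list(networks = as.integer(networks), p = as.integer(p),
                 q = as.integer(q), levels = as.integer(levels),
                 n = as.integer(n), variants = variants,
                 attach_prob = attach_prob, weight_range = weight_range,
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = seed),
            class = "sim_config")
}

#' Generate a scale-free network by degree-proportional edge growth
#'
#' Starts from a single edge between two random nodes and adds edges until
#' every node has degree at least 1.  Each addition either connects two
#' non-isolated nodes (probability `attach_prob`, default 0.3) or attaches
#' a still-isolated node to a non-isolated one (probability
#' `1 - attach_prob`); non-isolated endpoints are drawn with probability
#' proportional to their current degree.  Draws that would duplicate an
#' edge or form a self-loop are rejected and redrawn.
#'
#' @param num_nodes number of nodes (at least 2).
#' @param seed integer seed.
#' @param attach_prob probability of the connect-two-connected-nodes move.
#' @return An object of class `scale_free_graph`: list with `n_nodes`,
#'   `edges` (m x 2 matrix, first column < second) and `degree`.
#' @export
generate_scale_free_network <- function(num_nodes, seed = NULL,
                                        attach_prob = 0.3) {
  if (num_nodes < 2) stop("need at least 2 nodes")
  gen <- function() {
    degree <- integer(num_nodes)
    first <- sample.int(num_nodes, 2)
    edges <- matrix(sort(first), 1, 2)
    degree[first] <- 1L
    has_edge <- new.env(hash = TRUE)
    assign(paste(sort(first), collapse = "-"), TRUE, envir = has_edge)
    pick_by_degree <- function(exclude = 0L) {
      w <- degree
      if (exclude > 0L) w[exclude] <- 0L
      sample.int(num_nodes, 1, prob = w)
    }
    while (any(degree == 0L)) {
      if (runif(1) < attach_prob) {
        # connect two already-connected nodes; duplicate draws are
        # rejected and redrawn.  When the connected subgraph is (nearly)
        # complete no new pair may exist, so after repeated rejections
        # fall back to attaching an isolated node instead.
        found <- FALSE
        for (try in 1:100) {
          a <- pick_by_degree()
          bnode <- pick_by_degree(exclude = a)
          key <- paste(min(a, bnode), max(a, bnode), sep = "-")
          if (!exists(key, envir = has_edge)) { found <- TRUE; break }
        }
        if (!found) {
          iso <- which(degree == 0L)
          a <- if (length(iso) == 1L) iso else iso[sample.int(length(iso), 1)]
          bnode <- pick_by_degree()
          key <- paste(min(a, bnode), max(a, bnode), sep = "-")
        }
      } else {
        iso <- which(degree == 0L)
        a <- if (length(iso) == 1L) iso else iso[sample.int(length(iso), 1)]
        bnode <- pick_by_degree()
        key <- paste(min(a, bnode), max(a, bnode), sep = "-")
      }
      assign(key, TRUE, envir = has_edge)
      edges <- rbind(edges, c(min(a, bnode), max(a, bnode)))
      degree[a] <- degree[a] + 1L
      degree[bnode] <- degree[bnode] + 1L
    }
    structure(list(n_nodes = as.integer(num_nodes), edges = edges,
                   degree = degree),
              class = "scale_free_graph")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Assign MGM interaction parameters to a network
#'
#' Nodes `1..p` become continuous, nodes `p+1..p+q` categorical (with
#' `levels` levels each).  Every edge draws a weight `w` uniformly from
#' `weight_range`.  Continuous-continuous edges get `beta_st = +/- w` with
#' even sign probability; each beta diagonal entry is set to the node's
#' summed absolute incident cc weights plus a dominance margin (see
#' `diag_rule`), making beta strictly diagonally dominant and hence
#' positive definite.  Continuous-discrete edges get
#' `rho = w * (-1, -.5, .5, 1)` in the linear parameterization and a
#' random permutation of it otherwise.  Discrete-discrete edges get a
#' block with `w` on the diagonal and `-w` elsewhere (linear) or `w` on a
#' random permutation-matrix pattern and `-w` elsewhere (non-linear).
#' Intercepts (`alpha`, within-variable `phi`) are zero.
#'
#' @param graph a [generate_scale_free_network()] result with
#'   `p + q` nodes.
#' @param p,q numbers of continuous and categorical variables.
#' @param levels levels per categorical variable (scalar).
#' @param linear use the linear interaction parameterization.
#' @param weight_range uniform range of edge weights.
#' @param seed integer seed.
#' @param diag_rule `"per_node"` (default): each node's own absolute
#'   incident cc weight sum plus margin; `"global"`: one shared diagonal
#'   value, the maximum of those row sums plus margin.  Both are strictly
#'   diagonally dominant; the per-node rule yields conditional
#'   dependencies strong enough to be recovered at realistic sample
#'   sizes, while the global rule dampens every interaction by the
#'   largest hub's total weight.
#' @param diag_margin additive diagonal dominance margin (default 1).
#' @return An object of class `ground_truth`: list with `params` (an
#'   [mgm_params] holding the generating model), `weights` (edge table
#'   with columns `i`, `j`, `type`, `w`), `graph`, `linear`.
#' @export
assign_parameters <- function(graph, p, q, levels = 4L, linear = TRUE,
                              weight_range = c(0.5, 0.8), seed = NULL,
                              diag_rule = c("per_node", "global"),
                              diag_margin = 1) {
  diag_rule <- match.arg(diag_rule)
  if (graph$n_nodes != p + q) stop("graph size must equal p + q")
  gen <- function() {
    L <- as.integer(levels)
    totL <- q * L
    offs <- level_offsets(rep(L, q))
    beta <- matrix(0, p, p)
    rho <- matrix(0, totL, p)
    phi <- matrix(0, totL, totL)
    m <- nrow(graph$edges)
    w <- runif(m, weight_range[1], weight_range[2])
    type <- character(m)
    base <- c(-1, -0.5, 0.5, 1)
    if (L != 4L) {
      # evenly spaced, zero-sum ramp generalizing the 4-level pattern
      base <- seq(-1, 1, length.out = L)
      base <- base - mean(base)
    }
    for (e in seq_len(m)) {
      a <- graph$edges[e, 1]; bnode <- graph$edges[e, 2]
      if (bnode <= p) {
        type[e] <- "cc"
        sgn <- if (runif(1) < 0.5) 1 else -1
        beta[a, bnode] <- beta[bnode, a] <- sgn * w[e]
      } else if (a <= p) {
        type[e] <- "cd"
        j <- bnode - p
        v <- w[e] * base
        if (!linear) v <- v[sample.int(L)]
        rho[offs[j] + seq_len(L), a] <- v
      } else {
        type[e] <- "dd"
        r <- a - p; j <- bnode - p
        B <- matrix(-w[e], L, L)
        if (linear) {
          diag(B) <- w[e]
        } else {
          perm <- sample.int(L)
          B[cbind(seq_len(L), perm)] <- w[e]
        }
        ri <- offs[r] + seq_len(L); ci <- offs[j] + seq_len(L)
        phi[ri, ci] <- B
        phi[ci, ri] <- t(B)
      }
    }
    if (p > 0) {
      rowsum_abs <- rowSums(abs(beta))
      diag(beta) <- if (diag_rule == "global")
        max(rowsum_abs, 0) + diag_margin else rowsum_abs + diag_margin
    }
    params <- mgm_params(beta = beta, alpha = rep(0, p), rho = rho,
                         phi = phi, levels = rep(L, q))
    structure(list(params = params,
                   weights = data.frame(i = graph$edges[, 1],
                                        j = graph$edges[, 2],
                                        type = type, w = w),
                   graph = graph, linear = linear),
              class = "ground_truth")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Draw samples from a ground-truth MGM by Gibbs sampling
#'
#' Systematic-scan Gibbs sampling from the model's Gaussian and softmax
#' full conditionals, initialized at `x = 0`, `y = ` level 1.  After
#' `burnin` full sweeps one sample is retained every `thin` sweeps.
#'
#' @param model a [ground_truth][assign_parameters] object or an
#'   [mgm_params] with positive-definite beta.
#' @param n number of retained samples.
#' @param burnin burn-in sweeps (default 200).
#' @param thin sweeps between retained samples (default 10).
#' @param seed integer seed; same seed, same dataset.
#' @return A [mixed_data] with `n` rows.
#' @export
sample_dataset <- function(model, n, burnin = 200L, thin = 10L,
                           seed = NULL) {
  params <- if (inherits(model, "ground_truth")) model$params else model
  p <- length(params$alpha)
  if (p > 0) {
    ev <- min(eigen(params$beta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("beta must be positive definite to sample")
  }
  gen <- function() {
    res <- cpp_gibbs(params$beta, params$alpha, params$rho, params$phi,
                     params$levels, as.integer(n), as.integer(burnin),
                     as.integer(thin))
    X <- res$X; colnames(X) <- params$cont_names
    Y <- res$Y; colnames(Y) <- params$cat_names
    mixed_data(X = X, Y = Y, levels = params$levels)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate the full mixed-network benchmark
#'
#' For each configured network, generates a scale-free graph, assigns a
#' linear and/or a non-linear parameterization sharing the same edge set,
#' and draws a dataset from each by Gibbs sampling.  All randomness
#' derives from the master seed.
#'
#' @param config a [sim_config] object.
#' @param outdir optional directory: datasets are written as mixed tables
#'   and truths as edge lists.
#' @return A list with one entry per (network, variant): each a list with
#'   `dataset` (a [mixed_data]), `truth` (the true adjacency matrix),
#'   `model` (the [ground_truth][assign_parameters]), `network`, `linear`.
#' @export
simulate_benchmark <- function(config = sim_config(), outdir = NULL) {
  if (config$networks == 0L) return(list())
  seeds <- derive_seeds(config$seed, 3L * config$networks)
  out <- list()
  for (k in seq_len(config$networks)) {
    graph <- generate_scale_free_network(config$p + config$q,
                                         seed = seeds[3 * k - 2],
                                         attach_prob = config$attach_prob)
    for (variant in config$variants) {
      linear <- variant == "linear"
      model <- assign_parameters(graph, config$p, config$q, config$levels,
                                 linear = linear,
                                 weight_range = config$weight_range,
                                 seed = seeds[3 * k - 1])
      dataset <- sample_dataset(model, config$n, config$burnin,
                                config$thin,
                                seed = seeds[3 * k] + (!linear))
      entry <- list(dataset = dataset,
                    truth = adjacency_from_parameters(model$params),
                    model = model, network = k, linear = linear)
      out[[length(out) + 1L]] <- entry
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        stem <- file.path(outdir, sprintf("network%02d_%s", k, variant))
        write_mixed_table(dataset, paste0(stem, "_data.tsv"))
        write_edge_list(model$params, paste0(stem, "_truth.tsv"))
      }
    }
  }
  out
}

# spawn per-task integer seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max, k))
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}
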