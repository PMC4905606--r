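#' Draw subsample index sets for stability selection
#'
#' Draws `N` subsamples of size `b` without replacement.  The default
#' subsample size is `b = floor(10 * sqrt(n))` (capped at `n`), the
#' standard choice for stability selection on networks.
#'
#' @param n number of samples.
#' @param N number of subsamples (default 20).
#' @param b subsample size; defaults to `floor(10 * sqrt(n))`.
#' @param seed integer seed; same seed, same index sets.
#' @return An `N` x `b` integer matrix of sample indices, one subsample per
#'   row.
#' @export
draw_subsamples <- function(n, N = 20L, b = NULL, seed = NULL) {
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), n)
  b <- as.integer(b)
  if (b > n) stop("subsample size b exceeds n")
  if (N < 2) stop("need at least 2 subsamples")
  draw <- function() t(vapply(seq_len(N), function(i) sample.int(n, b),
                              integer(b)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Edge frequencies across an ensemble of adjacency matrices
#'
#' @param adjacencies list of equally sized binary adjacency matrices.
#' @return Matrix of edge frequencies theta-hat (elementwise mean).
#' @export
edge_frequency <- function(adjacencies) {
  if (length(adjacencies) < 1) stop("need at least one adjacency")
  Reduce(`+`, adjacencies) / length(adjacencies)
}

#' Edge instability from edge frequencies
#'
#' The probability that two independently drawn subsample graphs disagree
#' on an edge: `xi = 2 * theta * (1 - theta)`, maximized (0.5) at
#' `theta = 0.5` and zero for edges that always or never appear.
#'
#' @param theta matrix (or vector) of edge frequencies in `[0, 1]`.
#' @return Same shape as `theta`.
#' @export
edge_instability <- function(theta) 2 * theta * (1 - theta)

#' Total instability over an edge class
#'
#' Mean edge instability over the unordered pairs of the requested type,
#' with denominators `choose(p+q, 2)` (all), `choose(p, 2)` (cc), `p * q`
#' (cd) and `choose(q, 2)` (dd).
#'
#' @param xi (p+q) x (p+q) matrix of edge instabilities (rows/cols ordered
#'   continuous first).
#' @param edge_type one of `"all"`, `"cc"`, `"cd"`, `"dd"`.
#' @param p,q numbers of continuous and categorical variables.
#' @return Scalar mean instability.
#' @export
total_instability <- function(xi, edge_type = c("all", "cc", "cd", "dd"),
                              p, q) {
  edge_type <- match.arg(edge_type)
  denom <- switch(edge_type,
                  all = choose(p + q, 2), cc = choose(p, 2),
                  cd = p * q, dd = choose(q, 2))
  if (denom == 0)
    stop(sprintf("edge class '%s' is empty for p=%d, q=%d", edge_type, p, q))
  et <- edge_type_matrix(p, q)
  up <- upper.tri(xi)
  keep <- if (edge_type == "all") up else up & et == edge_type
  sum(xi[keep]) / denom
}

#' Monotonize an instability curve
#'
#' Replaces D-hat by its running supremum over all larger penalties:
#' `Dbar(lambda) = max of Dhat(t) over grid values t >= lambda`, making
#' the curve non-increasing in lambda so that thresholding it is
#' well-defined even when very small penalties yield dense-but-stable
#' graphs.
#'
#' @param dhat numeric vector of instabilities ordered by strictly
#'   decreasing lambda.
#' @param lambdas optional matching penalty values (checked for decreasing
#'   order).
#' @return The monotonized vector Dbar, same order.
#' @export
monotonize <- function(dhat, lambdas = NULL) {
  if (!is.null(lambdas) && is.unsorted(rev(lambdas), strictly = TRUE))
    stop("lambdas must be strictly decreasing")
  cummax(dhat)
}

#' Subsampling instability profile over a penalty grid
#'
#' Learns one single-penalty MGM per (subsample, lambda) pair -- warm
#' started down the grid within each subsample -- and records, per lambda:
#' edge frequencies theta-hat, edge instabilities xi-hat, total
#' instabilities D-hat overall and per edge type, their monotonized
#' versions, and the total number of predicted edges across the subsample
#' networks.  This single ensemble supports both single-penalty stability
#' selection and the edge-type-specific StEPS search.
#'
#' @param data a [mixed_data] object.
#' @param grid a single-mode [lambda_grid].
#' @param N number of subsamples.
#' @param b subsample size (default `floor(10 * sqrt(n))`).
#' @param config a [fit_config].
#' @param seed integer seed for the subsample draw.
#' @return An object of class `instability_profile` with fields `lambdas`,
#'   `theta` (list of matrices), `xi` (list of matrices), `dhat` and `dbar`
#'   (data frames with columns `lambda`, `all`, `cc`, `cd`, `dd`),
#'   `edge_counts` (per-lambda totals over subsample networks, split by
#'   type), `n_fits`, `N`, `b`, `p`, `q`.
#' @export
stability_profile <- function(data, grid, N = 20L, b = NULL,
                              config = fit_config(), seed = NULL) {
  if (grid$mode != "single")
    stop("stability_profile uses a single-mode grid")
  idx <- draw_subsamples(data$n, N, b, seed)
  N <- nrow(idx); b <- ncol(idx)
  lambdas <- grid$values
  G <- length(lambdas)
  tot <- data$p + data$q
  counts <- array(0, dim = c(tot, tot, G))
  et <- edge_type_matrix(data$p, data$q)
  up <- upper.tri(matrix(0, tot, tot))
  edge_counts <- matrix(0, G, 3,
                        dimnames = list(NULL, c("cc", "cd", "dd")))
  n_fits <- 0L
  for (i in seq_len(N)) {
    sub <- data[idx[i, ]]
    fd <- prepare_fit_data(sub, config$standardize)
    init <- NULL
    for (g in seq_len(G)) {
      fit <- fit_mgm_prepared(fd, penalty_weights(lambdas[g]), config, init)
      init <- fit
      n_fits <- n_fits + 1L
      A <- adjacency_from_parameters(fit)
      counts[, , g] <- counts[, , g] + A
      for (ty in c("cc", "cd", "dd"))
        edge_counts[g, ty] <- edge_counts[g, ty] + sum(A[up & et == ty])
    }
  }
  theta <- lapply(seq_len(G), function(g) counts[, , g] / N)
  xi <- lapply(theta, edge_instability)
  dh <- function(type) vapply(xi, function(x) {
    tryCatch(total_instability(x, type, data$p, data$q),
             error = function(e) NA_real_)
  }, numeric(1))
  dhat <- data.frame(lambda = lambdas, all = dh("all"), cc = dh("cc"),
                     cd = dh("cd"), dd = dh("dd"))
  dbar <- dhat
  for (cl in c("all", "cc", "cd", "dd"))
    if (!anyNA(dhat[[cl]])) dbar[[cl]] <- monotonize(dhat[[cl]], lambdas)
  structure(list(lambdas = lambdas, theta = theta, xi = xi,
                 dhat = dhat, dbar = dbar, edge_counts = edge_counts,
                 subsamples = idx, n_fits = n_fits, N = N, b = b,
                 p = data$p, q = data$q),
            class = "instability_profile")
}

#' @export
print.instability_profile <- function(x, ...) {
  cat(sprintf("instability_profile: %d lambdas x %d subsamples (b=%d), %d fits\n",
              length(x$lambdas), x$N, x$b, x$n_fits))
  print(x$dbar, row.names = FALSE)
  invisible(x)
}

# index of the selected lambda on a monotonized curve: smallest lambda
# whose Dbar stays at or below gamma, scanning from the largest down
stars_index <- function(dbar, gamma) {
  feasible <- dbar <= gamma
  if (!feasible[1]) return(NA_integer_)
  k <- 1L
  while (k < length(dbar) && feasible[k + 1L]) k <- k + 1L
  k
}

#' Single-penalty stability selection (StARS rule)
#'
#' Scans the monotonized total instability from the largest penalty down
#' and returns the smallest penalty for which it stays at or below the
#' instability threshold `gamma`.  If even the largest penalty exceeds the
#' threshold, the largest penalty is returned with a warning.  The final
#' model should be refit on all samples at the selected penalty (edge
#' prediction from the full-data fit outperforms predictions from
#' subsampled fits).
#'
#' @param profile an [stability_profile()] result.
#' @param gamma instability threshold (default 0.05).
#' @param edge_type which instability curve to threshold (default
#'   `"all"`).
#' @return The selected penalty value (scalar).
#' @export
stars_select <- function(profile, gamma = 0.05,
                         edge_type = c("all", "cc", "cd", "dd")) {
  edge_type <- match.arg(edge_type)
  dbar <- profile$dbar[[edge_type]]
  if (anyNA(dbar)) stop(sprintf("edge class '%s' is empty", edge_type))
  k <- stars_index(dbar, gamma)
  if (is.na(k)) {
    warning(sprintf("no penalty meets instability threshold %g for type '%s'; returning the largest",
                    gamma, edge_type))
    k <- 1L
  }
  profile$lambdas[k]
}

#' Stable Edge-specific Penalty Selection (StEPS)
#'
#' Selects the three edge-type penalties from a *single* shared-penalty
#' subsampling ensemble: one MGM is learned per (subsample, lambda) with
#' `lambda_cc = lambda_cd = lambda_dd = lambda`, the total instability is
#' computed separately for each edge type from the same ensemble, and the
#' StARS threshold rule is applied independently per type.  The search is
#' therefore linear (N x G fits) rather than cubic in the grid size.  The
#' returned model is refit on all samples with the three chosen penalties.
#'
#' @inheritParams stability_profile
#' @param gamma instability threshold (default 0.05).
#' @param profile optionally, a precomputed [stability_profile()] (its
#'   grid/ensemble settings take precedence).
#' @return An object of class `steps_selection`: a list with `penalties`
#'   (a [penalty_weights]), `lambda` (named vector), `params` (full-data
#'   refit), `profile` and `n_fits`.
#' @export
steps_select <- function(data, grid = lambda_grid(), N = 20L, b = NULL,
                         gamma = 0.05, config = fit_config(), seed = NULL,
                         profile = NULL) {
  if (is.null(profile))
    profile <- stability_profile(data, grid, N, b, config, seed)
  lam <- c(cc = stars_select(profile, gamma, "cc"),
           cd = stars_select(profile, gamma, "cd"),
           dd = stars_select(profile, gamma, "dd"))
  pen <- penalty_weights(lam[["cc"]], lam[["cd"]], lam[["dd"]])
  params <- fit_mgm(data, pen, config)
  structure(list(penalties = pen, lambda = lam, params = params,
                 profile = profile, gamma = gamma,
                 n_fits = profile$n_fits + 1L),
            class = "steps_selection")
}

#' @export
print.steps_selection <- function(x, ...) {
  cat(sprintf("steps_selection: lambda_cc=%g, lambda_cd=%g, lambda_dd=%g (gamma=%g, %d fits)\n",
              x$lambda[["cc"]], x$lambda[["cd"]], x$lambda[["dd"]],
              x$gamma, x$n_fits))
  invisible(x)
}

#' Cubic (three-dimensional) stability search
#'
#' The validity check for StEPS: learns one MGM per (subsample, penalty
#' triple) over the full Cartesian grid (`N * G^3` fits), computes total
#' instabilities as 3-D arrays, monotonizes them by running maxima along
#' each penalty dimension (iterated to a fixed point; the result is
#' order-independent), and among the feasible settings -- `pooled` rule:
#' monotonized overall instability at or below `gamma`; `per_type_max`
#' rule: the maximum of the three per-type monotonized instabilities at or
#' below `gamma` -- selects the one whose subsample networks carry the
#' most predicted edges in total.  Ties go to sparser penalties; if no
#' setting is feasible the most stable one is returned with a warning.
#'
#' @inheritParams steps_select
#' @param grid a triple-mode [lambda_grid].
#' @param rule `"per_type_max"` (default) or `"pooled"`.
#' @return An object of class `cubic_selection`: `penalties`, `lambda`,
#'   `params` (full-data refit), the instability arrays (`dhat`, `dbar`,
#'   per type and pooled), `edge_totals`, `feasible`, `n_fits`.
#' @export
cubic_stability_select <- function(data, grid, N = 20L, b = NULL,
                                   gamma = 0.05,
                                   rule = c("per_type_max", "pooled"),
                                   config = fit_config(), seed = NULL) {
  rule <- match.arg(rule)
  if (grid$mode != "triple")
    stop("cubic_stability_select needs a triple-mode grid")
  v <- grid$values
  G <- length(v)
  idx <- draw_subsamples(data$n, N, b, seed)
  N <- nrow(idx)
  tot <- data$p + data$q
  et <- edge_type_matrix(data$p, data$q)
  up <- upper.tri(matrix(0, tot, tot))
  masks <- list(cc = up & et == "cc", cd = up & et == "cd",
                dd = up & et == "dd")
  denom <- c(all = choose(tot, 2), cc = choose(data$p, 2),
             cd = data$p * data$q, dd = choose(data$q, 2))
  cand <- grid_candidates(grid)          # nested descending, dd innermost
  M <- nrow(cand)
  counts <- matrix(0, M, sum(up))        # per-candidate upper-tri frequency counts
  edge_totals <- numeric(M)
  n_fits <- 0L
  for (i in seq_len(N)) {
    sub <- data[idx[i, ]]
    fd <- prepare_fit_data(sub, config$standardize)
    init <- NULL
    for (m in seq_len(M)) {
      fit <- fit_mgm_prepared(fd, penalty_weights(as.numeric(cand[m, ])),
                              config, init)
      init <- fit
      n_fits <- n_fits + 1L
      A <- adjacency_from_parameters(fit)
      counts[m, ] <- counts[m, ] + A[up]
      edge_totals[m] <- edge_totals[m] + sum(A[up])
    }
  }
  theta <- counts / N
  xi <- 2 * theta * (1 - theta)
  dh <- function(mask, dn) rowSums(xi[, mask[up], drop = FALSE]) / dn
  dhat <- list(all = rowSums(xi) / denom[["all"]])
  for (ty in c("cc", "cd", "dd"))
    dhat[[ty]] <- if (denom[[ty]] > 0) dh(masks[[ty]], denom[[ty]]) else NULL
  # reshape to G x G x G arrays; candidate order is cc outer, cd, dd inner,
  # all descending, so dim = (dd, cd, cc) in column-major layout
  as_arr <- function(x) array(x, dim = c(G, G, G))
  dbar <- lapply(dhat, function(x) if (is.null(x)) NULL else
    monotonize_3d(as_arr(x)))
  feas_stat <- if (rule == "pooled") dbar$all else {
    per <- dbar[c("cc", "cd", "dd")]
    per <- per[!vapply(per, is.null, logical(1))]
    Reduce(pmax, per)
  }
  feasible <- as.numeric(feas_stat) <= gamma
  if (!any(feasible)) {
    warning("no penalty setting meets the instability threshold; returning the most stable")
    pick <- best_candidate(cand, as.numeric(feas_stat))
  } else {
    score <- ifelse(feasible, -edge_totals, Inf)
    pick <- best_candidate(cand, score)
  }
  pen <- penalty_weights(as.numeric(cand[pick, ]))
  params <- fit_mgm(data, pen, config)
  structure(list(penalties = pen,
                 lambda = c(cc = pen$lambda_cc, cd = pen$lambda_cd,
                            dd = pen$lambda_dd),
                 params = params, candidates = cand,
                 dhat = dhat, dbar = dbar, edge_totals = edge_totals,
                 feasible = feasible, rule = rule, gamma = gamma,
                 lambdas = v, n_fits = n_fits + 1L),
            class = "cubic_selection")
}

# running maximum over the descending-lambda upper orthant of a 3-D array,
# iterated along each dimension to a fixed point (one pass per dimension
# already realizes the orthant supremum; the loop verifies the fixed point)
monotonize_3d <- function(a) {
  run_max_dim <- function(a, d) {
    m <- setdiff(1:3, d)
    r <- apply(a, m, cummax)           # dims of r are c(d, m)
    dim(r) <- dim(a)[c(d, m)]          # apply() drops unit dimensions
    aperm(r, match(1:3, c(d, m)))
  }
  repeat {
    prev <- a
    for (d in 1:3) a <- run_max_dim(a, d)
    if (max(abs(a - prev)) == 0) break
  }
  a
}
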