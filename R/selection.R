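#' Penalty grid
#'
#' An ordered (strictly decreasing, strictly positive) list of penalty
#' values, used either as a shared single penalty or expanded to the full
#' Cartesian product of (lambda_cc, lambda_cd, lambda_dd) triples.
#'
#' @param values numeric vector of positive penalty values; sorted
#'   decreasing.  The default is the benchmark grid
#'   `c(.64, .32, .16, .08, .04)`.
#' @param mode `"single"` (shared penalty) or `"triple"` (full product).
#' @return An object of class `lambda_grid`.
#' @export
lambda_grid <- function(values = c(0.64, 0.32, 0.16, 0.08, 0.04),
                        mode = c("single", "triple")) {
  mode <- match.arg(mode)
  values <- sort(unique(as.numeric(values)), decreasing = TRUE)
  if (any(values <= 0)) stop("penalty values must be strictly positive")
  if (length(values) < 1) stop("empty grid")
  structure(list(values = values, mode = mode), class = "lambda_grid")
}

#' Thirteen-point log-spaced penalty grid preset
#'
#' Thirteen values evenly spaced on a log scale from 0.08 to 0.64, an
#' alternative finer grid for single-penalty scans.
#'
#' @param mode passed to [lambda_grid()].
#' @return A `lambda_grid`.
#' @export
lambda_grid_log13 <- function(mode = "single") {
  lambda_grid(exp(seq(log(0.64), log(0.08), length.out = 13)), mode = mode)
}

# candidate penalty triples as a data.frame, ordered so that consecutive
# rows differ in few coordinates (warm-start friendly, descending)
grid_candidates <- function(grid) {
  v <- grid$values
  if (grid$mode == "single") {
    data.frame(lambda_cc = v, lambda_cd = v, lambda_dd = v)
  } else {
    g <- expand.grid(lambda_dd = v, lambda_cd = v, lambda_cc = v,
                     KEEP.OUT.ATTRS = FALSE)
    g[, c("lambda_cc", "lambda_cd", "lambda_dd")]
  }
}

# index of the best candidate: lowest score, ties broken toward sparser
# penalties lexicographically (lambda_dd, then lambda_cd, then lambda_cc)
best_candidate <- function(cand, score) {
  order(score, -cand$lambda_dd, -cand$lambda_cd, -cand$lambda_cc)[1]
}

selection_result <- function(method, cand, score, best, params, grid,
                             n_fits, extra = NULL) {
  scores <- cbind(cand, score = score)
  out <- list(method = method,
              penalties = penalty_weights(as.numeric(cand[best, ])),
              scores = scores, params = params, grid = grid,
              n_fits = n_fits)
  out <- c(out, extra)
  structure(out, class = "mgm_selection")
}

#' @export
print.mgm_selection <- function(x, ...) {
  cat(sprintf("mgm_selection (%s): lambda_cc=%g, lambda_cd=%g, lambda_dd=%g (%d candidates, %d fits)\n",
              x$method, x$penalties$lambda_cc, x$penalties$lambda_cd,
              x$penalties$lambda_dd, nrow(x$scores), x$n_fits))
  invisible(x)
}

#' Akaike / Bayes information criteria for a fitted MGM
#'
#' The likelihood is replaced by the pseudolikelihood (summed over
#' samples): `AIC = 2 * NLPL + 2 * dof` and `BIC = 2 * NLPL + log(n) *
#' dof`, with network degrees of freedom from [degrees_of_freedom()].
#' Lower is better.
#'
#' @param params a fitted [mgm_params] object.
#' @param data the [mixed_data] the model was fit on.
#' @return Scalar score.
#' @export
aic_score <- function(params, data) {
  2 * negative_log_pseudolikelihood(params, data) + 2 * degrees_of_freedom(params)
}

#' @rdname aic_score
#' @export
bic_score <- function(params, data) {
  2 * negative_log_pseudolikelihood(params, data) +
    log(data$n) * degrees_of_freedom(params)
}

# fit every candidate on the full data with warm starts; cached and shared
# by the information-criterion and oracle selectors
fit_grid <- function(data, grid, config = fit_config()) {
  cand <- grid_candidates(grid)
  fd <- prepare_fit_data(data, config$standardize)
  plist <- lapply(seq_len(nrow(cand)), function(i) as.numeric(cand[i, ]))
  fits <- fit_path(fd, plist, config)
  list(candidates = cand, fits = fits)
}

#' Information-criterion penalty selection
#'
#' Fits every candidate of the grid on the full data (warm-started along
#' the grid) and selects the penalties minimizing [aic_score()] or
#' [bic_score()].
#'
#' @param data a [mixed_data] object.
#' @param grid a [lambda_grid].
#' @param method `"aic"` or `"bic"`.
#' @param config a [fit_config].
#' @param cache optional precomputed result of the internal grid fit (used
#'   by [run_benchmark()] to share fits between selectors).
#' @return An object of class `mgm_selection` with the chosen
#'   `penalties`, the per-candidate `scores` table and the selected
#'   full-data fit in `params`.
#' @export
ic_select <- function(data, grid, method = c("aic", "bic"),
                      config = fit_config(), cache = NULL) {
  method <- match.arg(method)
  if (is.null(cache)) cache <- fit_grid(data, grid, config)
  scorer <- if (method == "aic") aic_score else bic_score
  score <- vapply(cache$fits, scorer, numeric(1), data = data)
  best <- best_candidate(cache$candidates, score)
  selection_result(method, cache$candidates, score, best,
                   cache$fits[[best]], grid, length(cache$fits))
}

#' Oracle penalty selection against a known graph
#'
#' Selects the candidate whose predicted adjacency minimizes the number of
#' false positives plus false negatives against the true graph.  Not a
#' practical method (it requires the truth); it bounds the achievable
#' selection performance on simulated data.  Ties are broken toward
#' sparser penalties (largest `lambda_dd`, then `lambda_cd`, then
#' `lambda_cc`).
#'
#' @inheritParams ic_select
#' @param true_adjacency symmetric binary matrix over the same variables.
#' @return An `mgm_selection` object.
#' @export
oracle_select <- function(data, grid, true_adjacency, config = fit_config(),
                          cache = NULL) {
  tot <- data$p + data$q
  if (!all(dim(true_adjacency) == c(tot, tot)))
    stop("true adjacency does not match data dimensions")
  if (is.null(cache)) cache <- fit_grid(data, grid, config)
  up <- upper.tri(true_adjacency)
  score <- vapply(cache$fits, function(f) {
    A <- adjacency_from_parameters(f)
    sum(A[up] != true_adjacency[up])
  }, numeric(1))
  best <- best_candidate(cache$candidates, score)
  selection_result("oracle", cache$candidates, score, best,
                   cache$fits[[best]], grid, length(cache$fits))
}

# deterministic fold labels
fold_assignment <- function(n, K, seed = NULL) {
  draw <- function() sample(rep(seq_len(K), length.out = n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' K-fold cross-validated penalty selection
#'
#' For each candidate, averages the held-out per-sample negative
#' log-pseudolikelihood over K random (seeded) folds, selects the
#' minimizer and refits it on all data.  Training standardization is
#' applied to the held-out fold.
#'
#' @inheritParams ic_select
#' @param K number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return An `mgm_selection` object; `scores` holds the CV criterion.
#' @export
cross_validate <- function(data, grid, K = 5L, config = fit_config(),
                           seed = NULL) {
  if (data$n < K) stop("need at least K samples")
  cand <- grid_candidates(grid)
  folds <- fold_assignment(data$n, K, seed)
  plist <- lapply(seq_len(nrow(cand)), function(i) as.numeric(cand[i, ]))
  heldout <- matrix(NA_real_, nrow(cand), K)
  n_fits <- 0L
  for (k in seq_len(K)) {
    train <- data[folds != k]
    test <- data[folds == k]
    for (j in seq_len(data$q)) {
      seen <- tabulate(train$Y[, j], nbins = data$levels[j])
      if (any(seen == 0))
        warning(sprintf("fold %d: level(s) of '%s' unobserved in training data; kept with zero count",
                        k, data$cat_names[j]))
    }
    fd <- prepare_fit_data(train, config$standardize)
    fits <- fit_path(fd, plist, config)
    n_fits <- n_fits + length(fits)
    heldout[, k] <- vapply(fits, function(f)
      negative_log_pseudolikelihood(f, test) / test$n, numeric(1))
  }
  score <- rowMeans(heldout)
  best <- best_candidate(cand, score)
  refit <- fit_mgm(data, penalty_weights(as.numeric(cand[best, ])), config)
  n_fits <- n_fits + 1L
  selection_result("cv", cand, score, best, refit, grid, n_fits,
                   extra = list(folds = folds, heldout = heldout))
}
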