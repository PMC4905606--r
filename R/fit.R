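#' Edge-type sparsity penalties
#'
#' Holds the three nonnegative penalty weights: `lambda_cc` on absolute
#' continuous-continuous interactions, `lambda_cd` on the Euclidean norms of
#' the continuous-discrete vectors, `lambda_dd` on the Frobenius norms of
#' the discrete-discrete blocks.  Setting all three equal recovers the
#' single-penalty model.
#'
#' @param lambda_cc either a nonnegative scalar, a numeric vector of length
#'   3 (`cc`, `cd`, `dd`), or an existing `penalty_weights` object.
#' @param lambda_cd,lambda_dd nonnegative scalars (ignored when `lambda_cc`
#'   supplies all three).
#' @return An object of class `penalty_weights`.
#' @examples
#' penalty_weights(0.32)               # single penalty
#' penalty_weights(0.64, 0.32, 0.16)   # per edge type
#' @export
penalty_weights <- function(lambda_cc, lambda_cd = NULL, lambda_dd = NULL) {
  if (inherits(lambda_cc, "penalty_weights")) return(lambda_cc)
  v <- as.numeric(lambda_cc)
  if (is.null(lambda_cd) && is.null(lambda_dd)) {
    if (length(v) == 1) v <- rep(v, 3)
    if (length(v) != 3) stop("need one or three penalty values")
  } else {
    v <- c(v, as.numeric(lambda_cd), as.numeric(lambda_dd))
    if (length(v) != 3) stop("need one or three penalty values")
  }
  if (any(v < 0) || anyNA(v)) stop("penalties must be nonnegative")
  structure(list(lambda_cc = v[1], lambda_cd = v[2], lambda_dd = v[3]),
            class = "penalty_weights")
}

#' @export
print.penalty_weights <- function(x, ...) {
  cat(sprintf("penalties: lambda_cc=%g, lambda_cd=%g, lambda_dd=%g\n",
              x$lambda_cc, x$lambda_cd, x$lambda_dd))
  invisible(x)
}

#' Optimizer settings for the proximal-gradient fit
#'
#' @param max_iterations maximum number of proximal-gradient iterations.
#' @param tolerance convergence threshold on the relative change of the
#'   penalized objective between iterations.
#' @param step_size initial backtracking step size.
#' @param backtrack multiplicative step shrink factor in (0, 1).
#' @param acceleration use FISTA momentum (with monotone restart when the
#'   extrapolation overshoots).
#' @param standardize standardize continuous columns (zero mean, unit
#'   variance) before fitting; parameters are reported on the standardized
#'   scale and the scaling is stored with the result.
#' @param min_diag lower bound on the beta diagonal during optimization,
#'   keeping conditional variances positive.
#' @param seed reserved; the fit itself is deterministic.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 500L, tolerance = 1e-6,
                       step_size = 1.0, backtrack = 0.5,
                       acceleration = TRUE, standardize = TRUE,
                       min_diag = 1e-6, seed = NULL) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, step_size = step_size,
                 backtrack = backtrack, acceleration = acceleration,
                 standardize = standardize, min_diag = min_diag,
                 seed = seed),
            class = "fit_config")
}

# standardized design matrices shared by a sequence of fits on one dataset
prepare_fit_data <- function(data, standardize = TRUE) {
  X <- data$X
  scaling <- NULL
  if (standardize && data$p > 0) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) {
      warning("constant continuous column(s); left unscaled")
      scl[scl == 0] <- 1
    }
    X <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
    scaling <- list(center = center, scale = scl)
  }
  list(X = X, D = indicator_matrix(data), levels = data$levels,
       scaling = scaling, data = data)
}

fit_mgm_prepared <- function(fd, penalties, config, init = NULL) {
  data <- fd$data
  if (is.null(init)) init <- mgm_params_init(data$p, data$levels)
  res <- cpp_fit(fd$X, fd$D, data$levels,
                 penalties$lambda_cc, penalties$lambda_cd, penalties$lambda_dd,
                 init$beta, init$alpha, init$rho, init$phi,
                 tol = config$tolerance, maxit = config$max_iterations,
                 step0 = config$step_size, bt = config$backtrack,
                 accel = config$acceleration, min_diag = config$min_diag)
  out <- mgm_params(beta = res$beta, alpha = drop(res$alpha), rho = res$rho,
                    phi = res$phi, levels = data$levels,
                    cont_names = data$cont_names, cat_names = data$cat_names)
  out$scaling <- fd$scaling
  out$penalties <- penalties
  out$fit <- list(objective = res$objective, iterations = res$iterations,
                  converged = res$converged, termination = res$termination,
                  trace = as.numeric(res$trace))
  out
}

#' Fit a mixed graphical model by penalized pseudolikelihood
#'
#' Minimizes `negative_log_pseudolikelihood / n + penalty_value` by an
#' accelerated proximal gradient method (FISTA) with backtracking line
#' search and monotone restart.  Group soft-thresholding produces exact
#' zeros in shrunk interaction blocks; after every step the indicator
#' coefficient groups are re-projected onto their sum-to-zero subspace
#' (group means are absorbed into the intercepts, leaving the objective
#' unchanged).
#'
#' @param data a [mixed_data] object with at least 2 samples.
#' @param penalties a [penalty_weights] object or numeric of length 1 or 3.
#' @param config a [fit_config] object.
#' @param init optional [mgm_params] warm start (on the fitting scale).
#' @return An [mgm_params] object with extra fields: `penalties`, `scaling`
#'   (training standardization, if any) and `fit` (a list with `objective`,
#'   `iterations`, `converged`, `termination` and the per-iterate objective
#'   `trace`).
#' @examples
#' d <- mixed_data(X = matrix(rnorm(100), 50, 2))
#' fit <- fit_mgm(d, penalty_weights(0.1))
#' fit$fit$converged
#' @export
fit_mgm <- function(data, penalties, config = fit_config(), init = NULL) {
  if (data$n < 2) stop("need at least 2 samples")
  penalties <- penalty_weights(penalties)
  fd <- prepare_fit_data(data, config$standardize)
  fit_mgm_prepared(fd, penalties, config, init)
}

# warm-started sequence of fits over a list of penalty settings
fit_path <- function(fd, penalty_list, config) {
  fits <- vector("list", length(penalty_list))
  init <- NULL
  for (i in seq_along(penalty_list)) {
    fits[[i]] <- fit_mgm_prepared(fd, penalty_weights(penalty_list[[i]]),
                                  config, init)
    init <- fits[[i]]
  }
  fits
}

#' Gradient of the negative log-pseudolikelihood
#'
#' Returns the gradient (summed over samples) with respect to each
#' parameter block, in the same layout as the parameters.  Mainly useful
#' for optimality diagnostics.
#'
#' @inheritParams negative_log_pseudolikelihood
#' @return List with elements `beta`, `alpha`, `rho`, `phi` and the
#'   objective `value`.
#' @export
nlpl_gradient <- function(params, data) {
  X <- scale_to_params(params, data)
  D <- indicator_matrix(data)
  res <- cpp_nlpl(X, D, data$levels, params$beta, params$alpha,
                  params$rho, params$phi, gradient = TRUE)
  list(value = res$value, beta = res$grad_beta,
       alpha = drop(res$grad_alpha), rho = res$grad_rho,
       phi = res$grad_phi)
}

#' Proximal step of the penalized objective
#'
#' Takes a gradient step and applies the proximal operator of the
#' edge-type penalties: elementwise soft-thresholding of off-diagonal beta
#' at `step * lambda_cc`, group soft-thresholding of each rho vector at
#' `step * lambda_cd` and of each off-diagonal phi block at
#' `step * lambda_dd` (a group whose norm falls below its threshold becomes
#' exactly zero).  Intercepts and the beta diagonal are unpenalized; beta
#' symmetry, phi transpose-consistency and the sum-to-zero projection of
#' indicator groups are restored.
#'
#' @param params an [mgm_params] object.
#' @param gradient a list with elements `beta`, `alpha`, `rho`, `phi` (as
#'   from [nlpl_gradient()]).
#' @param step positive step size.
#' @param penalties a [penalty_weights] object.
#' @param min_diag lower bound applied to the beta diagonal.
#' @return The updated [mgm_params].
#' @export
proximal_step <- function(params, gradient, step, penalties,
                          min_diag = 1e-6) {
  if (step <= 0) stop("step must be positive")
  penalties <- penalty_weights(penalties)
  res <- cpp_prox(params$beta - step * gradient$beta,
                  params$alpha - step * gradient$alpha,
                  params$rho - step * gradient$rho,
                  params$phi - step * gradient$phi,
                  params$levels, step,
                  penalties$lambda_cc, penalties$lambda_cd,
                  penalties$lambda_dd, min_diag)
  out <- mgm_params(beta = res$beta, alpha = drop(res$alpha), rho = res$rho,
                    phi = res$phi, levels = params$levels,
                    cont_names = params$cont_names,
                    cat_names = params$cat_names)
  out$scaling <- params$scaling
  out
}
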