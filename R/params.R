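#' Mixed graphical model parameters
#'
#' The pairwise MGM is parameterized by: `beta`, a symmetric p x p matrix of
#' continuous-continuous interactions with strictly positive diagonal (the
#' diagonal plays the role of conditional precisions); `alpha`, a length-p
#' vector of continuous intercepts; `rho`, a totL x p matrix whose row block
#' for categorical variable j holds the vectors rho_sj of
#' continuous-discrete interactions (column s, rows = levels of j); and
#' `phi`, a symmetric totL x totL block matrix of discrete-discrete
#' interactions, whose within-variable diagonal blocks are diagonal matrices
#' of per-level intercepts.  Here totL = sum of the level counts.
#'
#' @param beta symmetric p x p numeric matrix, positive diagonal.
#' @param alpha numeric vector of length p.
#' @param rho totL x p numeric matrix (row blocks per categorical variable).
#' @param phi symmetric totL x totL numeric matrix.
#' @param levels integer vector of level counts.
#' @param cont_names,cat_names variable names (defaults generated).
#' @return An object of class `mgm_params`.
#' @seealso [mgm_params_init()] for the standard zero initialization.
#' @export
mgm_params <- function(beta, alpha, rho, phi, levels,
                       cont_names = NULL, cat_names = NULL) {
  p <- length(alpha); q <- length(levels)
  levels <- as.integer(levels)
  totL <- sum(levels)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(p, p))) stop("beta must be p x p")
  if (p > 0 && max(abs(beta - t(beta))) > 1e-8) stop("beta must be symmetric")
  if (p > 0 && any(diag(beta) <= 0)) stop("beta diagonal must be strictly positive")
  rho <- as.matrix(rho)
  if (!all(dim(rho) == c(totL, p))) stop("rho must be totL x p")
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(totL, totL))) stop("phi must be totL x totL")
  if (totL > 0 && max(abs(phi - t(phi))) > 1e-8)
    stop("phi blocks must be pairwise transpose-consistent")
  if (is.null(cont_names)) cont_names <- if (p > 0) paste0("x", seq_len(p)) else character(0)
  if (is.null(cat_names)) cat_names <- if (q > 0) paste0("y", seq_len(q)) else character(0)
  structure(list(beta = beta, alpha = as.numeric(alpha), rho = rho, phi = phi,
                 levels = levels, cont_names = cont_names,
                 cat_names = cat_names, scaling = NULL),
            class = "mgm_params")
}

#' Zero-initialized MGM parameters
#'
#' The standard starting point for the proximal-gradient fit: identity
#' `beta`, zero `alpha`, `rho`, `phi`.  It is feasible (positive conditional
#' variances) and gives a finite objective on any data.
#'
#' @param p number of continuous variables.
#' @param levels integer vector of categorical level counts.
#' @inheritParams mgm_params
#' @return An `mgm_params` object.
#' @export
mgm_params_init <- function(p, levels, cont_names = NULL, cat_names = NULL) {
  totL <- sum(levels)
  mgm_params(beta = diag(nrow = p), alpha = rep(0, p),
             rho = matrix(0, totL, p), phi = matrix(0, totL, totL),
             levels = levels, cont_names = cont_names, cat_names = cat_names)
}

#' @export
print.mgm_params <- function(x, ...) {
  p <- length(x$alpha); q <- length(x$levels)
  cat(sprintf("mgm_params: p=%d continuous, q=%d categorical\n", p, q))
  A <- adjacency_from_parameters(x)
  et <- edge_type_matrix(p, q)
  up <- upper.tri(A)
  cat(sprintf("  edges: %d cc, %d cd, %d dd\n",
              sum(A[up & et == "cc"]), sum(A[up & et == "cd"]),
              sum(A[up & et == "dd"])))
  if (!is.null(x$fit))
    cat(sprintf("  fit: objective %.6g, %d iterations (%s)\n",
                x$fit$objective, x$fit$iterations, x$fit$termination))
  invisible(x)
}

#' Extract a continuous-discrete interaction vector
#'
#' @param params an [mgm_params] object.
#' @param s continuous variable index.
#' @param j categorical variable index.
#' @return The length-`L_j` vector rho_sj.
#' @export
rho_block <- function(params, s, j) {
  offs <- level_offsets(params$levels)
  params$rho[offs[j] + seq_len(params$levels[j]), s]
}

#' Extract a discrete-discrete interaction block
#'
#' @param params an [mgm_params] object.
#' @param r,j categorical variable indices.
#' @return The `L_r` x `L_j` matrix phi_rj.
#' @export
phi_block <- function(params, r, j) {
  offs <- level_offsets(params$levels)
  params$phi[offs[r] + seq_len(params$levels[r]),
             offs[j] + seq_len(params$levels[j]), drop = FALSE]
}

# edge-type labels over the (p+q) x (p+q) node universe, "" on the diagonal
edge_type_matrix <- function(p, q) {
  tot <- p + q
  kind <- c(rep("c", p), rep("d", q))
  et <- matrix(paste0(rep(kind, each = tot), rep(kind, times = tot)),
               tot, tot, byrow = TRUE)
  et[et == "dc"] <- "cd"
  diag(et) <- ""
  et
}

#' Predicted adjacency matrix from MGM parameters
#'
#' An edge is predicted present when any parameter of its block exceeds the
#' threshold in absolute value: `|beta_st| > threshold` for
#' continuous-continuous pairs, `max |rho_sj| > threshold` for
#' continuous-discrete pairs and `max |phi_rj| > threshold` for
#' discrete-discrete pairs.  The default threshold 0 implements the
#' "any non-zero parameter" rule; group soft-thresholding makes shrunk
#' blocks exactly zero, so no tolerance is needed.
#'
#' @param params an [mgm_params] object.
#' @param threshold nonnegative magnitude threshold (default 0).
#' @return Symmetric binary (p+q) x (p+q) matrix with zero diagonal; rows
#'   and columns ordered continuous first, then categorical.
#' @export
adjacency_from_parameters <- function(params, threshold = 0) {
  p <- length(params$alpha); q <- length(params$levels)
  tot <- p + q
  A <- matrix(0L, tot, tot)
  rownames(A) <- colnames(A) <- c(params$cont_names, params$cat_names)
  offs <- level_offsets(params$levels)
  if (p > 1) {
    Ab <- (abs(params$beta) > threshold) * 1L
    diag(Ab) <- 0L
    A[1:p, 1:p] <- Ab
  }
  for (j in seq_len(q)) {
    rows <- offs[j] + seq_len(params$levels[j])
    for (s in seq_len(p)) {
      pres <- as.integer(max(abs(params$rho[rows, s])) > threshold)
      A[s, p + j] <- A[p + j, s] <- pres
    }
    for (r in seq_len(j - 1L)) {
      cols <- offs[r] + seq_len(params$levels[r])
      pres <- as.integer(max(abs(params$phi[rows, cols])) > threshold)
      A[p + j, p + r] <- A[p + r, p + j] <- pres
    }
  }
  A
}

#' Degrees of freedom of a fitted MGM
#'
#' Counts one degree of freedom per continuous-continuous edge, `L_j - 1`
#' per continuous-discrete edge, and `(L_i - 1)(L_j - 1)` per
#' discrete-discrete edge, reflecting the sum-to-zero constraints on the
#' indicator coefficient groups.  Edge presence follows
#' [adjacency_from_parameters()] at threshold 0.
#'
#' @param params an [mgm_params] object.
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(params) {
  p <- length(params$alpha); q <- length(params$levels)
  A <- adjacency_from_parameters(params)
  Lfree <- c(rep(1L, p), params$levels - 1L)
  dof <- 0L
  tot <- p + q
  for (a in seq_len(tot - 1L)) for (b in seq(a + 1L, tot))
    if (A[a, b] == 1L) dof <- dof + Lfree[a] * Lfree[b]
  as.integer(dof)
}
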