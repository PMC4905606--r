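#' Mixed-type dataset
#'
#' Container for a sample-by-variable table holding `p` continuous and `q`
#' categorical variables.  Continuous values are stored as a numeric matrix
#' `X`; categorical observations as a matrix `Y` of 1-based level indices
#' with per-variable level counts `levels` (each at least 2).
#'
#' @param X numeric matrix (n x p) of continuous observations, or `NULL`
#'   when the dataset has no continuous variables.
#' @param Y integer matrix (n x q) of 1-based level indices, or `NULL` when
#'   the dataset has no categorical variables.
#' @param levels integer vector of level counts per categorical variable.
#'   Defaults to the per-column maximum of `Y` (but at least 2).
#' @param level_labels optional list of character vectors naming the levels
#'   of each categorical variable.
#' @return An object of class `mixed_data` with fields `X`, `Y`, `levels`,
#'   `level_labels`, `cont_names`, `cat_names`, `n`, `p`, `q`.
#' @examples
#' d <- mixed_data(X = matrix(rnorm(20), 10, 2),
#'                 Y = matrix(sample(1:3, 10, TRUE), 10, 1))
#' d$p; d$q; d$levels
#' @export
mixed_data <- function(X = NULL, Y = NULL, levels = NULL, level_labels = NULL) {
  if (is.null(X) && is.null(Y)) stop("at least one of X, Y must be given")
  n <- if (!is.null(X)) nrow(X) else nrow(Y)
  if (is.null(n) || n < 1) stop("n must be at least 1")
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  if (is.null(Y)) Y <- matrix(integer(0), n, 0)
  X <- as.matrix(X); storage.mode(X) <- "double"
  Y <- as.matrix(Y); storage.mode(Y) <- "integer"
  if (nrow(X) != n || nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  p <- ncol(X); q <- ncol(Y)
  if (is.null(colnames(X)) && p > 0) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(colnames(Y)) && q > 0) colnames(Y) <- paste0("y", seq_len(q))
  if (is.null(levels)) {
    levels <- if (q > 0) pmax(2L, apply(Y, 2, max)) else integer(0)
  }
  levels <- as.integer(levels)
  if (length(levels) != q) stop("levels must have one entry per categorical variable")
  if (q > 0) {
    if (any(levels < 2)) stop("every categorical variable needs at least 2 levels")
    bad <- Y < 1L | Y > matrix(levels, n, q, byrow = TRUE)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("level index out of range at row %d, variable '%s'",
                   idx[1], colnames(Y)[idx[2]]))
    }
  }
  if (is.null(level_labels)) {
    level_labels <- lapply(levels, function(L) as.character(seq_len(L)))
  }
  if (length(level_labels) != q) stop("level_labels must have one entry per categorical variable")
  names(level_labels) <- colnames(Y)
  structure(list(X = X, Y = Y, levels = levels,
                 level_labels = level_labels,
                 cont_names = colnames(X), cat_names = colnames(Y),
                 n = n, p = p, q = q),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat(sprintf("mixed_data: %d samples, %d continuous, %d categorical\n",
              x$n, x$p, x$q))
  if (x$q > 0)
    cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Subset the rows (samples) of a mixed dataset
#'
#' @param x a [mixed_data] object.
#' @param i row index vector.
#' @param ... ignored.
#' @return A [mixed_data] with the selected samples; level dictionaries are
#'   preserved even when some levels become unobserved.
#' @export
`[.mixed_data` <- function(x, i, ...) {
  mixed_data(X = x$X[i, , drop = FALSE], Y = x$Y[i, , drop = FALSE],
             levels = x$levels, level_labels = x$level_labels)
}

# one-hot indicator matrix (n x sum(levels)); column blocks follow the
# categorical variables in order, rows of rho/phi use the same layout
indicator_matrix <- function(data) {
  totL <- sum(data$levels)
  D <- matrix(0, data$n, totL)
  offs <- level_offsets(data$levels)
  for (j in seq_len(data$q))
    D[cbind(seq_len(data$n), offs[j] + data$Y[, j])] <- 1
  D
}

# 0-based offsets of each categorical variable's block
level_offsets <- function(levels) {
  if (length(levels) == 0) return(integer(0))
  c(0L, cumsum(levels)[-length(levels)])
}
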