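#' Log unnormalized joint density of the MGM
#'
#' Evaluates the exponent of the pairwise MGM joint density at a single
#' observation:
#' \deqn{\sum_{s,t} -\tfrac12 \beta_{st} x_s x_t + \sum_s \alpha_s x_s +
#'       \sum_{s,j} \rho_{sj}(y_j) x_s + \sum_{r \le j} \phi_{rj}(y_r, y_j)}
#' The quadratic sum runs over all ordered pairs (the 1/2 factor with the
#' symmetry of beta counts each unordered interaction once); the phi sum
#' runs over unordered pairs plus the within-variable intercepts
#' \eqn{\phi_{rr}(y_r, y_r)}, which makes the conditional distributions
#' below exact renormalizations of this exponent.
#'
#' @param params an [mgm_params] object.
#' @param x numeric vector of length p.
#' @param y integer vector of length q (1-based level indices).
#' @return The scalar log unnormalized density.
#' @export
log_unnormalized_density <- function(params, x, y) {
  p <- length(params$alpha); q <- length(params$levels)
  if (length(x) != p) stop("x has wrong length")
  if (length(y) != q) stop("y has wrong length")
  y <- as.integer(y)
  if (q > 0 && any(y < 1L | y > params$levels)) stop("level index out of range")
  offs <- level_offsets(params$levels)
  val <- 0
  if (p > 0) {
    val <- val - 0.5 * drop(crossprod(x, params$beta %*% x)) + sum(params$alpha * x)
    for (j in seq_len(q))
      val <- val + sum(params$rho[offs[j] + y[j], ] * x)
  }
  for (j in seq_len(q)) {
    for (r in seq_len(j))
      val <- val + params$phi[offs[r] + y[r], offs[j] + y[j]]
  }
  val
}

#' Gaussian conditional of a continuous variable given the rest
#'
#' Derived from the joint density: \eqn{x_s \mid x_{\setminus s}, y} is
#' Gaussian with variance \eqn{1/\beta_{ss}} and mean
#' \eqn{(\alpha_s + \sum_j \rho_{sj}(y_j) - \sum_{t \ne s} \beta_{st} x_t)
#' / \beta_{ss}}.
#'
#' @param params an [mgm_params] object.
#' @param s index of the continuous variable.
#' @param x numeric vector of length p (the entry at position `s` is
#'   ignored).
#' @param y integer vector of length q.
#' @return List with elements `mean` and `variance`.
#' @export
continuous_conditional <- function(params, s, x, y) {
  p <- length(params$alpha); q <- length(params$levels)
  if (s < 1 || s > p) stop("invalid continuous index")
  bss <- params$beta[s, s]
  if (bss <= 0) stop("nonpositive beta diagonal")
  offs <- level_offsets(params$levels)
  num <- params$alpha[s]
  for (j in seq_len(q)) num <- num + params$rho[offs[j] + y[j], s]
  if (p > 1) num <- num - sum(params$beta[s, -s] * x[-s])
  list(mean = num / bss, variance = 1 / bss)
}

#' Conditional distribution of a categorical variable given the rest
#'
#' Softmax over the levels k of
#' \eqn{\sum_s \rho_{sr}(k) x_s + \sum_{j \ne r} \phi_{rj}(k, y_j) +
#' \phi_{rr}(k, k)}.
#'
#' @param params an [mgm_params] object.
#' @param r index of the categorical variable.
#' @param x numeric vector of length p.
#' @param y integer vector of length q (the entry at position `r` is
#'   ignored).
#' @return Probability vector over the `L_r` levels (sums to 1).
#' @export
categorical_conditional <- function(params, r, x, y) {
  p <- length(params$alpha); q <- length(params$levels)
  if (r < 1 || r > q) stop("invalid categorical index")
  offs <- level_offsets(params$levels)
  L <- params$levels[r]
  rows <- offs[r] + seq_len(L)
  eta <- diag(params$phi[rows, rows, drop = FALSE])
  if (p > 0) eta <- eta + drop(params$rho[rows, , drop = FALSE] %*% x)
  for (j in seq_len(q)) {
    if (j == r) next
    eta <- eta + params$phi[rows, offs[j] + y[j]]
  }
  e <- exp(eta - max(eta))
  e / sum(e)
}

# apply a fitted model's training standardization to new data
scale_to_params <- function(params, data) {
  X <- data$X
  if (!is.null(params$scaling) && data$p > 0) {
    X <- sweep(X, 2, params$scaling$center, "-")
    X <- sweep(X, 2, params$scaling$scale, "/")
  }
  X
}

#' Negative log-pseudolikelihood of an MGM on a dataset
#'
#' Sum over samples and variables of the negative log conditional density of
#' each variable given all others, using the Gaussian and softmax
#' conditionals implied by the joint density.  If `params` carries a
#' standardization from [fit_mgm()], the continuous columns of `data` are
#' standardized with the stored training centers/scales before evaluation.
#'
#' @param params an [mgm_params] object.
#' @param data a [mixed_data] object with matching dimensions.
#' @param per_sample if `TRUE`, return the length-n vector of per-sample
#'   contributions instead of their sum.
#' @return Scalar (default) or per-sample numeric vector.
#' @export
negative_log_pseudolikelihood <- function(params, data, per_sample = FALSE) {
  p <- length(params$alpha); q <- length(params$levels)
  if (data$p != p || data$q != q || !identical(data$levels, params$levels))
    stop("params and data dimensions disagree")
  n <- data$n
  X <- scale_to_params(params, data)
  D <- indicator_matrix(data)
  offs <- level_offsets(params$levels)
  val <- numeric(n)
  if (p > 0) {
    bd <- diag(params$beta)
    if (any(bd <= 0)) stop("nonpositive conditional variance")
    Boff <- params$beta; diag(Boff) <- 0
    Eta <- matrix(params$alpha, n, p, byrow = TRUE) - X %*% Boff
    if (q > 0) Eta <- Eta + D %*% params$rho
    Mu <- sweep(Eta, 2, bd, "/")
    R <- X - Mu
    val <- val + rowSums(sweep(0.5 * R^2, 2, bd, "*")) +
      sum(0.5 * log(2 * pi) - 0.5 * log(bd))
  }
  if (q > 0) {
    H <- D %*% params$phi
    if (p > 0) H <- H + X %*% t(params$rho)
    for (r in seq_len(q)) {
      cols <- offs[r] + seq_len(params$levels[r])
      Db <- D[, cols, drop = FALSE]
      pd <- diag(params$phi[cols, cols, drop = FALSE])
      Hb <- H[, cols, drop = FALSE] - sweep(Db, 2, pd, "*")
      Hb <- sweep(Hb, 2, pd, "+")
      m <- apply(Hb, 1, max)
      lse <- m + log(rowSums(exp(Hb - m)))
      val <- val + lse - rowSums(Hb * Db)
    }
  }
  if (per_sample) val else sum(val)
}

#' Edge-type penalty value
#'
#' \eqn{\lambda_{cc} \sum_{t<s} |\beta_{st}| + \lambda_{cd} \sum_{s,j}
#' \|\rho_{sj}\|_2 + \lambda_{dd} \sum_{r<j} \|\phi_{rj}\|_F}.  The beta
#' diagonal and the within-variable phi intercepts are never penalized.
#'
#' @param params an [mgm_params] object.
#' @param penalties a [penalty_weights] object (or numeric of length 1
#'   or 3).
#' @return Scalar penalty value.
#' @export
penalty_value <- function(params, penalties) {
  penalties <- penalty_weights(penalties)
  p <- length(params$alpha); q <- length(params$levels)
  offs <- level_offsets(params$levels)
  pen <- 0
  if (p > 1)
    pen <- pen + penalties$lambda_cc * sum(abs(params$beta[lower.tri(params$beta)]))
  for (j in seq_len(q)) {
    rows <- offs[j] + seq_len(params$levels[j])
    for (s in seq_len(p))
      pen <- pen + penalties$lambda_cd * sqrt(sum(params$rho[rows, s]^2))
    for (r in seq_len(j - 1L)) {
      cols <- offs[r] + seq_len(params$levels[r])
      pen <- pen + penalties$lambda_dd * sqrt(sum(params$phi[rows, cols]^2))
    }
  }
  pen
}
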