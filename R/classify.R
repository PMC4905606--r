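#' Predict a categorical variable from a trained MGM
#'
#' For each test sample, evaluates the full negative log-pseudolikelihood
#' with the target variable clamped to each of its levels (all other
#' variables at their observed values) and predicts the level minimizing
#' it.  Ties go to the lowest level index.  When the test data contain the
#' target column, prediction accuracy against it is reported.
#'
#' @param params a fitted [mgm_params].
#' @param test a [mixed_data] with the same variables as the training
#'   data (the target column's observed values are used only for
#'   accuracy).
#' @param target name or index of a categorical variable.
#' @return An object of class `mgm_classification`: list with `target`,
#'   `predicted` (integer levels), `scores` (n x L matrix of per-level
#'   negative log-pseudolikelihoods), `truth`, `accuracy`.
#' @export
predict_categorical <- function(params, test, target) {
  q <- length(params$levels)
  if (is.character(target)) target <- match(target, params$cat_names)
  if (is.na(target) || target < 1 || target > q)
    stop("target is not a categorical variable of the model")
  L <- params$levels[target]
  scores <- matrix(NA_real_, test$n, L)
  for (k in seq_len(L)) {
    Yk <- test$Y
    Yk[, target] <- k
    dk <- mixed_data(X = test$X, Y = Yk, levels = test$levels,
                     level_labels = test$level_labels)
    scores[, k] <- negative_log_pseudolikelihood(params, dk,
                                                 per_sample = TRUE)
  }
  predicted <- apply(scores, 1, which.min)   # first minimum = lowest level
  truth <- test$Y[, target]
  structure(list(target = params$cat_names[target],
                 predicted = as.integer(predicted), scores = scores,
                 truth = truth,
                 accuracy = mean(predicted == truth)),
            class = "mgm_classification")
}

#' @export
print.mgm_classification <- function(x, ...) {
  cat(sprintf("mgm_classification of '%s': %d samples, accuracy %.3f\n",
              x$target, length(x$predicted), x$accuracy))
  invisible(x)
}

#' Cross-validated classification accuracy over a penalty grid
#'
#' For each candidate penalty setting, fits the MGM on K-1 folds and
#' predicts the target variable on the held-out fold with
#' [predict_categorical()]; reports the pooled accuracy per candidate.
#'
#' @param data a [mixed_data] object.
#' @param target name or index of a categorical variable.
#' @param grid a [lambda_grid].
#' @param K number of folds (default 8).
#' @param config a [fit_config].
#' @param seed integer seed for the fold assignment.
#' @return A data.frame with the candidate penalties and their
#'   cross-validated `accuracy`.
#' @export
cv_classification_accuracy <- function(data, target, grid, K = 8L,
                                       config = fit_config(),
                                       seed = NULL) {
  cand <- grid_candidates(grid)
  folds <- fold_assignment(data$n, K, seed)
  plist <- lapply(seq_len(nrow(cand)), function(i) as.numeric(cand[i, ]))
  correct <- matrix(0, nrow(cand), K)
  tested <- integer(K)
  for (k in seq_len(K)) {
    train <- data[folds != k]
    test <- data[folds == k]
    tested[k] <- test$n
    fd <- prepare_fit_data(train, config$standardize)
    fits <- fit_path(fd, plist, config)
    for (i in seq_along(fits)) {
      pred <- predict_categorical(fits[[i]], test, target)
      correct[i, k] <- sum(pred$predicted == pred$truth)
    }
  }
  cbind(cand, accuracy = rowSums(correct) / sum(tested))
}
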