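#' Configuration for the model-selection benchmark
#'
#' @param sim a [sim_config] describing the simulated datasets (or `NULL`
#'   when `datasets` are supplied to [run_benchmark()] directly).
#' @param methods subset of `c("aic", "bic", "cv", "oracle", "stars1",
#'   "steps3", "cubic")`.
#' @param classical_grid triple-mode [lambda_grid] searched by AIC, BIC,
#'   CV and the oracle.
#' @param stability_grid single-mode [lambda_grid] subsampled by StARS /
#'   StEPS.
#' @param cubic_grid triple-mode [lambda_grid] for the cubic stability
#'   search.
#' @param gamma instability threshold.
#' @param N number of subsamples.
#' @param K cross-validation folds.
#' @param fit a [fit_config].
#' @param seed master seed.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(sim = sim_config(),
                             methods = c("aic", "bic", "cv", "oracle",
                                         "stars1", "steps3"),
                             classical_grid = lambda_grid(mode = "triple"),
                             stability_grid = lambda_grid(mode = "single"),
                             cubic_grid = lambda_grid(mode = "triple"),
                             gamma = 0.05, N = 20L, K = 5L,
                             fit = fit_config(), seed = NULL) {
  methods <- match.arg(methods, c("aic", "bic", "cv", "oracle", "stars1",
                                  "steps3", "cubic"), several.ok = TRUE)
  structure(list(sim = sim, methods = methods,
                 classical_grid = classical_grid,
                 stability_grid = stability_grid, cubic_grid = cubic_grid,
                 gamma = gamma, N = as.integer(N), K = as.integer(K),
                 fit = fit, seed = seed),
            class = "benchmark_config")
}

# selection + evaluation of one method on one dataset
run_one_method <- function(method, entry, config, caches, seed) {
  data <- entry$dataset
  sel <- switch(method,
    aic = ic_select(data, config$classical_grid, "aic", config$fit,
                    cache = caches$grid),
    bic = ic_select(data, config$classical_grid, "bic", config$fit,
                    cache = caches$grid),
    cv = cross_validate(data, config$classical_grid, config$K, config$fit,
                        seed = seed),
    oracle = oracle_select(data, config$classical_grid, entry$truth,
                           config$fit, cache = caches$grid),
    stars1 = {
      lam <- stars_select(caches$profile, config$gamma, "all")
      params <- fit_mgm(data, penalty_weights(lam), config$fit)
      list(penalties = penalty_weights(lam), params = params,
           n_fits = caches$profile$n_fits + 1L)
    },
    steps3 = steps_select(data, gamma = config$gamma, config = config$fit,
                          profile = caches$profile),
    cubic = cubic_stability_select(data, config$cubic_grid, config$N,
                                   gamma = config$gamma,
                                   config = config$fit, seed = seed))
  met <- recovery_metrics(edge_confusion(
    adjacency_from_parameters(sel$params), entry$truth,
    p = data$p, q = data$q))
  met_all <- met[met$type == "all", ]
  data.frame(network = entry$network,
             linear = entry$linear, method = method,
             lambda_cc = sel$penalties$lambda_cc,
             lambda_cd = sel$penalties$lambda_cd,
             lambda_dd = sel$penalties$lambda_dd,
             precision = met_all$precision, recall = met_all$recall,
             f1 = met_all$f1, mcc = met_all$mcc,
             accuracy = met_all$accuracy,
             edges = sum(adjacency_from_parameters(sel$params)) / 2)
}

#' Run the model-selection benchmark end to end
#'
#' Simulates (or takes) a collection of datasets with known generating
#' graphs, runs every configured selection method on each dataset, scores
#' edge recovery of the selected full-data models, and aggregates per
#' method.  Full-data grid fits are shared between AIC, BIC and the
#' oracle; the subsampling ensemble is shared between single-penalty
#' stability selection (`stars1`) and StEPS (`steps3`).  A failing method
#' on a dataset is recorded with a warning and excluded from aggregation.
#'
#' @param config a [benchmark_config].
#' @param datasets optional list of entries (as produced by
#'   [simulate_benchmark()]) to use instead of simulating.
#' @return An object of class `benchmark_report`: list with `per_dataset`
#'   (one row per dataset x method), `summary` (mean and standard error
#'   per method and metric), `failures`, `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), datasets = NULL) {
  if (is.null(datasets)) datasets <- simulate_benchmark(config$sim)
  seeds <- derive_seeds(config$seed, max(1L, length(datasets)))
  rows <- list(); failures <- list()
  need_grid <- any(c("aic", "bic", "oracle") %in% config$methods)
  need_profile <- any(c("stars1", "steps3") %in% config$methods)
  for (d in seq_along(datasets)) {
    entry <- datasets[[d]]
    caches <- list()
    if (need_grid)
      caches$grid <- fit_grid(entry$dataset, config$classical_grid,
                              config$fit)
    if (need_profile)
      caches$profile <- stability_profile(entry$dataset,
                                          config$stability_grid, config$N,
                                          config = config$fit,
                                          seed = seeds[d])
    for (method in config$methods) {
      res <- tryCatch(
        run_one_method(method, entry, config, caches, seeds[d]),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("method '%s' failed on dataset %d: %s", method, d,
                        conditionMessage(res)))
        failures[[length(failures) + 1L]] <-
          list(dataset = d, method = method,
               message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (length(rows) == 0) {
    warning("no method succeeded on any dataset")
    return(structure(list(per_dataset = NULL, summary = NULL,
                          failures = failures, config = config),
                     class = "benchmark_report"))
  }
  per_dataset <- do.call(rbind, rows)
  metrics <- c("precision", "recall", "f1", "mcc", "accuracy", "edges")
  summary <- do.call(rbind, lapply(split(per_dataset, per_dataset$method),
    function(g) {
      row <- data.frame(method = g$method[1], n_datasets = nrow(g))
      for (m in metrics) {
        row[[paste0(m, "_mean")]] <- mean(g[[m]])
        row[[paste0(m, "_se")]] <- if (nrow(g) > 1)
          sd(g[[m]]) / sqrt(nrow(g)) else NA_real_
      }
      row
    }))
  rownames(summary) <- NULL
  structure(list(per_dataset = per_dataset, summary = summary,
                 failures = failures, config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d dataset-method rows, %d failures\n",
              nrow(x$per_dataset), length(x$failures)))
  cols <- c("method", "n_datasets", "precision_mean", "recall_mean",
            "f1_mean", "mcc_mean", "accuracy_mean")
  print(x$summary[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}
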