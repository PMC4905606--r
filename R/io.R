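#' Read and write mixed data tables
#'
#' The mixed-table format is delimited text with a header row of variable
#' names and a second row declaring each column `continuous` or
#' `categorical`.  Categorical cells hold level labels, mapped to 1-based
#' indices in order of first appearance (or in the order of `level_labels`
#' stored with the dataset when writing).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param types optional character vector of column types overriding the
#'   type declaration row.
#' @return `read_mixed_table` returns a [mixed_data]; `write_mixed_table`
#'   invisibly returns `path`.
#' @export
read_mixed_table <- function(path, sep = "\t", types = NULL) {
  lines <- readLines(path)
  # optional "#levels <name> <label> ..." comments fix the level order;
  # otherwise levels are mapped in first-appearance order
  level_dict <- list()
  for (ln in grep("^#levels", lines, value = TRUE)) {
    f <- strsplit(sub("^#levels\t?", "", ln), sep, fixed = TRUE)[[1]]
    level_dict[[f[1]]] <- f[-1]
  }
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 3) stop("mixed table needs a name row, a type row and data")
  nm <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  declared <- strsplit(lines[2], sep, fixed = TRUE)[[1]]
  if (is.null(types)) types <- declared
  if (length(types) != length(nm))
    stop("type declaration does not cover all columns")
  if (!all(types %in% c("continuous", "categorical")))
    stop("column types must be 'continuous' or 'categorical'")
  # strsplit drops trailing empty fields; pad so they surface as missing
  split_keep <- function(x) {
    out <- strsplit(x, sep, fixed = TRUE)
    nsep <- lengths(gregexpr(sep, x, fixed = TRUE)) - (!grepl(sep, x, fixed = TRUE))
    lapply(seq_along(out), function(i)
      c(out[[i]], rep("", nsep[i] + 1L - length(out[[i]]))))
  }
  cells <- split_keep(lines[-(1:2)])
  n <- length(cells)
  bad <- which(vapply(cells, length, integer(1)) != length(nm))
  if (length(bad) > 0)
    stop(sprintf("row %d has %d cells, expected %d", bad[1] + 2L,
                 length(cells[[bad[1]]]), length(nm)))
  tab <- do.call(rbind, cells)
  if (any(tab == ""))  {
    idx <- which(tab == "", arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at row %d, column '%s'", idx[1] + 2L,
                 nm[idx[2]]))
  }
  cont <- which(types == "continuous")
  cat_ <- which(types == "categorical")
  X <- NULL
  if (length(cont) > 0) {
    X <- matrix(NA_real_, n, length(cont), dimnames = list(NULL, nm[cont]))
    for (i in seq_along(cont)) {
      v <- suppressWarnings(as.numeric(tab[, cont[i]]))
      if (anyNA(v))
        stop(sprintf("unparseable value in continuous column '%s' at row %d",
                     nm[cont[i]], which(is.na(v))[1] + 2L))
      X[, i] <- v
    }
  }
  Y <- NULL; level_labels <- NULL; levels <- NULL
  if (length(cat_) > 0) {
    Y <- matrix(NA_integer_, n, length(cat_),
                dimnames = list(NULL, nm[cat_]))
    level_labels <- vector("list", length(cat_))
    for (i in seq_along(cat_)) {
      labs <- level_dict[[nm[cat_[i]]]]
      if (is.null(labs)) labs <- unique(tab[, cat_[i]])  # first appearance
      if (length(unique(tab[, cat_[i]])) == 1)
        warning(sprintf("categorical column '%s' has a single observed level",
                        nm[cat_[i]]))
      idx <- match(tab[, cat_[i]], labs)
      if (anyNA(idx))
        stop(sprintf("label in column '%s' missing from its level dictionary",
                     nm[cat_[i]]))
      Y[, i] <- idx
      level_labels[[i]] <- labs
    }
    levels <- pmax(2L, vapply(level_labels, length, integer(1)))
    level_labels <- lapply(seq_along(level_labels), function(i) {
      l <- level_labels[[i]]
      if (length(l) < levels[i]) c(l, paste0("unobserved", seq_len(levels[i] - length(l)))) else l
    })
  }
  mixed_data(X = X, Y = Y, levels = levels, level_labels = level_labels)
}

#' @rdname read_mixed_table
#' @param data a [mixed_data] object.
#' @export
write_mixed_table <- function(data, path, sep = "\t") {
  nm <- c(data$cont_names, data$cat_names)
  types <- c(rep("continuous", data$p), rep("categorical", data$q))
  cols <- c(lapply(seq_len(data$p),
                   function(s) sprintf("%.17g", data$X[, s])),
            lapply(seq_len(data$q),
                   function(j) data$level_labels[[j]][data$Y[, j]]))
  body <- if (length(cols) > 0) do.call(paste, c(cols, sep = sep)) else character(0)
  dict <- vapply(seq_len(data$q), function(j)
    paste(c("#levels", data$cat_names[j], data$level_labels[[j]]),
          collapse = sep), character(1))
  writeLines(c(dict, paste(nm, collapse = sep), paste(types, collapse = sep),
               body), path)
  invisible(path)
}

#' Read and write edge lists
#'
#' An edge list is a delimited table with columns `source`, `target`,
#' `edge_type` (`cc`, `cd`, `dd`) and `weight` (the maximum-magnitude
#' parameter of the edge's block; signed for cc edges).  Node universe and
#' node types are recorded in `#node` header comments so that the full
#' adjacency matrix, including isolated nodes, round-trips exactly.
#'
#' @param params an [mgm_params] object (or a binary adjacency matrix
#'   together with `types`).
#' @param path file path.
#' @param threshold edge-presence threshold (see
#'   [adjacency_from_parameters()]).
#' @param sep field separator.
#' @return `write_edge_list` invisibly returns `path`; `read_edge_list`
#'   returns the adjacency matrix with a `types` attribute.
#' @export
write_edge_list <- function(params, path, threshold = 0, sep = "\t") {
  p <- length(params$alpha); q <- length(params$levels)
  A <- adjacency_from_parameters(params, threshold)
  nm <- c(params$cont_names, params$cat_names)
  et <- edge_type_matrix(p, q)
  offs <- level_offsets(params$levels)
  block_weight <- function(a, b) {       # a < b, node indices
    if (b <= p) return(params$beta[a, b])
    if (a <= p) {
      v <- params$rho[offs[b - p] + seq_len(params$levels[b - p]), a]
      return(v[which.max(abs(v))])
    }
    B <- phi_block(params, a - p, b - p)
    B[which.max(abs(B))]
  }
  header <- c("# mgmsteps edge list",
              sprintf("#node%s%s%s%s", sep, nm, sep,
                      c(rep("continuous", p), rep("categorical", q))),
              paste(c("source", "target", "edge_type", "weight"),
                    collapse = sep))
  rows <- character(0)
  ord <- order(nm)
  for (ai in seq_len(p + q - 1)) for (bi in seq(ai + 1, p + q)) {
    a <- ord[ai]; b <- ord[bi]
    lo <- min(a, b); hi <- max(a, b)
    if (A[lo, hi] == 1)
      rows <- c(rows, paste(nm[lo], nm[hi], et[lo, hi],
                            sprintf("%.17g", block_weight(lo, hi)),
                            sep = sep))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, sep = "\t") {
  lines <- readLines(path)
  node_lines <- grep("^#node", lines, value = TRUE)
  parts <- strsplit(sub("^#node", "", node_lines), sep, fixed = TRUE)
  nm <- vapply(parts, function(x) x[2], character(1))
  types <- vapply(parts, function(x) x[3], character(1))
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]                       # column header
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (ln in body) {
    f <- strsplit(ln, sep, fixed = TRUE)[[1]]
    A[f[1], f[2]] <- A[f[2], f[1]] <- 1L
  }
  attr(A, "types") <- setNames(types, nm)
  A
}

#' Read and write MGM parameter containers
#'
#' A plain-text serialization of all parameter blocks (beta, alpha, rho,
#' phi), the level dictionaries and any training standardization, keyed by
#' variable names.  Numbers are written with 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param params an [mgm_params] object.
#' @param path file path.
#' @return `write_mgm_params` invisibly returns `path`;
#'   `read_mgm_params` returns the [mgm_params].
#' @export
write_mgm_params <- function(params, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  p <- length(params$alpha); q <- length(params$levels)
  out <- c("# mgmsteps parameters v1",
           paste0("p\t", p), paste0("q\t", q),
           paste0("cont_names\t", paste(params$cont_names, collapse = "\t")),
           paste0("cat_names\t", paste(params$cat_names, collapse = "\t")),
           paste0("levels\t", paste(params$levels, collapse = "\t")))
  out <- c(out, "beta",
           vapply(seq_len(p), function(s) num(params$beta[s, ]), character(1)))
  out <- c(out, "alpha", if (p > 0) num(params$alpha) else character(0))
  totL <- sum(params$levels)
  out <- c(out, "rho",
           vapply(seq_len(totL), function(l) num(params$rho[l, ]), character(1)))
  out <- c(out, "phi",
           vapply(seq_len(totL), function(l) num(params$phi[l, ]), character(1)))
  if (!is.null(params$scaling))
    out <- c(out, paste0("scaling_center\t", num(params$scaling$center)),
             paste0("scaling_scale\t", num(params$scaling$scale)))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_mgm_params
#' @export
read_mgm_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(fields, function(x) x[1], character(1))
  get1 <- function(key) fields[[match(key, keys)]][-1]
  p <- as.integer(get1("p")); q <- as.integer(get1("q"))
  cont_names <- if (p > 0) get1("cont_names") else character(0)
  cat_names <- if (q > 0) get1("cat_names") else character(0)
  levels <- if (q > 0) as.integer(get1("levels")) else integer(0)
  totL <- sum(levels)
  block <- function(key, nrows, ncols) {
    i <- match(key, keys)
    if (nrows == 0 || ncols == 0) return(matrix(0, nrows, ncols))
    m <- do.call(rbind, lapply(fields[i + seq_len(nrows)], as.numeric))
    matrix(m, nrows, ncols)
  }
  beta <- block("beta", p, p)
  alpha <- if (p > 0) as.numeric(fields[[match("alpha", keys) + 1L]]) else numeric(0)
  rho <- block("rho", totL, p)
  phi <- block("phi", totL, totL)
  out <- mgm_params(beta, alpha, rho, phi, levels, cont_names, cat_names)
  if ("scaling_center" %in% keys)
    out$scaling <- list(center = as.numeric(get1("scaling_center")),
                        scale = as.numeric(get1("scaling_scale")))
  out
}

#' Write an instability report
#'
#' One row per penalty value with the raw and monotonized total
#' instabilities, overall and per edge type, and the total subsample edge
#' counts.
#'
#' @param profile an [stability_profile()] result.
#' @param path file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_instability_report <- function(profile, path, sep = "\t") {
  tab <- data.frame(lambda = profile$lambdas,
                    dhat_all = profile$dhat$all, dhat_cc = profile$dhat$cc,
                    dhat_cd = profile$dhat$cd, dhat_dd = profile$dhat$dd,
                    dbar_all = profile$dbar$all, dbar_cc = profile$dbar$cc,
                    dbar_cd = profile$dbar$cd, dbar_dd = profile$dbar$dd,
                    edges_cc = profile$edge_counts[, "cc"],
                    edges_cd = profile$edge_counts[, "cd"],
                    edges_dd = profile$edge_counts[, "dd"])
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
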