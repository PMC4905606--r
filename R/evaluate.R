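#' Edge confusion counts between predicted and true graphs
#'
#' Counts TP/FP/FN/TN over the universe of unordered node pairs, overall
#' and restricted to each edge type; absence predictions count toward
#' TN/FN.  Per-type counts partition the overall counts exactly:
#' `choose(p, 2)` cc pairs, `p * q` cd pairs, `choose(q, 2)` dd pairs.
#'
#' @param predicted,truth symmetric binary adjacency matrices of equal
#'   size, ordered continuous variables first.
#' @param p,q numbers of continuous and categorical variables (default:
#'   inferred as all-continuous when omitted, i.e. a single `"all"` row is
#'   meaningful).
#' @param edge_type which rows to return: subset of
#'   `c("all", "cc", "cd", "dd")`.
#' @return A data.frame with columns `type`, `tp`, `fp`, `fn`, `tn`,
#'   `pairs`, of class `edge_confusion`.
#' @export
edge_confusion <- function(predicted, truth, p = nrow(predicted), q = 0L,
                           edge_type = c("all", "cc", "cd", "dd")) {
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth adjacencies differ in size")
  if (p + q != nrow(predicted)) stop("p + q must equal the matrix size")
  edge_type <- match.arg(edge_type, several.ok = TRUE)
  et <- edge_type_matrix(p, q)
  up <- upper.tri(truth)
  rows <- lapply(edge_type, function(ty) {
    keep <- if (ty == "all") up else up & et == ty
    pr <- predicted[keep] > 0
    tr <- truth[keep] > 0
    data.frame(type = ty,
               tp = sum(pr & tr), fp = sum(pr & !tr),
               fn = sum(!pr & tr), tn = sum(!pr & !tr),
               pairs = sum(keep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("edge_confusion", "data.frame")
  out
}

#' Edge-recovery metrics from confusion counts
#'
#' Standard binary-recovery metrics over unordered node pairs:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1,
#' accuracy `(TP+TN)/pairs`, and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#' {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' which equals 1 for perfect agreement, -1 for total disagreement and 0
#' for chance-level prediction, and is robust to the heavy
#' absence/presence imbalance of sparse graphs.  Metrics with a zero
#' denominator are reported as 0 and flagged in the `degenerate` column so
#' that averaging across datasets stays defined.
#'
#' @param confusion an [edge_confusion()] data.frame (any subset of rows).
#' @return The input with columns `precision`, `recall`, `f1`, `accuracy`,
#'   `mcc`, `degenerate` appended.
#' @export
recovery_metrics <- function(confusion) {
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  tp <- as.numeric(confusion$tp); fp <- as.numeric(confusion$fp)
  fn <- as.numeric(confusion$fn); tn <- as.numeric(confusion$tn)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  degenerate <- (tp + fp) == 0 | (tp + fn) == 0 | mcc_den == 0
  out <- cbind(confusion, precision = precision, recall = recall, f1 = f1,
               accuracy = accuracy, mcc = mcc, degenerate = degenerate)
  class(out) <- c("edge_confusion", "data.frame")
  out
}
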