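#' Confusion counts at a decision threshold
#'
#' A residue is called binding iff its probability is `>= threshold`
#' (ties count as positive calls). Padded positions are excluded via the
#' mask.
#'
#' @param probs,labels,mask Conforming vectors/matrices.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`, `n`,
#'   `threshold`.
#' @export
confusion_at_threshold <- function(probs, labels, mask = NULL, threshold = 0.5) {
  p <- as.vector(probs); y <- as.vector(labels)
  m <- if (is.null(mask)) rep(1, length(p)) else as.vector(mask)
  if (length(p) != length(y) || length(p) != length(m)) stop("shape mismatch")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  real <- m == 1
  if (!any(real)) stop("no real residues to evaluate")
  p <- p[real]; y <- y[real]
  call <- as.integer(p >= threshold)
  structure(list(tp = sum(call == 1L & y == 1L), fp = sum(call == 1L & y == 0L),
                 fn = sum(call == 0L & y == 1L), tn = sum(call == 0L & y == 0L),
                 n = length(p), threshold = threshold),
            class = "confusion_counts")
}

#' Threshold-dependent metric panel from confusion counts
#'
#' Computes precision, recall, F1, accuracy, balanced accuracy (BAC, the
#' mean of sensitivity and specificity) and the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Zero-division conventions: precision, recall and F1 are 0 when their
#' denominator is 0; MCC is 0 when any confusion-matrix marginal is 0.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `fp`,
#'   `fn`, `tn`).
#' @return Named numeric vector with elements `precision`, `recall`, `f1`,
#'   `accuracy`, `bac`, `mcc`.
#' @export
metric_panel <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  bac <- (recall + specificity) / 2
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = accuracy, bac = bac, mcc = mcc)
}

#' F1 as the harmonic mean of precision and recall
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return `2 P R / (P + R)` (0 when `P + R = 0`).
#' @export
f1_from_precision_recall <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' Equivalent to the probability that a random positive residue outranks a
#' random negative one, with half credit for tied scores (midrank
#' convention).
#'
#' @inheritParams confusion_at_threshold
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels, mask = NULL) {
  v <- masked_scores(probs, labels, mask)
  n1 <- sum(v$y == 1); n0 <- sum(v$y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC AUC undefined: both classes must be present among real residues")
  }
  r <- rank(v$p)
  (sum(r[v$y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Scores are swept from high to low; at each distinct score the curve
#' gains `(R_i - R_(i-1)) * P_i` (average-precision style step
#' integration, ties grouped at one threshold).
#'
#' @inheritParams confusion_at_threshold
#' @return Scalar PR AUC in `(0, 1]`.
#' @export
pr_auc <- function(probs, labels, mask = NULL) {
  v <- masked_scores(probs, labels, mask)
  n1 <- sum(v$y == 1)
  if (n1 == 0L || n1 == length(v$y)) {
    stop("PR AUC undefined: both classes must be present among real residues")
  }
  o <- order(v$p, decreasing = TRUE)
  ps <- v$p[o]; ys <- v$y[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(ps[-length(ps)] != ps[-1], TRUE)  # last index of each tied block
  precision <- tp[keep] / (tp[keep] + fp[keep])
  recall <- tp[keep] / n1
  sum(diff(c(0, recall)) * precision)
}

masked_scores <- function(probs, labels, mask) {
  p <- as.vector(probs); y <- as.vector(labels)
  m <- if (is.null(mask)) rep(1, length(p)) else as.vector(mask)
  if (length(p) != length(y) || length(p) != length(m)) stop("shape mismatch")
  real <- m == 1
  if (!any(real)) stop("no real residues to evaluate")
  list(p = p[real], y = y[real])
}

#' Evaluate a model on blind hold-out chains
#'
#' Pools all real residues of the evaluated chains (micro-averaging) and
#' reports the seven-metric panel in the conventional column order: AUC,
#' PR AUC, accuracy, precision, recall, F1, MCC, plus BAC and the
#' confusion counts. Cross-regime evaluation (e.g. an H-trained model on L
#' chains) is permitted. If `train_ids` is supplied, any overlap between
#' it and the evaluated complex ids is a hard error (leakage guard).
#'
#' @param state A trained `model_state`.
#' @param chains List of `labeled_chain` to evaluate.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @param train_ids Optional character vector of complex ids seen in
#'   training/validation.
#' @return A `metrics_report` list.
#' @export
evaluate_blind <- function(state, chains, threshold = 0.5, train_ids = NULL) {
  stopifnot(inherits(state, "model_state"), length(chains) > 0L)
  ids <- vapply(chains, `[[`, character(1), "complex_id")
  if (!is.null(train_ids)) {
    overlap <- intersect(unique(ids), train_ids)
    if (length(overlap)) {
      stop("leakage: evaluation complex id(s) were seen in training: ",
           paste(utils::head(overlap, 5), collapse = ", "))
    }
  }
  probs_list <- predict_chains(state, chains)
  p <- unlist(probs_list)
  y <- unlist(lapply(chains, `[[`, "labels"))
  counts <- confusion_at_threshold(p, y, threshold = threshold)
  panel <- metric_panel(counts)
  structure(
    list(threshold = threshold, counts = counts,
         auc = roc_auc(p, y), pr_auc = pr_auc(p, y),
         accuracy = panel[["accuracy"]], precision = panel[["precision"]],
         recall = panel[["recall"]], f1 = panel[["f1"]],
         bac = panel[["bac"]], mcc = panel[["mcc"]],
         n_chains = length(chains), n_residues = counts$n),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d chains, %d residues, threshold %.2f\n",
              x$n_chains, x$n_residues, x$threshold))
  vals <- c(AUC = x$auc, `PR AUC` = x$pr_auc, Accuracy = x$accuracy,
            Precision = x$precision, Recall = x$recall, F1 = x$f1,
            BAC = x$bac, MCC = x$mcc)
  print(round(vals, 3))
  invisible(x)
}

# flat named numeric vector of the seven-metric panel (table column order)
report_row <- function(report) {
  c(auc = report$auc, pr_auc = report$pr_auc, accuracy = report$accuracy,
    precision = report$precision, recall = report$recall, f1 = report$f1,
    mcc = report$mcc, bac = report$bac)
}

#' Aggregate per-fold metric reports as mean and standard deviation
#'
#' The spread is the sample standard deviation (n - 1 denominator).
#'
#' @param fold_reports List of at least two `metrics_report` objects (or
#'   named numeric vectors).
#' @return A data.frame with one row per metric: `metric`, `mean`, `sd`.
#' @export
aggregate_cv <- function(fold_reports) {
  if (length(fold_reports) < 2L) stop("need at least 2 folds to aggregate")
  rows <- lapply(fold_reports, function(r) {
    if (inherits(r, "metrics_report")) report_row(r) else r
  })
  m <- do.call(rbind, rows)
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd), row.names = NULL,
             stringsAsFactors = FALSE)
}
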