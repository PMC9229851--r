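# Dice objective and the confusion-matrix evaluation suite with ROC/PR
# curve areas for vessel-versus-background pixel classification.

#' Dice coefficient between two binary masks
#'
#' `(2|P n G| + w) / (|P| + |G| + w)`; the smoothing constant `w` keeps the
#' ratio defined when both masks are empty.
#'
#' @param P,G binary arrays of identical shape.
#' @param w smoothing constant (>= 0).
#' @return real in \[0, 1\].
#' @export
dice_coefficient <- function(P, G, w = 1e-5) {
  if (!identical(dim(P), dim(G)) || length(P) != length(G))
    stop("P and G must have identical shape")
  stopifnot(w >= 0)
  inter <- sum(P * G)
  (2 * inter + w) / (sum(P) + sum(G) + w)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + w) / (sum(p) + sum(g) + w)` on probabilities, the
#' differentiable training objective; exactly `1 - soft Dice`.
#'
#' @param probs probability array in \[0, 1\].
#' @param G binary array of the same shape.
#' @param w smoothing constant.
#' @return real in \[0, 1\].
#' @export
dice_loss <- function(probs, G, w = 1e-5) {
  if (length(probs) != length(G)) stop("shape mismatch")
  if (min(probs) < -1e-12 || max(probs) > 1 + 1e-12)
    stop("probs must lie in [0, 1]")
  1 - dice_coefficient(probs, G, w)
}

#' Confusion counts over the field of view
#'
#' Exhaustive four-way pixel classification of a binary prediction against
#' ground truth, restricted to pixels with `fov == 1`.
#'
#' @param pred binary prediction array.
#' @param G binary ground truth of the same shape.
#' @param fov binary evaluation mask of the same shape (`NULL` = all pixels).
#' @return a list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, G, fov = NULL) {
  if (length(pred) != length(G)) stop("shape mismatch between pred and G")
  if (is.null(fov)) fov <- rep(1, length(pred))
  if (length(fov) != length(pred)) stop("shape mismatch with fov")
  sel <- fov == 1
  p <- pred[sel]; g <- G[sel]
  structure(list(TP = sum(p == 1 & g == 1), TN = sum(p == 0 & g == 0),
                 FP = sum(p == 1 & g == 0), FN = sum(p == 0 & g == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warning(name, " is undefined (zero denominator)")
    return(NA_real_)
  }
  num / den
}

# full-sweep ROC and PR curves over all distinct score thresholds,
# trapezoidal areas
roc_pr_curves <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  P <- sum(y == 1); Ng <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)    # last index of each tied score
  tp <- c(0, tp[keep]); fp <- c(0, fp[keep])
  tpr <- if (P > 0) tp / P else rep(NA_real_, length(tp))
  fpr <- if (Ng > 0) fp / Ng else rep(NA_real_, length(fp))
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  auc_roc <- if (P > 0 && Ng > 0)
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2) else NA_real_
  auc_pr <- if (P > 0)
    sum(diff(tpr) * (prec[-1] + prec[-length(prec)]) / 2) else NA_real_
  list(roc = cbind(fpr = fpr, tpr = tpr),
       pr = cbind(recall = tpr, precision = prec),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Metric report from scores and ground truth
#'
#' Computes Dice, Accuracy, Sensitivity, Specificity and Precision from the
#' confusion counts at the given threshold, plus areas under the ROC and
#' precision-recall curves from the full threshold sweep. Undefined ratios
#' (zero denominators) are reported as `NA` with a warning, never silently 0.
#'
#' @param scores probability array.
#' @param G binary ground truth of the same shape.
#' @param fov binary evaluation mask (`NULL` = all pixels).
#' @param threshold binarization threshold in (0, 1).
#' @param counts optional precomputed [confusion()] counts consistent with
#'   the thresholded scores.
#' @return a list of class `metric_report` with the confusion counts, the
#'   five ratio metrics, `auc_roc`, `auc_pr` and the curve points.
#' @export
report <- function(scores, G, fov = NULL, threshold = 0.5, counts = NULL) {
  pred <- (scores >= threshold) * 1
  if (is.null(counts)) counts <- confusion(pred, G, fov)
  sel <- if (is.null(fov)) rep(TRUE, length(scores)) else fov == 1
  cv <- roc_pr_curves(as.numeric(scores[sel]), as.numeric(G[sel]))
  with(counts, {
    structure(list(
      counts = counts,
      dice = safe_ratio(2 * TP, 2 * TP + FN + FP, "dice"),
      accuracy = safe_ratio(TP + TN, TP + FN + FP + TN, "accuracy"),
      sensitivity = safe_ratio(TP, TP + FN, "sensitivity"),
      specificity = safe_ratio(TN, TN + FP, "specificity"),
      precision = safe_ratio(TP, TP + FP, "precision"),
      auc_roc = cv$auc_roc, auc_pr = cv$auc_pr,
      roc = cv$roc, pr = cv$pr, threshold = threshold
    ), class = "metric_report")
  })
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("Dice %.4f  Acc %.4f  Se %.4f  Sp %.4f  Pr %.4f  ",
                     "AUC_ROC %.4f  AUC_PR %.4f\n"),
              x$dice, x$accuracy, x$sensitivity, x$specificity, x$precision,
              x$auc_roc, x$auc_pr))
  invisible(x)
}

#' Serialize a metric report as a flat key-value record
#'
#' @param x a `metric_report`.
#' @param path output text file; when `NULL` the lines are returned.
#' @return character lines, invisibly when written.
#' @export
write_report <- function(x, path = NULL) {
  keys <- c("dice", "accuracy", "sensitivity", "specificity", "precision",
            "auc_roc", "auc_pr", "threshold")
  lines <- c(sprintf("%s\t%.6f", keys, vapply(keys, function(k)
    as.numeric(x[[k]]), numeric(1))),
    sprintf("%s\t%d", c("TP", "TN", "FP", "FN"),
            vapply(c("TP", "TN", "FP", "FN"), function(k)
              as.integer(x$counts[[k]]), integer(1))))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Export curve points as a two-column table
#'
#' @param x a `metric_report`.
#' @param which `"roc"` or `"pr"`.
#' @param path output TSV path; when `NULL` the matrix is returned.
#' @return the curve matrix.
#' @export
write_curve <- function(x, which = c("roc", "pr"), path = NULL) {
  which <- match.arg(which)
  m <- x[[which]]
  if (!is.null(path))
    utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(m)
}

# mean of per-image metric reports (counts summed for reference)
aggregate_reports <- function(reports) {
  keys <- c("dice", "accuracy", "sensitivity", "specificity", "precision",
            "auc_roc", "auc_pr")
  agg <- lapply(keys, function(k)
    mean(vapply(reports, function(r) as.numeric(r[[k]]), numeric(1)),
         na.rm = TRUE))
  names(agg) <- keys
  agg
}
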