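## Scoring of detection results against simulated ground truth.

#' Confusion counts at an FDR cutoff
#'
#' For one comparison label, classifies each testable protein as called
#' (`adj.pvalue < alpha`) or not, against the ground-truth differential
#' flag, and returns the confusion counts. The four counts partition the
#' testable proteins.
#'
#' @param results `tmt_comparison_result` rows restricted to one label
#'   (rows with missing p-values are ignored as untestable).
#' @param truth Data frame with columns `Protein` and either `Spike`
#'   (logical) or `true_log2FC` (nonzero = differential).
#' @param alpha FDR cutoff (default 0.05).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(results, truth, alpha = 0.05) {
  if (length(unique(results$Label)) > 1) {
    stop("restrict results to a single comparison label", call. = FALSE)
  }
  res <- results[!is.na(results$adj.pvalue), , drop = FALSE]
  miss <- setdiff(res$Protein, truth$Protein)
  if (length(miss) > 0) {
    stop("protein(s) in results absent from truth: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  flag <- if ("Spike" %in% names(truth)) {
    setNames(as.logical(truth$Spike), truth$Protein)
  } else {
    setNames(truth$true_log2FC != 0, truth$Protein)
  }
  pos <- res$adj.pvalue < alpha
  istrue <- unname(flag[res$Protein])
  c(TP = sum(pos & istrue), FP = sum(pos & !istrue),
    TN = sum(!pos & !istrue), FN = sum(!pos & istrue))
}

#' Empirical FDR, sensitivity and specificity
#'
#' `eFDR = FP / (TP + FP)` (0 by convention when nothing is called),
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param counts Named counts from [confusion_counts()].
#' @return Named numeric vector `c(eFDR, sensitivity, specificity)`.
#' @export
efdr_sens_spec <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  c(eFDR = if (TP + FP == 0) 0 else FP / (TP + FP),
    sensitivity = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    specificity = if (TN + FP == 0) NA_real_ else TN / (TN + FP))
}

#' Area under the ROC curve of the adjusted-p ranking
#'
#' AUC of ranking proteins by adjusted p-value (ascending, most significant
#' first) against the ground truth, computed by the Mann-Whitney identity
#' with midranks for ties.
#'
#' @inheritParams confusion_counts
#' @return AUC in [0, 1], or `NA` with a warning when the truth contains a
#'   single class.
#' @export
roc_auc <- function(results, truth) {
  res <- results[!is.na(results$adj.pvalue), , drop = FALSE]
  flag <- if ("Spike" %in% names(truth)) {
    setNames(as.logical(truth$Spike), truth$Protein)
  } else {
    setNames(truth$true_log2FC != 0, truth$Protein)
  }
  y <- unname(flag[res$Protein])
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    warning("ROC undefined: ground truth contains a single class",
            call. = FALSE)
    return(NA_real_)
  }
  r <- rank(-res$adj.pvalue, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate results against truth for every comparison label
#'
#' @param results Full `tmt_comparison_result`.
#' @param truth Ground-truth fold-change table with columns `Protein`,
#'   `Label`, `true_log2FC` (as produced by the simulator).
#' @param alpha FDR cutoff.
#' @return Data frame with one row per label: counts, eFDR, sensitivity,
#'   specificity, AUC.
#' @export
evaluate_results <- function(results, truth, alpha = 0.05) {
  labs <- unique(results$Label)
  do.call(rbind, lapply(labs, function(lb) {
    res <- results[results$Label == lb, , drop = FALSE]
    tr <- truth[truth$Label == lb, , drop = FALSE]
    cc <- confusion_counts(res, tr, alpha = alpha)
    mm <- efdr_sens_spec(cc)
    data.frame(Label = lb, TP = cc[["TP"]], FP = cc[["FP"]],
               TN = cc[["TN"]], FN = cc[["FN"]],
               eFDR = mm[["eFDR"]], sensitivity = mm[["sensitivity"]],
               specificity = mm[["specificity"]],
               AUC = suppressWarnings(roc_auc(res, tr)),
               stringsAsFactors = FALSE)
  }))
}
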