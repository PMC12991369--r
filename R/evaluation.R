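# Confusion-matrix metrics and tuning-grid sweeps. Essential is the
# positive class throughout; the three-way labels of the mixture
# classifier map 'ambiguous' to non-essential.

#' Confusion counts of an essentiality call
#'
#' @param truth Logical vector (`TRUE` = essential), optionally named by
#'   gene; or a `data.frame` with `gene_id` and `essential` columns.
#' @param labels Predicted labels in the same form (logical, or character
#'   `"essential"` / `"non-essential"` / `"ambiguous"`); when both sides
#'   carry gene identifiers the sets must match and are aligned by id.
#' @return A list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(truth, labels) {
  t_names <- NULL; l_names <- NULL
  if (is.data.frame(truth)) {
    t_names <- truth$gene_id; truth <- truth$essential
  } else t_names <- names(truth)
  if (is.data.frame(labels)) {
    l_names <- labels$gene_id
    labels <- if (!is.null(labels$essential)) labels$essential else labels$label
  } else l_names <- names(labels)
  if (is.character(labels)) labels <- labels == "essential"
  if (!is.null(t_names) && !is.null(l_names)) {
    if (!setequal(t_names, l_names))
      stop("gene sets of truth and labels differ")
    labels <- labels[match(t_names, l_names)]
  }
  if (length(truth) != length(labels))
    stop("truth and labels must cover the same genes")
  list(TP = sum(truth & labels), FP = sum(!truth & labels),
       FN = sum(truth & !labels), TN = sum(!truth & !labels))
}

#' Matthews correlation coefficient
#'
#' `(TP * TN - FP * FN) / sqrt((TP + FP)(TP + FN)(TN + FP)(TN + FN))`,
#' defined as 0 when any factor of the denominator is zero. MCC is 1 for
#' perfect agreement, 0 for random labeling, -1 for perfect disagreement,
#' and is robust to the strong class imbalance of essentiality screens.
#'
#' @param counts Confusion counts from [confusion()].
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Precision and recall
#'
#' Both are 0 (not NaN) when their denominator is empty.
#'
#' @param counts Confusion counts from [confusion()].
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(counts) {
  tp <- as.numeric(counts$TP)
  list(precision = if (tp + counts$FP == 0) 0 else tp / (tp + counts$FP),
       recall = if (tp + counts$FN == 0) 0 else tp / (tp + counts$FN))
}

#' Sweep a tuning grid and score against ground truth
#'
#' Runs one method across a grid of tuning values (weights or thresholds)
#' and reports, per value, the number of genes called essential and the
#' MCC / precision / recall against the truth labels.
#'
#' @inheritParams call_method
#' @param truth Truth labels, see [confusion()].
#' @param grid Tuning values to evaluate.
#' @return A `data.frame` with columns `tuning`, `n_called`, `TP`, `FP`,
#'   `FN`, `TN`, `mcc`, `precision`, `recall`.
#' @export
sweep_grid <- function(genes, iss, truth, method = "connis",
                       grid = seq(0.1, 1, by = 0.1), alpha = 0.05,
                       correction = "holm", trunc_frac = 0.05) {
  s <- summarize_genes(genes, iss, trunc_frac)
  theta <- genome_density(iss)
  fit <- if (method == "exp_gamma") fit_exp_gamma(s$insertion_index)
  rows <- lapply(grid, function(v) {
    res <- if (method == "exp_gamma")
      call_exp_gamma(genes, iss, t = v, summary = s, fit = fit)
    else
      call_method(genes, iss, method = method, tuning = v, alpha = alpha,
                  correction = correction, theta = theta, summary = s)
    cts <- confusion(truth, res)
    pr <- precision_recall(cts)
    data.frame(tuning = v, n_called = sum(res$essential), TP = cts$TP,
               FP = cts$FP, FN = cts$FN, TN = cts$TN, mcc = mcc(cts),
               precision = pr$precision, recall = pr$recall)
  })
  do.call(rbind, rows)
}
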