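# Evaluation stack: confusion matrices, per-class sensitivity and
# specificity (one-vs-rest), balanced accuracy, threshold-sweep ROC and
# AUC, and fold-mean aggregation.

#' Confusion matrix
#'
#' `counts[t, p]` is the number of slides with true class `t` predicted
#' as class `p`. Classes are 1-based integer indices in `1..C`.
#'
#' @param y_true,y_pred integer class labels in `1..C`.
#' @param C number of classes.
#' @return C x C integer matrix (rows = truth, columns = prediction).
#' @export
confusionMatrix <- function(y_true, y_pred, C) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  if (length(y_true) == 0L) stop("cannot tabulate empty inputs")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 1L | y_true > C) || any(y_pred < 1L | y_pred > C))
    stop("labels must lie in 1..C")
  m <- matrix(0L, C, C)
  for (i in seq_along(y_true))
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  m
}

#' Balanced accuracy (percent)
#'
#' Mean over classes of the per-class recall (diagonal over row sum),
#' times 100; every class equally weighted regardless of prevalence.
#'
#' @param m confusion matrix (rows = truth).
#' @return percent in `[0, 100]`.
#' @export
balancedAccuracy <- function(m) {
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("no samples of class ", paste(which(rs == 0), collapse = ", "),
         "; balanced accuracy undefined")
  mean(diag(as.matrix(m)) / rs) * 100
}

#' Per-class sensitivity and specificity (percent, one-vs-rest)
#'
#' Sensitivity is TP/(TP+FN) for class `cls`; specificity is TN/(TN+FP)
#' with all other classes pooled as the negative set.
#'
#' @param m confusion matrix (rows = truth).
#' @param cls 1-based class index.
#' @return named numeric: `sensitivity`, `specificity`, both in
#'   `[0, 100]`.
#' @export
sensSpec <- function(m, cls) {
  m <- as.matrix(m)
  C <- nrow(m)
  stopifnot(cls >= 1, cls <= C)
  if (sum(m[cls, ]) == 0) stop("class ", cls, " has no samples")
  tp <- m[cls, cls]
  fn <- sum(m[cls, ]) - tp
  fp <- sum(m[, cls]) - tp
  tn <- sum(m) - tp - fn - fp
  if (tn + fp == 0)
    stop("class ", cls, " has no negatives; specificity undefined")
  c(sensitivity = 100 * tp / (tp + fn), specificity = 100 * tn / (tn + fp))
}

#' Threshold-sweep ROC curve and AUC
#'
#' Sweeps every distinct score as a decision threshold (plus the two
#' endpoints) to trace the (FPR, TPR) curve, and integrates it by the
#' trapezoid rule. Ties receive half credit, so the AUC equals the
#' Mann-Whitney pair-count statistic.
#'
#' @param scores per-slide probability (or score) for the positive side.
#' @param labels binary labels: logical, or 0/1, or a two-level factor
#'   whose second level is positive.
#' @return list: `curve` (data.frame `fpr`, `tpr`, `threshold`), `auc`.
#' @export
rocAuc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!any(labels) || all(labels))
    stop("ROC needs both positive and negative labels")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Build an EvalReport from predictions
#'
#' @param y_true,y_pred integer labels in `1..C`.
#' @param probs optional n x C matrix of class probabilities (for the
#'   one-vs-rest AUCs; classes absent from `y_true` get `NA`).
#' @param C number of classes.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(y_true, y_pred, probs = NULL, C) {
  m <- confusionMatrix(y_true, y_pred, C)
  ss <- vapply(seq_len(C), function(cl) {
    if (sum(m[cl, ]) == 0) return(c(NA_real_, NA_real_))
    sensSpec(m, cl)
  }, numeric(2))
  auc <- rep(NA_real_, C)
  if (!is.null(probs)) {
    for (cl in seq_len(C)) {
      pos <- y_true == cl
      if (any(pos) && !all(pos))
        auc[cl] <- rocAuc(probs[, cl], pos)$auc
    }
  }
  new("EvalReport", confusion = m, sensitivity = ss[1, ],
      specificity = ss[2, ], balancedAccuracy = balancedAccuracy(m),
      auc = auc, nSlides = length(y_true))
}

#' Aggregate per-fold reports into a mean report
#'
#' Scalar metrics (balanced accuracy, per-class sensitivity, specificity
#' and AUC) are averaged arithmetically across folds; confusion matrices
#' are summed element-wise.
#'
#' @param reports nonempty list of [EvalReport-class] with matching
#'   class counts.
#' @return an [EvalReport-class].
#' @export
aggregateFolds <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate")
  Cs <- vapply(reports, function(r) nrow(r@confusion), integer(1))
  if (length(unique(Cs)) != 1L)
    stop("reports disagree on the number of classes")
  conf <- Reduce(`+`, lapply(reports, function(r) r@confusion))
  meanrows <- function(get) {
    rowMeans(vapply(reports, get, numeric(Cs[1])))
  }
  new("EvalReport",
      confusion = conf,
      sensitivity = meanrows(function(r) r@sensitivity),
      specificity = meanrows(function(r) r@specificity),
      balancedAccuracy = mean(vapply(reports, function(r)
        r@balancedAccuracy, numeric(1))),
      auc = meanrows(function(r) r@auc),
      nSlides = sum(vapply(reports, function(r) r@nSlides, numeric(1))))
}

#' Write an EvalReport to JSON (plus CSV side files)
#'
#' @param report an [EvalReport-class].
#' @param path JSON file path; `<path>.confusion.csv` and, when curves
#'   are supplied, `<path>.roc.csv` are written next to it.
#' @param roc optional list of per-class ROC curves from [rocAuc()].
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path, roc = NULL) {
  stopifnot(is(report, "EvalReport"))
  jsonlite::write_json(
    list(balanced_accuracy = report@balancedAccuracy,
         sensitivity = report@sensitivity,
         specificity = report@specificity,
         auc = report@auc,
         n_slides = report@nSlides),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  data.table::fwrite(as.data.frame(report@confusion),
                     paste0(path, ".confusion.csv"))
  if (!is.null(roc)) {
    pts <- do.call(rbind, lapply(seq_along(roc), function(i)
      cbind(class = i, roc[[i]]$curve)))
    data.table::fwrite(pts, paste0(path, ".roc.csv"))
  }
  invisible(path)
}
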