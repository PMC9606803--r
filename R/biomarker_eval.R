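#' Cluster-mean feature matrix
#'
#' For each subject and each cluster mask, the feature is the mean of that
#' subject's map inside the mask (e.g. the association-z of the hub cluster,
#' or the seed-FC z of a target cluster).
#'
#' @param maps_by_feature Named list; each element is a list of per-subject
#'   [voxel_map()]s for one feature.
#' @param masks Named list of logical 3-D cluster masks, aligned with
#'   `maps_by_feature`.
#' @return n_subjects x n_features numeric matrix with feature labels.
#' @export
extract_cluster_features <- function(maps_by_feature, masks) {
  stopifnot(length(maps_by_feature) == length(masks))
  feats <- mapply(function(maps, mask) {
    mask <- array(as.logical(mask), dim(maps[[1]]$values))
    if (!any(mask)) stop("empty cluster mask", call. = FALSE)
    if (!all(dim(mask) == dim(maps[[1]]$values)))
      stop("mask outside map grid", call. = FALSE)
    vapply(maps, function(m) mean(m$values[mask]), numeric(1))
  }, maps_by_feature, masks)
  feats <- matrix(feats, ncol = length(masks),
                  dimnames = list(NULL, names(masks)))
  if (any(!is.finite(feats))) stop("non-finite feature values",
                                   call. = FALSE)
  feats
}

#' Confusion metrics with the patient group as positive class
#'
#' Accuracy = (TP + TN) / n, sensitivity = TP / P, specificity = TN / N,
#' reported as percentages.
#'
#' @param predictions Character/factor vector of predicted labels.
#' @param labels True labels.
#' @param positive Positive-class label (default `"AD"`).
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the `confusion` counts (tp, fn, tn, fp).
#' @export
confusion_metrics <- function(predictions, labels, positive = "AD") {
  if (length(predictions) == 0L) stop("empty input", call. = FALSE)
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  pos <- labels == positive
  tp <- sum(pos & predictions == positive)
  fn <- sum(pos & predictions != positive)
  tn <- sum(!pos & predictions != positive)
  fp <- sum(!pos & predictions == positive)
  list(accuracy = 100 * (tp + tn) / length(labels),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from midranks; equal to
#' trapezoidal integration of the ROC curve.
#'
#' @param decision_values Numeric scores, larger = more positive-class.
#' @param labels True labels.
#' @param positive Positive-class label (default `"AD"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(decision_values, labels, positive = "AD") {
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(decision_values)  # midranks handle ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-out cross-validated linear SVM
#'
#' Each subject is held out once; features are standardized on the training
#' fold only, a linear support vector machine (cost 1) is fitted, and the
#' held-out prediction and decision value are recorded. Metrics are computed
#' from the pooled held-out predictions; AUC uses the held-out decision
#' values with the patient group as positive class.
#'
#' @param features n x f numeric feature matrix.
#' @param labels Group labels (`"AD"` / `"HC"` by default conventions).
#' @param positive Positive-class label.
#' @param cost SVM cost parameter (default 1).
#' @param seed Unused by the deterministic fit; kept so callers can thread a
#'   seed uniformly through stochastic and deterministic stages.
#' @return List of class `classifier_report`: `accuracy`, `sensitivity`,
#'   `specificity` (percent), `auc`, `confusion`, `predictions`,
#'   `decision_values` (oriented so larger = more positive-class).
#' @export
loocv_linear_svm <- function(features, labels, positive = "AD", cost = 1,
                             seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels/features mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need >= 2 subjects per class", call. = FALSE)
  preds <- character(n)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (length(unique(tr_y)) < 2L)
      stop("single-class training fold", call. = FALSE)
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    zs <- function(x) sweep(sweep(x, 2L, mu), 2L, sdv, "/")
    fit <- e1071::svm(zs(tr_x), factor(tr_y), kernel = "linear",
                      cost = cost, scale = FALSE)
    pr <- stats::predict(fit, zs(features[i, , drop = FALSE]),
                         decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients the decision value toward the first training level
    if (!startsWith(colnames(attr(pr, "decision.values"))[1],
                    paste0(positive, "/")))
      dv <- -dv
    preds[i] <- as.character(pr)
    dec[i] <- dv
  }
  met <- confusion_metrics(preds, labels, positive)
  structure(c(met, list(auc = roc_auc(dec, labels, positive),
                        predictions = preds, decision_values = dec,
                        labels = labels)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> accuracy %.2f%%, sensitivity ",
                     "%.2f%%, specificity %.2f%%, AUC %.3f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Brain-behavior Pearson correlations with FDR control
#'
#' Pearson r and two-sided p for every (feature, score) pair, with
#' Benjamini-Hochberg step-up q-values over the whole tested family.
#' Zero-variance vectors are flagged and excluded from the family with a
#' warning.
#'
#' @param features n x f feature matrix with column labels.
#' @param scores n x s matrix or data.frame of cognitive scores (e.g.
#'   columns `mmse`, `moca`).
#' @return data.frame with columns `feature`, `score`, `r`, `p`, `q`.
#' @export
pearson_with_fdr <- function(features, scores) {
  features <- as.matrix(features)
  scores <- as.data.frame(scores)
  if (nrow(features) != nrow(scores))
    stop("features and scores differ in rows", call. = FALSE)
  if (nrow(features) < 4L)
    stop("need >= 4 paired observations", call. = FALSE)
  rows <- list()
  skipped <- character()
  for (f in colnames(features)) {
    for (s in colnames(scores)) {
      x <- features[, f]; y <- scores[[s]]
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        skipped <- c(skipped, sprintf("(%s, %s)", f, s))
        next
      }
      ct <- stats::cor.test(x, y)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, score = s,
                   r = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (length(skipped))
    warning("zero variance in ", paste(skipped, collapse = ", "),
            "; excluded from FDR family", call. = FALSE)
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
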