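# Performance reporting: confusion matrix, accuracy/precision/recall/F1,
# ROC curve with trapezoid AUC, and stratified k-fold cross-validation.

#' Confusion matrix from 0-based integer labels
#'
#' @param true_labels,predicted_labels equal-length integer vectors with
#'   entries in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return `n_classes` x `n_classes` integer matrix; entry (i, j) counts
#'   samples with true class i-1 predicted as class j-1 (rows = true).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (any(c(true_labels, predicted_labels) < 0) ||
      any(c(true_labels, predicted_labels) >= n_classes)) {
    stop("label index out of range [0, ", n_classes, ")", call. = FALSE)
  }
  m <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(true_labels)) {
    i <- true_labels[k] + 1L
    j <- predicted_labels[k] + 1L
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Binary case (2 x 2): the positive class is label index 1 (the
#' lexicographically second label) unless `positive` says otherwise;
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean,
#' each 0 by convention when its denominator is 0. Multiclass: macro
#' average of the one-vs-rest values.
#'
#' @param confusion square integer matrix, rows = true classes.
#' @param positive positive class index (0-based) for the binary case.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(confusion, positive = 1L) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  n <- nrow(confusion)
  one_vs_rest <- function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1)
  }
  prf <- if (n == 2L) {
    one_vs_rest(positive + 1L)
  } else {
    rowMeans(vapply(seq_len(n), one_vs_rest, numeric(3)))
  }
  list(accuracy = sum(diag(confusion)) / total,
       precision = unname(prf["precision"]),
       recall = unname(prf["recall"]),
       f1 = unname(prf["f1"]))
}

#' ROC curve and trapezoid AUC for binary scores
#'
#' Thresholds sweep the distinct scores in descending order with ties
#' grouped; the curve starts at (0, 0) and ends at (1, 1) and the AUC is
#' the trapezoid-rule area (equivalently the Mann-Whitney U statistic over
#' positive/negative pairs). With a single-class truth the AUC is `NA`.
#'
#' @param true_labels binary 0/1 vector (1 = positive).
#' @param positive_scores real scores, higher = more positive.
#' @return List with `roc_points` (data.frame `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_curve <- function(true_labels, positive_scores) {
  if (length(true_labels) != length(positive_scores)) {
    stop("labels and scores have different lengths", call. = FALSE)
  }
  n_pos <- sum(true_labels == 1)
  n_neg <- sum(true_labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    return(list(roc_points = data.frame(fpr = c(0, 1), tpr = c(0, 1),
                                        threshold = c(Inf, -Inf)),
                auc = NA_real_))
  }
  thr <- sort(unique(positive_scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t)
    sum(true_labels == 1 & positive_scores >= t) / n_pos, 0))
  fpr <- c(0, vapply(thr, function(t)
    sum(true_labels == 0 & positive_scores >= t) / n_neg, 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr,
                               threshold = c(Inf, thr)),
       auc = auc)
}

#' Full evaluation report for a model on labeled features
#'
#' @param model a `phenodnn_model` (or bare network).
#' @param features feature matrix.
#' @param labels 0-based integer true labels.
#' @param positive positive class index for binary metrics/ROC.
#' @return An `evaluation_report`: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc` (binary only, macro one-vs-rest otherwise), `roc_points`
#'   (binary only), `confusion`.
#' @export
evaluate_model <- function(model, features, labels, positive = 1L) {
  net <- if (inherits(model, "phenodnn_model")) model$network else model
  p <- predict_proba(model, features)
  pred <- max.col(p, ties.method = "first") - 1L
  conf <- confusion_matrix(labels, pred, net$n_classes)
  metrics <- classification_metrics(conf, positive)
  if (net$n_classes == 2L) {
    roc <- roc_curve(as.integer(labels == positive), p[, positive + 1L])
    auc <- roc$auc
    roc_points <- roc$roc_points
  } else {
    aucs <- vapply(seq_len(net$n_classes) - 1L, function(k)
      roc_curve(as.integer(labels == k), p[, k + 1L])$auc, 0)
    auc <- mean(aucs, na.rm = TRUE)
    roc_points <- NULL
  }
  structure(c(metrics, list(auc = auc, roc_points = roc_points,
                            confusion = conf)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f  auc %s\n",
    x$accuracy, x$precision, x$recall, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  cat("confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Samples of each class are shuffled with the seed and dealt round-robin
#' into k folds (fold sizes within one sample per class). For each fold the
#' full preprocessing pipeline (abundance filter, CSS state) is refit on
#' the training portion only, a network is trained, and accuracy is
#' measured on the held-out fold.
#'
#' @param table raw `abundance_table`.
#' @param meta `sample_metadata`.
#' @param pre_config a [preprocess_config()].
#' @param net_config a [network_config()].
#' @param k number of folds (every class must have >= k samples).
#' @param seed integer seed for the fold assignment.
#' @return List with `fold_accuracy` (length k) and `mean_accuracy`.
#' @export
cross_validate <- function(table, meta, pre_config = preprocess_config(),
                           net_config = network_config(), k = 5L,
                           seed = 1L) {
  aligned <- align_table_metadata(table, meta, "intersect")
  table <- aligned$table; meta <- aligned$meta
  counts <- table(meta$mapping)
  if (any(counts < k)) {
    stop("class '", names(counts)[which(counts < k)[1]],
         "' has fewer than k = ", k, " samples", call. = FALSE)
  }
  fold_of <- stats::setNames(integer(length(meta$mapping)),
                             names(meta$mapping))
  withr::with_seed(seed, {
    for (cls in meta$label_order) {
      ids <- names(meta$mapping)[meta$mapping == cls]
      ids <- ids[sample.int(length(ids))]
      fold_of[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  accs <- vapply(seq_len(k), function(fold) {
    test_ids <- names(fold_of)[fold_of == fold]
    train_ids <- names(fold_of)[fold_of != fold]
    split <- structure(list(train_ids = train_ids,
                            validation_ids = character(),
                            test_ids = test_ids, seed = seed),
                       class = "data_split")
    model <- fit_phenodnn(table, meta, pre_config, net_config, split = split)
    test_table <- subset_samples(table, test_ids)
    pred <- predict_table(model, test_table)
    mean(pred$predicted_label == unname(meta$mapping[test_ids]))
  }, 0)
  list(fold_accuracy = accs, mean_accuracy = mean(accs))
}
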