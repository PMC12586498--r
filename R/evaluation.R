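#' One-vs-rest confusion counts
#'
#' @param labels,predictions Equal-length integer class vectors.
#' @param positive_class The class treated as positive.
#' @return Named numeric vector `(TP, FP, FN, TN)`.
#' @export
binary_counts <- function(labels, predictions, positive_class) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length", call. = FALSE)
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  c(TP = sum(pos & ppos), FP = sum(!pos & ppos),
    FN = sum(pos & !ppos), TN = sum(!pos & !ppos))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Ratios with a zero denominator are reported as 0 and flagged in
#' `undefined` (keeps per-class tables machine-readable).
#'
#' @param counts Named vector `(TP, FP, FN, TN)` from [binary_counts()].
#' @return List: `accuracy`, `precision`, `recall`, `f1`, `undefined`
#'   (character vector of flagged metrics).
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]; tn <- counts[["TN"]]
  total <- tp + fp + fn + tn
  if (total == 0) stop("all-zero counts", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (tp + tn) / total, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

# One-vs-rest ROC for one class by threshold sweep with ties grouped.
roc_one <- function(scores, positive) {
  P <- sum(positive); Nn <- sum(!positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  ends <- which(diff(c(s, -Inf)) != 0)  # last index of each tie group
  tp <- cumsum(p)[ends]; fp <- cumsum(!p)[ends]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' Per class, sweeps thresholds over that class's predicted probability
#' (equal scores move together), builds the ROC polyline and integrates the
#' AUC by the trapezoidal rule. The macro AUC is the unweighted mean over
#' classes present in the labels; absent classes are flagged and excluded.
#'
#' @param scores N x C matrix of class probabilities.
#' @param labels Integer labels (0-based).
#' @return A `roc_curve` list: `per_class` (points + auc each), `auc`
#'   (per-class vector, NA where undefined), `macro_auc`, `missing_classes`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  C <- ncol(scores)
  per <- vector("list", C)
  aucs <- rep(NA_real_, C)
  missing <- integer(0)
  for (cl in seq_len(C)) {
    pos <- labels == cl - 1L
    if (!any(pos) || all(pos)) { missing <- c(missing, cl - 1L); next }
    per[[cl]] <- roc_one(scores[, cl], pos)
    aucs[cl] <- per[[cl]]$auc
  }
  structure(list(per_class = per, auc = aucs,
                 macro_auc = mean(aucs, na.rm = TRUE),
                 missing_classes = missing),
            class = "roc_curve")
}

#' Evaluate a trained model on labeled samples
#'
#' Runs the forward pass on every sample and assembles the confusion matrix
#' (rows = true class, columns = predicted), per-class and macro precision /
#' recall / F1, overall accuracy, and one-vs-rest ROC/AUC. Per-class recall
#' equals the confusion-matrix diagonal over the row sum.
#'
#' @param model A trained `leafproto_model`.
#' @param samples List of [image_sample()] to evaluate (e.g. the test split).
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, samples) {
  if (length(samples) == 0) abort_config("empty evaluation set")
  samples <- resize_all(samples, model$backbone$input_side)
  C <- model$n_classes
  probs <- matrix(0, length(samples), C)
  preds <- integer(length(samples))
  for (i in seq_along(samples)) {
    p <- predict_volume(extract_features(samples[[i]], model$backbone, model$params),
                        model$bank, model$head)
    probs[i, ] <- p$probabilities
    preds[i] <- p$predicted_class
  }
  labels <- sample_labels(samples)
  confusion <- matrix(0L, C, C,
                      dimnames = list(true = 0:(C - 1), predicted = 0:(C - 1)))
  for (i in seq_along(labels))
    confusion[labels[i] + 1L, preds[i] + 1L] <- confusion[labels[i] + 1L, preds[i] + 1L] + 1L
  per_class <- lapply(0:(C - 1), function(cl)
    classification_metrics(binary_counts(labels, preds, cl)))
  roc <- roc_auc(probs, labels)
  structure(list(
    accuracy = mean(preds == labels),
    per_class = data.frame(
      class = 0:(C - 1),
      precision = vapply(per_class, `[[`, 0, "precision"),
      recall = vapply(per_class, `[[`, 0, "recall"),
      f1 = vapply(per_class, `[[`, 0, "f1"),
      undefined = vapply(per_class, function(x) paste(x$undefined, collapse = ";"), "")),
    macro_precision = mean(vapply(per_class, `[[`, 0, "precision")),
    macro_recall = mean(vapply(per_class, `[[`, 0, "recall")),
    macro_f1 = mean(vapply(per_class, `[[`, 0, "f1")),
    confusion = confusion,
    roc = roc,
    macro_auc = roc$macro_auc,
    predictions = data.frame(image_id = sample_ids(samples), label = labels,
                             predicted = preds),
    probabilities = probs), class = "eval_report")
}

#' Write an evaluation report to disk
#'
#' JSON report plus CSVs for the confusion matrix, per-sample predictions
#' (with probabilities) and ROC points.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(accuracy = report$accuracy,
               macro_precision = report$macro_precision,
               macro_recall = report$macro_recall,
               macro_f1 = report$macro_f1,
               macro_auc = report$macro_auc,
               per_class = report$per_class,
               per_class_auc = report$roc$auc,
               confusion = unname(apply(report$confusion, 1, as.list)))
  path <- file.path(dir, "eval_report.json")
  write_json_file(json, path)
  write.csv(as.data.frame(report$confusion), file.path(dir, "confusion.csv"))
  pr <- cbind(report$predictions,
              as.data.frame(report$probabilities,
                            col.names = paste0("p", seq_len(ncol(report$probabilities)))))
  write.csv(pr, file.path(dir, "predictions.csv"), row.names = FALSE)
  rocs <- do.call(rbind, lapply(seq_along(report$roc$per_class), function(cl) {
    pc <- report$roc$per_class[[cl]]
    if (is.null(pc)) return(NULL)
    cbind(class = cl - 1L, pc$points)
  }))
  if (!is.null(rocs)) write.csv(rocs, file.path(dir, "roc_points.csv"), row.names = FALSE)
  invisible(path)
}

#' k-fold cross-validation of the full training pipeline
#'
#' Trains and evaluates once per fold of a stratified k-fold partition and
#' reports per-fold accuracies, their mean, and the spread (max - min), the
#' stability notion used for this architecture.
#'
#' @param samples List of [image_sample()].
#' @param k Number of folds.
#' @param config A [train_config()].
#' @param backbone A [backbone_config()].
#' @param ... Passed to [train_model()].
#' @param seed Seed for the fold assignment.
#' @return List: `reports`, `fold_accuracies`, `mean_accuracy`, `spread`.
#' @export
cross_validate <- function(samples, k, config, backbone = backbone_config(
  input_side = config$input_side), ..., seed = config$seed) {
  manifests <- make_kfold_splits(samples, k, seed)
  reports <- lapply(manifests, function(mf) {
    sp <- apply_split(samples, mf)
    fit <- train_model(sp, config, backbone, ...)
    evaluate_model(fit$model, sp[vapply(sp, function(s) s$split, "") == "test"])
  })
  accs <- vapply(reports, `[[`, 0, "accuracy")
  list(reports = reports, fold_accuracies = accs,
       mean_accuracy = mean(accs), spread = max(accs) - min(accs))
}
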