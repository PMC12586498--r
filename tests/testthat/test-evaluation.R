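test_that("binary counts enumerate one-vs-rest outcomes", {
  labs <- c(rep(1, 10), rep(0, 10))
  expect_equal(binary_counts(labs, labs, 1),
               c(TP = 10, FP = 0, FN = 0, TN = 10))
  # all predicted positive, 3 of 10 actually positive
  labs2 <- c(rep(1, 3), rep(0, 7))
  expect_equal(binary_counts(labs2, rep(1, 10), 1),
               c(TP = 3, FP = 7, FN = 0, TN = 0))
  # vacuous positive class
  expect_equal(binary_counts(rep(0, 5), rep(0, 5), 1)[c("TP", "FN")],
               c(TP = 0, FN = 0))
  expect_error(binary_counts(1:3, 1:4, 1), "equal length")
})

test_that("classification metrics reproduce hand-computed values", {
  m <- classification_metrics(c(TP = 8, FP = 2, FN = 1, TN = 9))
  expect_equal(m$accuracy, 0.85, tolerance = 1e-9)
  expect_equal(m$precision, 0.8, tolerance = 1e-9)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-9)
  expect_length(m$undefined, 0)
  perfect <- classification_metrics(c(TP = 5, FP = 0, FN = 0, TN = 7))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  deg <- classification_metrics(c(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(deg$accuracy, 0.5)
  expect_equal(deg$precision, 0)
  expect_equal(deg$recall, 0)
  expect_true("precision" %in% deg$undefined)
  expect_error(classification_metrics(c(TP = 0, FP = 0, FN = 0, TN = 0)), "zero")
})

test_that("AUC is 1, 0.5 and 0 on separable, constant and inverted scores", {
  labels <- c(rep(0, 5), rep(1, 5))
  sep <- cbind(c(rep(0.9, 5), rep(0.1, 5)), c(rep(0.1, 5), rep(0.9, 5)))
  r <- roc_auc(sep, labels)
  expect_equal(r$auc, c(1, 1))
  const <- matrix(0.5, 10, 2)
  expect_equal(roc_auc(const, labels)$auc, c(0.5, 0.5))
  inv <- sep[, c(2, 1)]
  expect_equal(roc_auc(inv, labels)$auc, c(0, 0))
})

test_that("AUC is invariant under strictly monotone score transforms and flags absent classes", {
  set.seed(61)
  labels <- sample(0:2, 40, replace = TRUE)
  raw <- matrix(runif(40 * 3), 40, 3)
  r1 <- roc_auc(raw, labels)
  r2 <- roc_auc(exp(3 * raw), labels)  # strictly monotone per column
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  # absent class flagged and excluded from the macro mean
  labels2 <- labels; labels2[labels2 == 2] <- 1
  r3 <- roc_auc(raw, labels2)
  expect_true(2 %in% r3$missing_classes)
  expect_equal(r3$macro_auc, mean(r3$auc[1:2]))
})

test_that("AUC agrees with an independent implementation on random scores", {
  set.seed(62)
  for (rep in 1:5) {
    labels <- sample(0:1, 30, replace = TRUE)
    scores <- runif(30)
    mine <- roc_auc(cbind(1 - scores, scores), labels)$auc[2]
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("evaluation report satisfies its counting identities", {
  fit <- micro_fit()
  te <- micro_dataset()
  te <- te[vapply(te, function(s) s$split == "test", TRUE)]
  rep_ <- evaluate_model(fit$model, te)
  # confusion-matrix row sums equal per-class test counts
  expect_equal(unname(rowSums(rep_$confusion)),
               as.vector(table(factor(leafproto:::sample_labels(te), levels = 0:1))))
  # accuracy equals trace / total
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion),
               tolerance = 1e-12)
  # macro metrics are unweighted means of the per-class values
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1), tolerance = 1e-12)
  expect_true(all(rep_$per_class$precision >= 0 & rep_$per_class$precision <= 1))
  # probabilities are a valid distribution per sample
  expect_equal(unname(rowSums(rep_$probabilities)), rep(1, length(te)),
               tolerance = 1e-6)
})

test_that("report metrics match an independent recomputation from saved predictions", {
  fit <- micro_fit()
  te <- micro_dataset()
  te <- te[vapply(te, function(s) s$split == "test", TRUE)]
  rep_ <- evaluate_model(fit$model, te)
  labs <- rep_$predictions$label
  preds <- rep_$predictions$predicted
  expect_equal(rep_$accuracy, mean(labs == preds), tolerance = 1e-9)
  for (cl in 0:1) {
    tp <- sum(labs == cl & preds == cl); fp <- sum(labs != cl & preds == cl)
    fn <- sum(labs == cl & preds != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(rep_$per_class$precision[cl + 1], prec, tolerance = 1e-9)
    expect_equal(rep_$per_class$recall[cl + 1], rec, tolerance = 1e-9)
  }
})

test_that("evaluation artifacts serialize to disk", {
  fit <- micro_fit()
  te <- micro_dataset()
  te <- te[vapply(te, function(s) s$split == "test", TRUE)]
  rep_ <- evaluate_model(fit$model, te)
  dir <- withr::local_tempdir()
  write_eval_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "eval_report.json")))
  expect_true(file.exists(file.path(dir, "confusion.csv")))
  expect_true(file.exists(file.path(dir, "predictions.csv")))
  back <- jsonlite::read_json(file.path(dir, "eval_report.json"))
  expect_equal(back$accuracy, rep_$accuracy, tolerance = 1e-12)
})

test_that("cross-validation yields one report per fold and a coherent mean", {
  ds <- micro_dataset()
  cfg <- desk_train_config(seed = 8, epochs = 1, batch_size = 8, input_side = 32,
                           push_every = 1, head_tune_epochs = 1)
  cv <- cross_validate(ds, 2, cfg,
                       backbone_config(input_side = 32, addon_channels = 8),
                       per_class = 2, embed_dim = 8)
  expect_length(cv$reports, 2)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies), tolerance = 1e-12)
  expect_equal(cv$spread, max(cv$fold_accuracies) - min(cv$fold_accuracies))
})
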