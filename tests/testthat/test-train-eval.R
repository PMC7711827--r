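test_that("stratified folds are balanced per class and partition the data", {
  labels <- rep(c("malignant", "degenerative", "normal"), c(328, 271, 179))
  fold <- stratified_kfold(labels, 10, seed = 1)
  expect_identical(length(fold), 778L)
  expect_equal(sort(unique(fold)), 0:9)
  tab <- table(labels, fold)
  expect_true(all(tab["malignant", ] %in% 32:33))
  expect_true(all(tab["degenerative", ] %in% 27:28))
  expect_true(all(tab["normal", ] %in% 17:18))
  # every record appears in exactly one test fold
  expect_identical(as.integer(table(fold)), as.integer(colSums(tab)))
  expect_identical(sum(tab), 778L)
  expect_error(stratified_kfold(labels, 1), "folds")
  expect_error(stratified_kfold(rep(c("a", "b"), c(5, 100)), 10), "fewer than")
})

test_that("one-vs-rest counts decompose the confusion matrix", {
  cm <- confusion_from_labels(c(rep(0L, 5), rep(1L, 6), rep(2L, 7)),
                              c(rep(0L, 5), rep(1L, 6), rep(2L, 7)))
  expect_equal(unname(one_vs_rest_counts(cm, "malignant")), c(6, 0, 12, 0))
  # single-class test set: everything is the positive class
  cm1 <- confusion_from_labels(rep(0L, 18), rep(0L, 18))
  expect_equal(unname(one_vs_rest_counts(cm1, "normal")), c(18, 0, 0, 0))
  # conservation for every class
  for (cl in scint_classes())
    expect_equal(sum(one_vs_rest_counts(cm, cl)), sum(cm))
})

test_that("metric formulas agree exactly with a brute-force recount oracle", {
  set.seed(99)
  n_trials <- 1e4
  for (t in seq_len(n_trials)) {
    n <- sample(5:40, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    cm <- confusion_from_labels(truth, pred)
    cl <- sample(0:2, 1)
    counts <- one_vs_rest_counts(cm, cl + 1L)
    got <- suppressWarnings(class_metrics(counts))
    want <- oracle_metrics(truth, pred, cl)
    if (sum(counts) != want[["counts_sum"]])
      expect_equal(sum(counts), want[["counts_sum"]])
    for (m in c("precision", "recall", "f1", "sensitivity", "specificity"))
      if (got[[m]] != want[[m]]) expect_equal(got[[m]], want[[m]])  # exact rational agreement
    if (got[["recall"]] != got[["sensitivity"]])
      expect_identical(got[["recall"]], got[["sensitivity"]])
  }
  succeed()
})

test_that("metric edge cases follow the documented zero-denominator convention", {
  expect_warning(m <- class_metrics(c(TP = 0, FP = 0, TN = 5, FN = 0)), "precision")
  expect_identical(m[["precision"]], 0)
  m2 <- class_metrics(c(TP = 8, FP = 2, TN = 88, FN = 2))
  expect_equal(m2[["precision"]], 0.8)
  expect_equal(m2[["recall"]], 0.8)
  expect_equal(m2[["f1"]], 0.8)
  expect_equal(m2[["specificity"]], 88 / 90)
  # F1 never exceeds the larger of precision and recall
  set.seed(3)
  for (i in 1:200) {
    c4 <- sample(0:20, 4, replace = TRUE)
    m <- suppressWarnings(class_metrics(c(TP = c4[1], FP = c4[2], TN = c4[3], FN = c4[4])))
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
  }
})

test_that("overall accuracy is the trace ratio and permutation-invariant", {
  cm <- matrix(c(1, 0, 0, 1, 2, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(overall_accuracy(cm), 0.8)           # 4 of 5
  expect_equal(overall_accuracy(diag(c(3, 4, 5))), 1)
  perm <- c(2, 3, 1)
  expect_equal(overall_accuracy(cm[perm, perm]), overall_accuracy(cm))
  expect_error(overall_accuracy(matrix(0, 3, 3)), "empty")
})

test_that("confusion() counts argmax predictions with conservation", {
  spec <- tiny_spec()
  model <- instantiate_model(spec, seed = 1)
  x <- array(runif(10 * 16 * 16), c(10, 16, 16, 1))
  y <- sample(0:2, 10, replace = TRUE)
  cm <- confusion(model, x, y)
  expect_identical(sum(cm), 10L)
  expect_identical(as.integer(rowSums(cm)),
                   as.integer(table(factor(y, levels = 0:2))))
})

test_that("training reduces the loss on a small easy dataset, deterministically", {
  ds <- generate_dataset(phantom_config(image_height = 128L, image_width = 32L,
    class_counts = c(malignant = 20L, degenerative = 20L, normal = 20L), seed = 21))
  data <- preprocess_dataset(ds, preprocess_config(target_size = 16, channels = 1))
  spec <- tiny_spec(16L, 1L)
  cfgt <- train_config(epochs = 2, seed = 9, augment = FALSE)
  m1 <- train_fold(instantiate_model(spec, 3), data$x, data$y, cfgt)
  expect_length(m1$loss_trace, 2)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_lt(rev(m1$loss_trace)[1], m1$loss_trace[1])
  # same seed, data and config give the identical loss trace
  m2 <- train_fold(instantiate_model(spec, 3), data$x, data$y, cfgt)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$weights, m2$weights)
  expect_error(train_fold(instantiate_model(spec, 3),
                          data$x[0, , , , drop = FALSE], integer(0), cfgt),
               "empty training set")
})

test_that("cross_validate produces a complete, conserved report", {
  ds <- generate_dataset(phantom_config(image_height = 128L, image_width = 32L,
    class_counts = c(malignant = 12L, degenerative = 12L, normal = 12L), seed = 5))
  data <- preprocess_dataset(ds, preprocess_config(target_size = 16, channels = 1))
  cfgt <- train_config(epochs = 1, folds = 3, seed = 2, augment = FALSE)
  rep <- cross_validate(data$x, data$y, cfgt, spec = tiny_spec(16L, 1L))
  expect_s3_class(rep, "cv_report")
  expect_length(rep$folds, 3)
  expect_identical(dim(rep$mean_metrics), c(3L, 6L))
  expect_identical(sum(rep$pooled_confusion), 36L)
  expect_equal(rep$mean_accuracy,
               mean(vapply(rep$folds, `[[`, numeric(1), "accuracy")))
  d <- tempfile()
  write_cv_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("metrics_per_fold.csv",
                                             "pooled_confusion.csv", "summary.json")))))
  smry <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(smry$mean_accuracy, rep$mean_accuracy)
  unlink(d, recursive = TRUE)
})
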