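make_manifest <- function(n_subj_per_class, epochs_per_subj) {
  rows <- list()
  for (cl in class_levels()) {
    for (s in seq_len(n_subj_per_class)) {
      id <- sprintf("%s%02d", cl, s)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = id, label = cl,
                   epoch = seq_len(epochs_per_subj),
                   start_sample = (seq_len(epochs_per_subj) - 1L) * 640L,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("segment-level folds partition epochs with balanced classes", {
  mf <- make_manifest(4, 10)  # 120 epochs, 40 per class
  plan <- make_folds(mf, k = 5, mode = "segment", seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_len(nrow(mf)))
  expect_equal(lengths(tests), rep(24L, 5))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    props <- prop.table(table(mf$label[f$test]))
    expect_true(all(abs(props - 1 / 3) <= 0.05))
  }
  expect_identical(plan, make_folds(mf, k = 5, mode = "segment", seed = 1))
  expect_false(identical(plan$folds,
                         make_folds(mf, k = 5, mode = "segment", seed = 2)$folds))
})

test_that("subject-level folds never split a subject across train and test", {
  mf <- make_manifest(10, 10)
  plan <- make_folds(mf, k = 5, mode = "subject", seed = 3)
  for (f in plan$folds) {
    expect_length(intersect(mf$subject_id[f$train], mf$subject_id[f$test]), 0)
    # 10 subjects per class over 5 folds: exactly 2 test subjects per class
    per_class <- table(unique(mf[f$test, c("subject_id", "label")])$label)
    expect_true(all(per_class == 2))
  }
  expect_equal(sort(unlist(lapply(plan$folds, `[[`, "test"))), seq_len(nrow(mf)))
  expect_error(make_folds(make_manifest(3, 5), k = 5, mode = "subject"),
               "planning error")
})

test_that("confusion matrices count truth rows against prediction columns", {
  truth <- rep(0:2, each = 5)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm)), c(5L, 5L, 5L))
  expect_equal(sum(cm), 15L)

  all0 <- confusion_matrix(truth, rep(0L, 15))
  expect_equal(unname(all0[, 1]), c(5L, 5L, 5L))
  expect_equal(sum(all0[, 2:3]), 0L)

  set.seed(4)
  for (i in 1:10) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    expect_equal(sum(confusion_matrix(a, b)), 30L)
  }
  expect_error(confusion_matrix(c(0, 3), c(0, 1)), "class code")
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 2)), "length")
})

test_that("the hand-worked confusion matrix reproduces its metrics", {
  cm <- matrix(c(4, 1, 0,
                 1, 4, 0,
                 0, 0, 5), 3, 3, byrow = TRUE)
  r <- compute_metrics(cm)
  expect_equal(r$accuracy, 13 / 15)
  expect_equal(r$micro$precision, 13 / 15)
  expect_equal(r$micro$recall, 13 / 15)
  expect_equal(r$micro$f1, 13 / 15)
  expect_equal(r$per_class$tp, c(4, 4, 5))
  expect_equal(r$per_class$fp, c(1, 1, 0))
  expect_equal(r$per_class$precision, c(0.8, 0.8, 1))
})

test_that("perfect and degenerate classifiers hit the metric boundary cases", {
  perfect <- compute_metrics(diag(c(5, 5, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro$f1, 1)
  expect_equal(perfect$micro$f1, 1)

  # a class never predicted: precision 0 with a warning
  cm <- matrix(c(5, 0, 0,
                 5, 0, 0,
                 5, 0, 0), 3, 3, byrow = TRUE)
  expect_warning(r <- compute_metrics(cm), "precision")
  expect_equal(r$per_class$precision[2:3], c(0, 0))
  expect_equal(r$accuracy, 1 / 3)
  expect_error(compute_metrics(matrix(0, 3, 3)), "input error")
})

test_that("micro precision = recall = F1 = accuracy for any confusion matrix", {
  set.seed(7)
  for (i in 1:200) {
    r <- suppressWarnings(compute_metrics(random_confusion()))
    expect_equal(r$micro$precision, r$accuracy)
    expect_equal(r$micro$recall, r$accuracy)
    expect_equal(r$micro$f1, r$accuracy)
  }
})

test_that("cross-validation aggregates per-fold reports and pools confusions", {
  d <- separable_tensors(15, shape = c(19L, 64L, 3L), seed = 9)
  manifest <- data.frame(
    subject_id = paste0(rep(class_levels(), each = 15), rep(1:5, 3)),
    label = rep(class_levels(), each = 15))
  tn <- structure(list(data = d$x, manifest = manifest),
                  class = "imf_tensor_set")
  spec <- model_spec(list(
    conv2d_layer(8L, c(1L, 6L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 2L), stride = c(1L, 2L), padding = "valid"),
    flatten_layer(),
    dense_layer(16L),
    dense_layer(3L, activation = "softmax")), input_shape = c(19L, 64L, 3L))
  plan <- make_folds(tn, k = 5, mode = "segment", seed = 1)
  cfg <- train_config(learning_rate = 1e-3, epochs = 10, batch_size = 8,
                      seed = 1, normalize = "zscore")
  rep <- cross_validate(tn, spec, cfg, plan)
  expect_length(rep$fold_reports, 5)
  expect_equal(sum(rep$pooled$confusion), 45)
  accs <- vapply(rep$fold_reports, `[[`, numeric(1), "accuracy")
  expect_equal(rep$aggregate$accuracy, mean(accs))
  # equal-sized folds: mean fold accuracy equals pooled accuracy
  expect_equal(rep$aggregate$accuracy, rep$pooled$accuracy)
  # an easy separable problem should be learned well
  expect_gte(rep$aggregate$accuracy, 0.8)

  dir <- withr::local_tempdir()
  write_cv_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("metrics.json",
                                               "confusion_pooled.csv",
                                               "fold_accuracy.csv",
                                               "run_manifest.json")))))
  m <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
  expect_equal(m$aggregate$accuracy, rep$aggregate$accuracy)
})
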