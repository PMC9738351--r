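#' Plan a stratified k-fold split
#'
#' Two granularities. `"segment"`: epochs are dealt into folds within each
#' class, so every fold's test set matches the global class proportions (this
#' mirrors an 80/20 split of epochs at k = 5). `"subject"`: whole subjects
#' are dealt into folds within each class, so no subject contributes epochs
#' to both train and test of the same fold — the leakage-safe choice when
#' several epochs come from one recording.
#'
#' @param x An `epoch_set`, `imf_tensor_set`, or a manifest data frame with
#'   `subject_id` and `label` columns.
#' @param k Number of folds (default 5).
#' @param mode `"segment"` or `"subject"`.
#' @param seed Seed for the shuffles; fixed seed gives an identical plan.
#' @return A `fold_plan`: list with `k`, `mode`, `seed`, and `folds`, each
#'   fold holding disjoint `train`/`test` index vectors; test sets partition
#'   the epoch indices.
#' @export
make_folds <- function(x, k = 5L, mode = c("segment", "subject"), seed = 1L) {
  mode <- match.arg(mode)
  manifest <- if (is.data.frame(x)) x else x$manifest
  n <- nrow(manifest)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  lab <- manifest$label
  fold_of <- integer(n)
  set.seed(seed)
  if (mode == "segment") {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    for (cl in unique(lab)) {
      subj <- unique(manifest$subject_id[lab == cl])
      if (length(subj) < k) {
        stop("planning error: class ", cl, " has ", length(subj),
             " subject(s), fewer than k = ", k, call. = FALSE)
      }
      subj <- subj[sample.int(length(subj))]
      sf <- rep_len(seq_len(k), length(subj))
      for (j in seq_along(subj)) {
        fold_of[manifest$subject_id == subj[j] & lab == cl] <- sf[j]
      }
    }
  }
  folds <- lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
  structure(list(k = as.integer(k), mode = mode, seed = as.integer(seed),
                 folds = folds, n = n),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<fold_plan> k=%d mode=%s seed=%d; test sizes: %s\n",
              x$k, x$mode, x$seed, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Three-class confusion matrix
#'
#' Entry `(i, j)` counts epochs of true class `i` predicted as class `j`
#' (rows = truth, columns = prediction), over the fixed ES/PNES/CS coding.
#'
#' @param true,predicted Equal-length label vectors (codes 0:2 or class
#'   names).
#' @return 3 x 3 integer matrix with ES/PNES/CS dimnames.
#' @export
confusion_matrix <- function(true, predicted) {
  true <- class_code(true)
  predicted <- class_code(predicted)
  if (length(true) != length(predicted)) {
    stop("label error: length mismatch", call. = FALSE)
  }
  m <- table(factor(true, levels = 0:2), factor(predicted, levels = 0:2))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(true = class_levels(), predicted = class_levels()))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest counts (TP, FP, FN, TN) feed the standard accuracy,
#' precision, recall and F1 formulas, reported under both averaging schemes:
#' micro (counts pooled across classes before the formulas) and macro
#' (unweighted mean of per-class values). For single-label multiclass data,
#' micro precision = micro recall = micro F1 = accuracy identically. A class
#' with an undefined (0/0) precision or recall scores 0 with a warning.
#'
#' @param confusion Nonnegative integer 3 x 3 matrix (rows = truth).
#' @return A `metrics_report`: list with `confusion`, `per_class` (data frame
#'   of counts and per-class metrics), `micro`, `macro`, `accuracy`, `n`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0) {
    stop("input error: confusion matrix must be nonnegative with positive sum",
         call. = FALSE)
  }
  n <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn

  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) {
      warning("undefined ", what, " (0/0) for class(es) ",
              paste(class_levels()[den == 0], collapse = ", "),
              "; reported as 0", call. = FALSE)
    }
    out
  }
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  acc_c <- (tp + tn) / n

  micro <- local({
    p <- sum(tp) / sum(tp + fp)
    r <- sum(tp) / sum(tp + fn)
    list(accuracy = (sum(tp) + sum(tn)) / (3 * n), precision = p, recall = r,
         f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
  })
  macro <- list(accuracy = mean(acc_c), precision = mean(prec),
                recall = mean(rec), f1 = mean(f1))
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = class_levels(), tp = tp, fp = fp,
                           fn = fn, tn = tn, precision = prec, recall = rec,
                           f1 = f1, row.names = NULL),
    micro = micro, macro = macro,
    accuracy = sum(tp) / n, n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.4f\n", x$n, x$accuracy))
  cat(sprintf("  micro: P %.4f  R %.4f  F1 %.4f\n",
              x$micro$precision, x$micro$recall, x$micro$f1))
  cat(sprintf("  macro: P %.4f  R %.4f  F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$confusion)
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Trains a freshly initialized model per fold (weight seed derived from the
#' plan seed and fold number — no carry-over between folds), evaluates on the
#' fold's held-out epochs, and aggregates fold metrics by their mean. The
#' pooled confusion matrix across folds is also reported.
#'
#' @param tensors An `imf_tensor_set` (or array plus `labels`).
#' @param spec A `model_spec`.
#' @param cfg A [train_config()].
#' @param plan A [make_folds()] plan built over the same epochs.
#' @param labels Optional label vector when `tensors` is a bare array.
#' @param verbose Report per-fold progress.
#' @return A `cv_report`: list with `fold_reports` (one `metrics_report` per
#'   fold), `aggregate` (mean accuracy/precision/recall/F1, micro and macro),
#'   `pooled` (metrics of the summed confusion), and provenance (`plan`,
#'   `cfg`, spec parameter total).
#' @export
cross_validate <- function(tensors, spec, cfg, plan, labels = NULL,
                           verbose = FALSE) {
  y <- labels_for(tensors, labels)
  x <- as_tensor_array(tensors)
  if (plan$n != dim(x)[1]) {
    stop("fold plan was built over a different epoch set", call. = FALSE)
  }
  fold_reports <- vector("list", plan$k)
  pooled <- matrix(0L, 3, 3)
  for (f in seq_len(plan$k)) {
    if (verbose) message("fold ", f, "/", plan$k)
    tr <- plan$folds[[f]]$train
    te <- plan$folds[[f]]$test
    fold_seed <- (plan$seed * 131L + f) %% 2147483647L
    model <- build_model(spec, seed = fold_seed)
    fold_cfg <- cfg
    fold_cfg$seed <- fold_seed
    model <- train_model(model, x[tr, , , , drop = FALSE], y[tr], fold_cfg,
                         verbose = verbose)
    pred <- predict_classes(model, x[te, , , , drop = FALSE])
    cm <- confusion_matrix(y[te], pred$label)
    fold_reports[[f]] <- compute_metrics(cm)
    pooled <- pooled + cm
    rm(model, pred)
    gc(verbose = FALSE)  # large per-fold buffers; keep peak memory bounded
  }
  agg_of <- function(which_avg, metric) {
    mean(vapply(fold_reports, function(r) r[[which_avg]][[metric]], numeric(1)))
  }
  aggregate <- list(
    accuracy = mean(vapply(fold_reports, `[[`, numeric(1), "accuracy")),
    micro = list(precision = agg_of("micro", "precision"),
                 recall = agg_of("micro", "recall"),
                 f1 = agg_of("micro", "f1")),
    macro = list(precision = agg_of("macro", "precision"),
                 recall = agg_of("macro", "recall"),
                 f1 = agg_of("macro", "f1")))
  structure(list(fold_reports = fold_reports, aggregate = aggregate,
                 pooled = compute_metrics(pooled), plan = plan, cfg = cfg,
                 total_parameters = total_parameters(spec)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  accs <- vapply(x$fold_reports, `[[`, numeric(1), "accuracy")
  cat(sprintf("<cv_report> %d folds (%s-level)\n", x$plan$k, x$plan$mode))
  cat(sprintf("  fold accuracies: %s\n", paste(sprintf("%.3f", accs), collapse = " ")))
  cat(sprintf("  mean accuracy %.4f | micro P/R/F1 %.4f/%.4f/%.4f | macro F1 %.4f\n",
              x$aggregate$accuracy, x$aggregate$micro$precision,
              x$aggregate$micro$recall, x$aggregate$micro$f1,
              x$aggregate$macro$f1))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes metrics to JSON, the pooled confusion matrix and per-fold
#' accuracies to CSV, and a reproducibility manifest (seed, fold plan, config)
#' to JSON.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  accs <- vapply(report$fold_reports, `[[`, numeric(1), "accuracy")
  jsonlite::write_json(
    list(aggregate = report$aggregate,
         fold_accuracy = accs,
         pooled_accuracy = report$pooled$accuracy,
         total_parameters = report$total_parameters),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$pooled$confusion),
                   file.path(dir, "confusion_pooled.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fold = seq_along(accs), accuracy = accs),
                   file.path(dir, "fold_accuracy.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = report$plan$k, mode = report$plan$mode, seed = report$plan$seed,
         test_sizes = vapply(report$plan$folds, function(f) length(f$test),
                             integer(1)),
         train_config = unclass(report$cfg)),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
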