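#' Stratified 50:50 train/test split
#'
#' Splits the feature rows in half within each class; when a class has an
#' odd count the extra row goes to the training half. Deterministic given
#' the seed.
#'
#' @param features a `feature_matrix` with labels.
#' @param seed integer seed for the within-class shuffles.
#' @return List with `train` and `test` `feature_matrix` objects and the row
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_5050 <- function(features, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- features$labels
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 rows")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cls in names(counts)) {
    rows <- which(labels == cls)
    rows <- rows[sample.int(length(rows))]
    n_train <- ceiling(length(rows) / 2)
    train_idx <- c(train_idx, rows[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  subset_fm <- function(idx) {
    structure(list(values = features$values[idx, , drop = FALSE],
                   column_names = features$column_names,
                   labels = labels[idx],
                   window_size = features$window_size),
              class = "feature_matrix")
  }
  list(train = subset_fm(train_idx), test = subset_fm(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Confusion matrix and accuracy report
#'
#' Builds the confusion matrix (rows = truth, columns = prediction), the
#' one-vs-rest TP/TN/FP/FN counts per class, the per-class accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`, and the overall accuracy
#' `trace(confusion) / n_test` (also reported as a percentage).
#'
#' @param truth,predicted equal-length label vectors.
#' @param class_names ordered class labels; defaults to the sorted union
#'   (or [gait_classes()] when the labels are the four gaits).
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(truth, predicted, class_names = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty label vectors")
  if (is.null(class_names)) {
    u <- union(unique(truth), unique(predicted))
    class_names <- if (setequal(u, gait_classes())) gait_classes() else sort(u)
  }
  if (!all(truth %in% class_names) || !all(predicted %in% class_names))
    stop("unknown label")
  tf <- factor(truth, levels = class_names)
  pf <- factor(predicted, levels = class_names)
  confusion <- unclass(table(truth = tf, predicted = pf))
  n <- length(truth)
  per_class <- t(vapply(class_names, function(cls) {
    tp <- confusion[cls, cls]
    fn <- sum(confusion[cls, ]) - tp
    fp <- sum(confusion[, cls]) - tp
    tn <- n - tp - fn - fp
    c(TP = tp, TN = tn, FP = fp, FN = fn,
      accuracy = (tp + tn) / n)
  }, numeric(5)))
  acc <- sum(diag(confusion)) / n
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy_overall = acc,
                 accuracy_percent = 100 * acc,
                 accuracy_per_class = per_class[, "accuracy"],
                 n_test = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall accuracy %.4f (%.1f%%) on %d samples\n",
              x$accuracy_overall, x$accuracy_percent, x$n_test))
  print(x$confusion)
  cat("per-class one-vs-rest accuracy:\n")
  print(round(x$per_class[, "accuracy"], 4))
  invisible(x)
}
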