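# Evaluation protocol: stratified k-fold cross-validation with per-class
# recall, macro-averaged precision, averaged confusion matrices and
# prediction timing; leave-one-subject-out generalization; fold-wise
# t-tests between algorithm variants.

#' Stratified k-fold assignment
#'
#' Shuffles each class under `seed` and deals its samples round-robin
#' into `k` folds, so per-fold class proportions match the global ones
#' within one sample per class.
#'
#' @param labels Class labels; every class needs >= `k` samples.
#' @param k Number of folds (>= 2), default 10.
#' @param seed RNG seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  y <- as_factor_keep(labels)
  counts <- table(y)
  if (any(counts < k))
    stop("class(es) smaller than k: ",
         paste(names(counts)[counts < k], collapse = ", "))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Confusion matrix
#'
#' Entry (i, j) counts samples of actual class i predicted as class j.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param class_order Row/column order; defaults to [gait_classes()] when
#'   applicable, otherwise the sorted label union. Labels outside it are
#'   an error.
#' @return C x C integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, class_order = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (is.null(class_order)) {
    u <- unique(c(actual, predicted))
    class_order <- if (all(u %in% gait_classes()))
      intersect(gait_classes(), u) else sort(u)
  }
  bad <- setdiff(unique(c(actual, predicted)), class_order)
  if (length(bad) > 0L)
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  a <- factor(actual, levels = class_order)
  p <- factor(predicted, levels = class_order)
  unclass(table(actual = a, predicted = p))
}

# per-class recall / precision and accuracy from a confusion matrix;
# empty rows/columns contribute 0
cm_metrics <- function(cm) {
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, 0)
  precision <- ifelse(cs > 0, diag(cm) / cs, 0)
  list(recall = recall, precision = precision,
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Cross-validated evaluation of a reduction + classification pipeline
#'
#' Stratified k-fold protocol: within every fold the reducer and the
#' classifier are fitted on the training split only (no leakage), the
#' held-out split is predicted, and accuracy, per-class recall, per-class
#' precision, the confusion matrix and the wall time to predict a
#' resampled reference batch are recorded. Macro precision is the mean of
#' the per-class precisions, reported in percent alongside the overall
#' accuracy (the two coincide on balanced, near-diagonal results).
#'
#' @param features Feature data frame from [extract_features()], or
#'   `list(x = matrix, y = labels)`.
#' @param reducer,classifier Pipeline specification, see
#'   [gait_recognizer()].
#' @param k Folds, default 10.
#' @param seed Seed for fold shuffling and classifier fits.
#' @param batch_size Reference batch for the timing metric; defaults to
#'   2000 samples for dynamic features and 130 for static, following the
#'   evaluation protocol this harness mirrors.
#' @param class_order Label order for reports.
#' @return A `gait_cv` object: per-fold accuracies, mean per-class
#'   recall, macro precision (%), averaged confusion matrix, mean
#'   prediction time (ms) per reference batch.
#' @export
evaluate_pipeline <- function(features, reducer = list(kind = "lda"),
                              classifier = list(kind = "svmlin"),
                              k = 10L, seed = 1L, batch_size = NULL,
                              class_order = NULL) {
  if (is.data.frame(features)) {
    xy <- feature_xy(features)
    section <- if ("section" %in% names(features))
      as.character(features$section[1]) else NULL
  } else {
    xy <- list(x = as.matrix(features$x), y = as_factor_keep(features$y))
    section <- features$section %||% NULL
  }
  if (is.null(batch_size))
    batch_size <- if (identical(section, "static")) 130L else 2000L
  x <- xy$x
  if (is.null(class_order)) {
    class_order <- if (all(levels(xy$y) %in% gait_classes()))
      intersect(gait_classes(), levels(xy$y)) else levels(xy$y)
  }
  y <- factor(as.character(xy$y), levels = class_order)
  folds <- stratified_kfold(y, k = k, seed = seed)
  fold_acc <- numeric(k)
  fold_time <- numeric(k)
  recalls <- matrix(0, k, length(class_order),
                    dimnames = list(NULL, class_order))
  precisions <- recalls
  cms <- vector("list", k)
  for (fi in seq_len(k)) {
    tr <- folds != fi; te <- !tr
    fit <- gait_recognizer(x[tr, , drop = FALSE], y[tr],
                           reducer = reducer, classifier = classifier,
                           seed = seed, class_order = class_order)
    pred <- predict(fit, x[te, , drop = FALSE])
    cm <- confusion_matrix(y[te], pred, class_order)
    m <- cm_metrics(cm)
    fold_acc[fi] <- m$accuracy
    recalls[fi, ] <- m$recall
    precisions[fi, ] <- m$precision
    cms[[fi]] <- cm
    bidx <- rep_len(which(te), batch_size)
    fold_time[fi] <- unname(system.time(
      predict(fit, x[bidx, , drop = FALSE]))["elapsed"]) * 1000
  }
  structure(list(
    fold_accuracy = fold_acc,
    mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc),
    recall = colMeans(recalls),
    precision = colMeans(precisions),
    macro_precision_pct = 100 * mean(colMeans(precisions)),
    overall_accuracy_pct = 100 * mean(fold_acc),
    confusion = Reduce(`+`, cms) / k,
    mean_time_ms = mean(fold_time),
    batch_size = batch_size,
    k = k, seed = seed, classes = class_order,
    reducer = reducer, classifier = classifier, section = section),
    class = "gait_cv")
}

#' @export
print.gait_cv <- function(x, ...) {
  rk <- if (is.function(x$reducer)) "custom" else toupper(x$reducer$kind %||% "lda")
  ck <- if (is.function(x$classifier)) "custom" else x$classifier$kind %||% "svmlin"
  cat(sprintf("Stratified %d-fold cross-validation: %s + %s\n", x$k, rk, ck))
  cat(sprintf("  Recall (%s): %s\n", paste(x$classes, collapse = ", "),
              paste(sprintf("%.2f", x$recall), collapse = "/")))
  cat(sprintf("  Average precision (%%): %.2f   Accuracy (%%): %.2f +- %.2f\n",
              x$macro_precision_pct, x$overall_accuracy_pct,
              100 * x$sd_accuracy))
  cat(sprintf("  Time cost (ms, per %d-sample batch): %.2f\n",
              x$batch_size, x$mean_time_ms))
  invisible(x)
}

#' Results table row in the style of an algorithm-comparison table
#'
#' @param x A `gait_cv`.
#' @param algorithm Label for the row.
#' @return One-row data frame: Algorithm, per-class recall, average
#'   precision (%), time cost (ms).
#' @export
cv_table_row <- function(x, algorithm = "LDA+SVMlin") {
  df <- data.frame(Algorithm = algorithm,
                   Recall = paste(sprintf("%.2f", x$recall), collapse = "/"),
                   Average.precision.pct = round(x$macro_precision_pct, 2),
                   Time.cost.ms = round(x$mean_time_ms, 2),
                   stringsAsFactors = FALSE)
  df
}

#' Leave-one-subject-out evaluation
#'
#' One round per subject: the pipeline is fitted on all other subjects
#' and tested on the held-out subject, measuring generalization to
#' unseen individuals. A round whose training split lacks a class is
#' skipped with a warning and reported as `NA`.
#'
#' @param features Feature data frame with a `subject_id` column.
#' @param reducer,classifier Pipeline specification.
#' @param seed Seed for classifier fits.
#' @param class_order Label order.
#' @return A `gait_loso` object: per-subject accuracies, overall mean
#'   accuracy, per-class accuracy pooled over rounds.
#' @export
loso_evaluate <- function(features, reducer = list(kind = "lda"),
                          classifier = list(kind = "svmlin"),
                          seed = 1L, class_order = NULL) {
  if (!is.data.frame(features) || !"subject_id" %in% names(features))
    stop("features must be a data frame with a subject_id column")
  xy <- feature_xy(features)
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  if (is.null(class_order)) {
    class_order <- if (all(levels(xy$y) %in% gait_classes()))
      intersect(gait_classes(), levels(xy$y)) else levels(xy$y)
  }
  y <- factor(as.character(xy$y), levels = class_order)
  acc <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  correct_by_class <- stats::setNames(numeric(length(class_order)), class_order)
  total_by_class <- correct_by_class
  for (s in subjects) {
    te <- features$subject_id == s
    ytr <- y[!te]
    if (!all(class_order %in% unique(as.character(ytr)))) {
      warning("training split for subject ", s,
              " lacks class(es); round skipped")
      next
    }
    fit <- gait_recognizer(xy$x[!te, , drop = FALSE], ytr,
                           reducer = reducer, classifier = classifier,
                           seed = seed, class_order = class_order)
    pred <- predict(fit, xy$x[te, , drop = FALSE])
    acc[s] <- mean(pred == y[te])
    for (cl in unique(as.character(y[te]))) {
      sel <- y[te] == cl
      correct_by_class[cl] <- correct_by_class[cl] + sum(pred[sel] == cl)
      total_by_class[cl] <- total_by_class[cl] + sum(sel)
    }
  }
  per_class <- ifelse(total_by_class > 0,
                      correct_by_class / total_by_class, NA_real_)
  structure(list(per_subject = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 per_class_accuracy = per_class,
                 n_rounds = sum(!is.na(acc)),
                 classes = class_order),
            class = "gait_loso")
}

#' @export
print.gait_loso <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out: %d round(s), mean accuracy %.2f%%\n",
              x$n_rounds, 100 * x$mean_accuracy))
  cat("  per-class accuracy:",
      paste(sprintf("%s %.2f", x$classes, x$per_class_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}

#' Independent t-test between two sets of fold accuracies
#'
#' Welch's two-sample t-test by default, with the pooled-variance option.
#' Two identical zero-variance groups are reported as `t = 0, p = 1`;
#' differing zero-variance groups as `p = 0`.
#'
#' @param acc_a,acc_b Per-fold accuracy vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance (classical) formulation.
#' @return A `fold_ttest`: `statistic`, `p_value`, group `means`.
#' @export
compare_folds <- function(acc_a, acc_b, var_equal = FALSE) {
  if (length(acc_a) < 2L || length(acc_b) < 2L)
    stop("each group needs at least 2 values")
  means <- c(mean(acc_a), mean(acc_b))
  if (stats::var(acc_a) == 0 && stats::var(acc_b) == 0) {
    same <- isTRUE(all.equal(means[1], means[2]))
    return(structure(list(statistic = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0,
                          means = means,
                          method = "degenerate (zero variance)"),
                     class = "fold_ttest"))
  }
  ht <- stats::t.test(acc_a, acc_b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value, means = means,
                 method = ht$method),
            class = "fold_ttest")
}

#' @export
print.fold_ttest <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, p = %.4g (means %.4f vs %.4f)\n",
              x$method, x$statistic, x$p_value, x$means[1], x$means[2]))
  invisible(x)
}
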