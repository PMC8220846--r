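test_that("stratified folds preserve class proportions within one sample", {
  y <- rep(gait_classes(), each = 10)
  f <- stratified_kfold(y, k = 10, seed = 3)
  # 40 samples, 4 balanced classes, 10 folds: one of each class per fold
  tab <- table(y, f)
  expect_true(all(tab == 1))
  expect_identical(stratified_kfold(y, k = 10, seed = 3), f)
  expect_false(identical(stratified_kfold(y, k = 10, seed = 4), f))
  # unbalanced case: within +-1 per class
  y2 <- rep(c("a", "b"), c(23, 31))
  f2 <- stratified_kfold(y2, k = 5, seed = 1)
  expect_true(all(apply(table(y2, f2), 1, function(r) diff(range(r))) <= 1))
  expect_error(stratified_kfold(y, k = 1), "k must be")
  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 30)), k = 5),
               "smaller than k")
})

test_that("confusion matrices match a brute-force tally and canonical ordering", {
  set.seed(16)
  for (trial in 1:5) {
    cls <- letters[1:4]
    a <- sample(cls, 200, replace = TRUE)
    p <- sample(cls, 200, replace = TRUE)
    cm <- confusion_matrix(a, p, class_order = cls)
    ref <- matrix(0L, 4, 4, dimnames = list(actual = cls, predicted = cls))
    for (i in seq_along(a))
      ref[a[i], p[i]] <- ref[a[i], p[i]] + 1L
    expect_equal(unclass(cm), unclass(ref), ignore_attr = TRUE)
    expect_equal(sum(cm), 200)
  }
  cmp <- confusion_matrix(gait_classes(), gait_classes())
  expect_equal(rownames(cmp), gait_classes())  # canonical order, not sorted
  expect_equal(unname(diag(cmp)), rep(1L, 4), ignore_attr = TRUE)
  expect_error(confusion_matrix(c("a", "b"), c("a", "z"), class_order = c("a", "b")),
               "outside")
  expect_error(confusion_matrix(c("a"), c("a", "b")), "equal length")
})

test_that("fold t-tests match the closed-form pooled statistic and handle degeneracy", {
  expect_equal(compare_folds(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))$p_value, 1)
  expect_equal(compare_folds(rep(0.9, 3), rep(0.9, 3))$statistic, 0)
  expect_equal(compare_folds(rep(0.9, 3), rep(0.5, 3))$p_value, 0)
  # hand-computed pooled 3v3 example
  a <- c(0.90, 0.92, 0.94); b <- c(0.80, 0.84, 0.82)
  got <- compare_folds(a, b, var_equal = TRUE)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_ref, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_ref), 4), tolerance = 1e-12)
  # strongly separated groups are significant
  set.seed(17)
  g1 <- stats::rnorm(10, 0.9, 0.01); g2 <- stats::rnorm(10, 0.5, 0.01)
  expect_lt(compare_folds(g1, g2)$p_value, 1e-3)
  expect_error(compare_folds(0.5, c(0.4, 0.5)), "at least 2")
})

test_that("the CV harness reports memorization as perfect and random guessing as chance", {
  set.seed(18)
  X <- matrix(stats::rnorm(400), 200, 2)
  y <- rep(gait_classes(), each = 50)
  # memorizing classifier: nearest stored training point
  memorizer <- function(x, yy) {
    structure(list(x = x, y = as.character(yy)), class = "memorizer")
  }
  assign("predict.memorizer", function(object, newdata, ...) {
    d2 <- outer(rowSums(newdata^2), rowSums(object$x^2), `+`) -
      2 * newdata %*% t(object$x)
    factor(object$y[apply(d2, 1, which.min)], levels = gait_classes())
  }, envir = globalenv())
  on.exit(rm("predict.memorizer", envir = globalenv()), add = TRUE)
  # heavily duplicated train/test set: every test row also sits in training
  Xd <- X[rep(seq_len(200), 10), ]; yd <- rep(y, 10)
  cv <- evaluate_pipeline(list(x = Xd, y = yd), reducer = list(kind = "none"),
                          classifier = memorizer, k = 10, seed = 1,
                          batch_size = 10)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(sum(cv$confusion) - sum(diag(cv$confusion)), 0)
  # random-guess classifier on 4 balanced classes: ~25%
  guesser <- function(x, yy) structure(list(n = 0), class = "guesser")
  assign("predict.guesser", function(object, newdata, ...) {
    factor(sample(gait_classes(), nrow(newdata), replace = TRUE),
           levels = gait_classes())
  }, envir = globalenv())
  on.exit(rm("predict.guesser", envir = globalenv()), add = TRUE)
  set.seed(19)
  cv2 <- evaluate_pipeline(list(x = X, y = y), reducer = list(kind = "none"),
                           classifier = guesser, k = 10, seed = 1,
                           batch_size = 10)
  expect_lt(abs(cv2$mean_accuracy - 0.25), 0.12)
  # confusion rows sum to per-class actual counts (averaged per fold)
  expect_equal(unname(rowSums(cv2$confusion)), rep(5, 4), ignore_attr = TRUE)
})

test_that("the evaluated pipeline is deterministic and leakage-free under seeding", {
  ft <- tiny_features(10, "dynamic", seed = 23)
  cv_a <- evaluate_pipeline(ft, k = 5, seed = 2, batch_size = 20)
  cv_b <- evaluate_pipeline(ft, k = 5, seed = 2, batch_size = 20)
  expect_identical(cv_a$fold_accuracy, cv_b$fold_accuracy)
  expect_identical(cv_a$confusion, cv_b$confusion)
  expect_equal(cv_a$recall[["normal"]], cv_a$confusion["normal", "normal"] /
                 sum(cv_a$confusion["normal", ]), tolerance = 1e-9)
})

test_that("leave-one-subject-out reports per-subject rounds and skips impossible splits", {
  # 2 subjects with identical distributions and a separable problem
  set.seed(20)
  mk <- function(sid) {
    X <- matrix(stats::rnorm(160), 80, 2)
    y <- rep(gait_classes(), each = 20)
    X[, 1] <- X[, 1] + as.integer(factor(y, gait_classes())) * 10
    df <- as.data.frame(X)
    names(df) <- c("f1", "f2")
    df$label <- y
    df$subject_id <- sid
    df
  }
  feats <- rbind(mk("sA"), mk("sB"))
  res <- loso_evaluate(feats, reducer = list(kind = "none"),
                       classifier = list(kind = "svmlin"))
  expect_equal(res$n_rounds, 2L)
  expect_equal(unname(res$per_subject), c(1, 1))
  expect_error(loso_evaluate(mk("solo"), reducer = list(kind = "none")),
               "at least 2 subjects")
  # a subject holding all samples of one class forces a skipped round
  fA <- mk("sA"); fB <- mk("sB")
  fB <- fB[fB$label != "flat", ]
  expect_warning(res2 <- loso_evaluate(rbind(fA, fB),
                                       reducer = list(kind = "none"),
                                       classifier = list(kind = "svmlin")),
                 "lacks class")
  expect_true(is.na(res2$per_subject[["sB"]]) || is.na(res2$per_subject[["sA"]]))
})
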