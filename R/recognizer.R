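# The fitted gait-recognition model: reduction step + classifier, as one
# classed object with the usual predict/print/summary methods.

fit_reducer <- function(spec, x, y) {
  if (is.function(spec)) return(spec(x, y))
  kind <- spec$kind %||% "lda"
  switch(kind,
         lda = fit_lda(x, y, d = spec$d %||% NULL,
                       ridge = spec$ridge %||% 1e-6),
         pca = fit_pca(x, variance_target = spec$variance_target %||% 0.9),
         none = structure(list(p = ncol(x)), class = "gait_identity"),
         stop("unknown reducer kind: ", kind))
}

#' @export
predict.gait_identity <- function(object, newdata, ...)
  coerce_newdata(newdata, object$p)

fit_classifier <- function(spec, x, y, seed = 1L, class_order = NULL) {
  if (is.function(spec)) return(spec(x, y))
  kind <- spec$kind %||% "svmlin"
  switch(kind,
         svmlin = train_svm(x, y, kernel_spec("linear"),
                            C = spec$C %||% 1, tol = spec$tol %||% 1e-3,
                            seed = seed, class_order = class_order),
         svmrbf = train_svm(x, y, kernel_spec("rbf", gamma = spec$gamma %||% NULL),
                            C = spec$C %||% 1, tol = spec$tol %||% 1e-3,
                            seed = seed, class_order = class_order),
         nn = train_nn(x, y, hidden = spec$hidden %||% 10L,
                       epochs = spec$epochs %||% 500L,
                       learning_rate = spec$learning_rate %||% 0.01,
                       seed = seed, class_order = class_order),
         stop("unknown classifier kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a gait-recognition model
#'
#' The core fit of the package: a dimensionality-reduction step (linear
#' discriminant by default, 3 output dimensions for the four gait
#' classes; or PCA at a 90% variance target) followed by a maximum-margin
#' or neural-network classifier, trained on unit-norm plantar-pressure
#' feature vectors.
#'
#' @param x Feature matrix (samples x features) or a feature data frame
#'   from [extract_features()] (in which case `y` is taken from it).
#' @param y Gait class labels; ignored when `x` is a feature data frame.
#' @param reducer `list(kind = "lda"|"pca"|"none", ...)` or a function
#'   `(x, y)` returning an object with a `predict` method.
#' @param classifier `list(kind = "svmlin"|"svmrbf"|"nn", ...)` or a
#'   fitting function `(x, y)`.
#' @param seed Seed passed to stochastic classifier fits.
#' @param class_order Label order; defaults to [gait_classes()] when the
#'   labels are gait classes, otherwise to factor order.
#' @return A `gait_recognizer` object.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), 40, 2)
#' x[21:40, 1] <- x[21:40, 1] + 4
#' y <- rep(c("normal", "flat"), each = 20)
#' fit <- gait_recognizer(x, y, reducer = list(kind = "none"))
#' table(predict(fit, x), y)
gait_recognizer <- function(x, y = NULL,
                            reducer = list(kind = "lda"),
                            classifier = list(kind = "svmlin"),
                            seed = 1L, class_order = NULL) {
  if (is.data.frame(x) && any(grepl("^f[0-9]+$", names(x)))) {
    xy <- feature_xy(x)
    x <- xy$x
    if (is.null(y)) y <- xy$y
  }
  x <- as.matrix(x)
  if (is.null(class_order)) {
    class_order <- if (all(unique(as.character(y)) %in% gait_classes()))
      intersect(gait_classes(), unique(as.character(y)))
    else levels(as_factor_keep(y))
  }
  y <- factor(as.character(y), levels = class_order)
  red <- fit_reducer(reducer, x, y)
  z <- predict(red, x)
  clf <- fit_classifier(classifier, z, y, seed = seed,
                        class_order = class_order)
  structure(list(reducer = red, classifier = clf, classes = class_order,
                 reducer_spec = reducer, classifier_spec = classifier,
                 n_features = ncol(x), n_samples = nrow(x)),
            class = "gait_recognizer")
}

#' Predict gait classes with a fitted recognizer
#'
#' @param object A `gait_recognizer`.
#' @param newdata Feature matrix or feature data frame.
#' @param ... Passed on to the classifier's predict method (e.g. `type`).
#' @return Factor of predicted gait classes (or classifier-specific
#'   scores, depending on `type`).
#' @export
predict.gait_recognizer <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && any(grepl("^f[0-9]+$", names(newdata))))
    newdata <- feature_xy(newdata)$x
  z <- predict(object$reducer, as.matrix(newdata))
  predict(object$classifier, z, ...)
}

#' @export
print.gait_recognizer <- function(x, ...) {
  rk <- if (is.function(x$reducer_spec)) "custom" else x$reducer_spec$kind %||% "lda"
  ck <- if (is.function(x$classifier_spec)) "custom" else x$classifier_spec$kind %||% "svmlin"
  cat(sprintf("Gait recognizer: %s + %s, %d features, %d training samples\n",
              toupper(rk), ck, x$n_features, x$n_samples))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gait_recognizer <- function(object, ...) {
  print(object)
  cat("-- reducer --\n"); print(object$reducer)
  cat("-- classifier --\n"); print(object$classifier)
  invisible(object)
}
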