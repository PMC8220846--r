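# Small feed-forward classifier: 3 layers in total (input, one hidden
# layer of 10 logistic units, softmax output), trained by full-batch
# gradient descent on the mean cross-entropy.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

nn_forward <- function(model, x) {
  a1 <- sigmoid(x %*% model$W1 + matrix(model$b1, nrow(x), length(model$b1),
                                        byrow = TRUE))
  z2 <- a1 %*% model$W2 + matrix(model$b2, nrow(x), length(model$b2),
                                 byrow = TRUE)
  list(a1 = a1, prob = softmax_rows(z2))
}

#' Train the feed-forward gait classifier
#'
#' Backpropagation on the mean cross-entropy with full-batch gradient
#' descent; weights are initialised from `N(0, 1/sqrt(fan_in))` under
#' `seed`, so identical seeds give bit-identical final weights.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels.
#' @param hidden Hidden-layer width (default 10 units).
#' @param epochs Gradient-descent epochs (>= 1).
#' @param learning_rate Step size.
#' @param seed RNG seed for weight initialisation.
#' @param class_order Optional label ordering.
#' @return A `gait_nn` model (weight matrices, biases, classes, loss
#'   trace). Aborts with a diagnostic if the loss turns non-finite.
#' @export
train_nn <- function(x, y, hidden = 10L, epochs = 500L, learning_rate = 0.01,
                     seed = 1L, class_order = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (epochs < 1L) stop("epochs must be >= 1")
  y <- if (is.null(class_order)) as_factor_keep(y) else
    factor(as.character(y), levels = class_order)
  classes <- levels(y)
  n <- nrow(x); p <- ncol(x); C <- length(classes)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  set.seed(seed)
  model <- list(W1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
                b1 = numeric(hidden),
                W2 = matrix(stats::rnorm(hidden * C, 0, 1 / sqrt(hidden)),
                            hidden, C),
                b2 = numeric(C),
                classes = classes, hidden = hidden)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- nn_forward(model, x)
    loss <- -mean(log(pmax(fw$prob[Y == 1], 1e-300)))
    if (!is.finite(loss))
      stop("training aborted: non-finite loss at epoch ", ep)
    loss_trace[ep] <- loss
    dz2 <- (fw$prob - Y) / n
    dW2 <- crossprod(fw$a1, dz2)
    db2 <- colSums(dz2)
    da1 <- dz2 %*% t(model$W2)
    dz1 <- da1 * fw$a1 * (1 - fw$a1)
    dW1 <- crossprod(x, dz1)
    db1 <- colSums(dz1)
    model$W1 <- model$W1 - learning_rate * dW1
    model$b1 <- model$b1 - learning_rate * db1
    model$W2 <- model$W2 - learning_rate * dW2
    model$b2 <- model$b2 - learning_rate * db2
  }
  model$loss_trace <- loss_trace
  class(model) <- "gait_nn"
  model
}

#' Predict gait classes with the feed-forward classifier
#'
#' @param object A `gait_nn`.
#' @param newdata Samples x features matrix.
#' @param type `"class"` for argmax labels (ties break to the earlier
#'   class), `"prob"` for softmax scores (rows sum to 1).
#' @param ... Unused.
#' @return Factor of labels or probability matrix.
#' @export
predict.gait_nn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- coerce_newdata(newdata, nrow(object$W1))
  prob <- nn_forward(object, newdata)$prob
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[apply(prob, 1, which.max)], levels = object$classes)
}

#' @export
print.gait_nn <- function(x, ...) {
  cat(sprintf("Feed-forward classifier: %d -> %d (logistic) -> %d (softmax); final loss %.4f\n",
              nrow(x$W1), x$hidden, length(x$classes),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
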