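# Soft-margin support vector machines trained by SMO-style pairwise
# coordinate ascent on the dual, with linear and RBF kernels and
# one-vs-one voting for the multiclass problem.

#' Kernel specification
#'
#' @param kind `"linear"` or `"rbf"`.
#' @param gamma RBF width parameter; if `NULL` it is resolved at training
#'   time as `1 / (n_features * variance of all feature entries pooled)`.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), gamma = NULL) {
  kind <- match.arg(kind)
  if (!is.null(gamma) && (!is.finite(gamma) || gamma <= 0))
    stop("gamma must be finite and positive")
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

resolve_gamma <- function(kern, x) {
  if (kern$kind != "rbf") return(NULL)
  if (!is.null(kern$gamma)) return(kern$gamma)
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

# kernel Gram matrix between rows of x and rows of y
kernel_matrix <- function(kern, x, y = x, gamma = NULL) {
  if (kern$kind == "linear") return(tcrossprod(x, y))
  if (is.null(gamma)) gamma <- kern$gamma
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(d2, 0))
}

# SMO-style pairwise coordinate ascent on the soft-margin dual:
#   max  sum(a) - 1/2 sum_ij a_i a_j y_i y_j K_ij
#   s.t. 0 <= a_i <= C, sum_i a_i y_i = 0
# Deterministic: first index swept in order, second index chosen by the
# maximal |E_i - E_j| heuristic with lowest-index tie-break.
smo_solve <- function(K, y, C = 1, tol = 1e-3, max_passes = 10L,
                      max_iter = NULL) {
  n <- length(y)
  if (is.null(max_iter)) max_iter <- 500L * n
  alpha <- numeric(n)
  b <- 0
  fcache <- numeric(n)          # f_i = sum_j a_j y_j K_ij (without b)
  passes <- 0L
  iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    E <- fcache + b - y
    for (i in seq_len(n)) {
      iter <- iter + 1L
      Ei <- fcache[i] + b - y[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0))) next
      E <- fcache + b - y
      # second-choice heuristic: partners in decreasing |E_i - E_j| order,
      # falling through to the next candidate when an update is degenerate
      cand <- order(abs(Ei - E), seq_len(n), decreasing = c(TRUE, FALSE),
                    method = "radix")
      cand <- cand[cand != i]
      for (j in cand) {
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- K[i, i] + K[j, j] - 2 * K[i, j]
        if (eta <= 0) next
        aj <- aj_old + y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-12) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        dai <- ai - ai_old; daj <- aj - aj_old
        b1 <- b - Ei - y[i] * dai * K[i, i] - y[j] * daj * K[i, j]
        b2 <- b - Ej - y[i] * dai * K[i, j] - y[j] * daj * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2
          else (b1 + b2) / 2
        alpha[i] <- ai; alpha[j] <- aj
        fcache <- fcache + dai * y[i] * K[, i] + daj * y[j] * K[, j]
        changed <- changed + 1L
        break
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b, iterations = iter)
}

#' Train a multiclass SVM by SMO
#'
#' Solves the soft-margin dual of every one-vs-one binary subproblem by
#' SMO-style pairwise coordinate ascent to KKT tolerance; prediction
#' aggregates the pairwise decisions by voting. Training is fully
#' deterministic (index sweeps and tie-breaks are fixed), so `seed` is
#' accepted for interface symmetry but consumes no randomness.
#'
#' @param x Numeric matrix, samples x features; must be finite.
#' @param y Class labels (>= 2 classes).
#' @param kernel A [kernel_spec()]; the default RBF `gamma` is
#'   `1 / (n_features * variance of the pooled feature entries)`.
#' @param C Soft-margin penalty (> 0), default 1.
#' @param tol KKT tolerance.
#' @param max_passes Consecutive sweeps without an update before stopping.
#' @param seed Unused placeholder for pipeline symmetry.
#' @param class_order Optional label ordering; defaults to factor levels.
#' @return A `gait_svm` model holding, per binary subproblem, the support
#'   vectors, their signed dual coefficients `alpha_i y_i`, and the bias.
#' @export
train_svm <- function(x, y, kernel = kernel_spec("linear"), C = 1,
                      tol = 1e-3, max_passes = 10L, seed = 1L,
                      class_order = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (C <= 0) stop("C must be positive")
  y <- if (is.null(class_order)) as_factor_keep(y) else
    factor(as.character(y), levels = class_order)
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes")
  gamma <- resolve_gamma(kernel, x)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  binaries <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    xs <- x[sel, , drop = FALSE]
    ys <- ifelse(y[sel] == pr[1], 1, -1)
    K <- kernel_matrix(kernel, xs, gamma = gamma)
    fit <- smo_solve(K, ys, C = C, tol = tol, max_passes = max_passes)
    sv <- fit$alpha > 1e-12
    list(pair = pr,
         sv = xs[sv, , drop = FALSE],
         coef = fit$alpha[sv] * ys[sv],   # alpha_i * y_i
         alpha = fit$alpha[sv],
         y_sv = ys[sv],
         b = fit$b,
         iterations = fit$iterations)
  })
  structure(list(binaries = binaries, classes = classes, kernel = kernel,
                 gamma = gamma, C = C, tol = tol, n_features = ncol(x)),
            class = "gait_svm")
}

# pairwise decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b
binary_decision <- function(bin, kernel, gamma, x) {
  if (nrow(bin$sv) == 0L) return(rep(bin$b, nrow(x)))
  K <- kernel_matrix(kernel, x, bin$sv, gamma = gamma)
  drop(K %*% bin$coef) + bin$b
}

#' Predict gait classes with a trained SVM
#'
#' @param object A `gait_svm`.
#' @param newdata Samples x features matrix.
#' @param type `"class"` for labels, `"votes"` for the one-vs-one vote
#'   matrix, `"decision"` for the per-pair decision values.
#' @param ... Unused.
#' @return Factor of labels, or the requested matrix. Vote ties break to
#'   the earlier class in `object$classes`.
#' @export
predict.gait_svm <- function(object, newdata,
                             type = c("class", "votes", "decision"), ...) {
  type <- match.arg(type)
  newdata <- coerce_newdata(newdata, object$n_features)
  dec <- vapply(object$binaries, binary_decision, numeric(nrow(newdata)),
                kernel = object$kernel, gamma = object$gamma, x = newdata)
  dec <- matrix(dec, nrow = nrow(newdata))
  colnames(dec) <- vapply(object$binaries,
                          function(b) paste(b$pair, collapse = "/"),
                          character(1))
  if (type == "decision") return(dec)
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (k in seq_along(object$binaries)) {
    pr <- object$binaries[[k]]$pair
    win <- ifelse(dec[, k] >= 0, pr[1], pr[2])
    votes[cbind(seq_len(nrow(newdata)), match(win, object$classes))] <-
      votes[cbind(seq_len(nrow(newdata)), match(win, object$classes))] + 1L
  }
  if (type == "votes") return(votes)
  factor(object$classes[apply(votes, 1, which.max)], levels = object$classes)
}

#' @export
print.gait_svm <- function(x, ...) {
  nsv <- sum(vapply(x$binaries, function(b) nrow(b$sv), integer(1)))
  cat(sprintf("SVM (%s kernel%s), C = %g: %d classes, %d binary problems, %d support vectors\n",
              x$kernel$kind,
              if (x$kernel$kind == "rbf") sprintf(", gamma = %.4g", x$gamma) else "",
              x$C, length(x$classes), length(x$binaries), nsv))
  invisible(x)
}
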