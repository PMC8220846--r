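# Dimensionality reduction: PCA with variance-target component selection,
# and multiclass linear discriminant analysis fitted by maximising the
# ratio of projected between-class to within-class scatter,
# J(W) = tr(W' Sb W) / tr(W' Sw W), via the generalized eigenproblem
# Sb w = lambda Sw w.

# deterministic eigenvector sign convention: largest-magnitude entry positive
fix_signs <- function(V) {
  apply(V, 2, function(v) {
    i <- which.max(abs(v))
    if (v[i] < 0) -v else v
  })
}

#' Principal component analysis with a variance target
#'
#' Centres the data, eigendecomposes the sample (n-1) covariance, and
#' keeps the minimal number of leading components whose cumulative
#' explained-variance ratio reaches `variance_target`.
#'
#' @param x Numeric matrix, samples x features, >= 2 rows.
#' @param variance_target Fraction of variance to capture, in (0, 1].
#' @return A `gait_pca` fit: `mean`, `rotation` (components x features,
#'   orthonormal rows), `ratios` (all explained-variance ratios, sorted
#'   descending), `n_components`.
#' @export
fit_pca <- function(x, variance_target = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1)
    stop("variance_target must lie in (0, 1]")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / (nrow(x) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  if (total <= 0) stop("data has zero variance")
  ratios <- vals / total
  k <- which(cumsum(ratios) >= variance_target - 1e-12)[1]
  rot <- t(fix_signs(e$vectors[, seq_len(k), drop = FALSE]))
  structure(list(mean = mu, rotation = rot, ratios = ratios,
                 n_components = k, variance_target = variance_target),
            class = "gait_pca")
}

#' @export
print.gait_pca <- function(x, ...) {
  cat(sprintf("PCA fit: %d component(s) capturing %.1f%% of variance (target %.0f%%)\n",
              x$n_components, 100 * sum(x$ratios[seq_len(x$n_components)]),
              100 * x$variance_target))
  invisible(x)
}

#' Project data onto fitted principal components
#'
#' @param object A `gait_pca` fit.
#' @param newdata Samples x features matrix (or single vector).
#' @param ... Unused.
#' @return Samples x n_components score matrix.
#' @export
predict.gait_pca <- function(object, newdata, ...) {
  newdata <- coerce_newdata(newdata, length(object$mean))
  sweep(newdata, 2, object$mean) %*% t(object$rotation)
}

#' Reconstruct data from principal-component scores
#'
#' Inverse of [predict.gait_pca()]; exact when all components were kept.
#'
#' @param object A `gait_pca` fit.
#' @param scores Score matrix from [predict.gait_pca()].
#' @return Reconstructed samples x features matrix.
#' @export
pca_reconstruct <- function(object, scores) {
  sweep(as.matrix(scores) %*% object$rotation, 2, object$mean, `+`)
}

coerce_newdata <- function(newdata, p) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != p)
    stop("feature dimension mismatch: got ", ncol(newdata), ", expected ", p)
  newdata
}

# scatter matrices of labelled data
scatter_matrices <- function(x, y) {
  classes <- levels(y)
  p <- ncol(x)
  mu <- colMeans(x)
  Sb <- matrix(0, p, p)
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    xi <- x[y == cl, , drop = FALSE]
    mc <- colMeans(xi)
    d <- mc - mu
    Sb <- Sb + nrow(xi) * tcrossprod(d)
    xic <- sweep(xi, 2, mc)
    Sw <- Sw + crossprod(xic)
  }
  list(Sb = Sb, Sw = Sw, mean = mu)
}

# trace-ratio objective maximised by the discriminant fit; used in tests
lda_objective <- function(x, y, W) {
  s <- scatter_matrices(as.matrix(x), as_factor_keep(y))
  sum(diag(t(W) %*% s$Sb %*% W)) / sum(diag(t(W) %*% s$Sw %*% W))
}

as_factor_keep <- function(y) if (is.factor(y)) droplevels(y) else factor(y)

#' Multiclass linear discriminant reduction
#'
#' Maximises the ratio of projected between-class to within-class scatter
#' by solving the generalized eigenproblem `Sb w = lambda Sw w` and keeps
#' the top `d` eigenvectors (`d <= C - 1` for C classes; for the four gait
#' classes the default output dimension is 3). The within-class scatter is
#' ridge-regularised, `Sw + eps * tr(Sw)/p * I`, so the solve stays well
#' posed when features outnumber samples.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels; every class needs >= 2 samples.
#' @param d Output dimension; default `C - 1`.
#' @param ridge Relative ridge `eps` added to the within-class scatter.
#' @return A `gait_lda` fit: projection matrix `W` (features x d), data
#'   `mean`, per-class means, class labels.
#' @export
fit_lda <- function(x, y, d = NULL, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as_factor_keep(y)
  classes <- levels(y)
  C <- length(classes)
  if (C < 2L) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2L))
    stop("every class needs at least 2 samples; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (is.null(d)) d <- C - 1L
  if (d > C - 1L) stop("d must not exceed C - 1 = ", C - 1L)
  s <- scatter_matrices(x, y)
  p <- ncol(x)
  tr <- sum(diag(s$Sw))
  Sw_reg <- s$Sw + diag(if (tr > 0) ridge * tr / p else ridge, p)
  e <- eigen(solve(Sw_reg, s$Sb))
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(d)]
  W <- Re(e$vectors[, ord, drop = FALSE])
  W <- apply(W, 2, function(v) v / sqrt(sum(v^2)))
  W <- fix_signs(matrix(W, nrow = p))
  class_means <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(p)))
  structure(list(W = W, mean = s$mean, class_means = class_means,
                 classes = classes, d = d),
            class = "gait_lda")
}

#' @export
print.gait_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant fit: %d class(es) -> %d dimension(s)\n",
              length(x$classes), x$d))
  invisible(x)
}

#' Project data onto fitted discriminant directions
#'
#' @param object A `gait_lda` fit.
#' @param newdata Samples x features matrix (or single vector).
#' @param ... Unused.
#' @return Samples x d projection matrix.
#' @export
predict.gait_lda <- function(object, newdata, ...) {
  newdata <- coerce_newdata(newdata, length(object$mean))
  sweep(newdata, 2, object$mean) %*% object$W
}
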