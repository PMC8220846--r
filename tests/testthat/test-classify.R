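test_that("the symmetric two-point problem yields the canonical maximum margin", {
  fit <- train_svm(matrix(c(-1, 1), 2, 1), c("a", "b"), kernel_spec("linear"))
  b <- fit$binaries[[1]]
  expect_equal(b$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(b$b, 0, tolerance = 1e-6)
  dec <- predict(fit, matrix(c(-1, 0, 1), 3, 1), type = "decision")
  expect_equal(as.numeric(dec), c(1, 0, -1), tolerance = 1e-6)
  expect_equal(as.character(predict(fit, matrix(c(-2, 2), 2, 1))), c("a", "b"))
})

test_that("the RBF kernel separates XOR at gamma 1, C 1", {
  X <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  y <- c("p", "p", "q", "q")
  fit <- train_svm(X, y, kernel_spec("rbf", gamma = 1), C = 1)
  expect_equal(mean(predict(fit, X) == y), 1)
  # against the exhaustive active-set dual oracle
  K <- gaitpress:::kernel_matrix(kernel_spec("rbf", gamma = 1), X)
  ora <- svm_dual_oracle(K, c(1, 1, -1, -1), C = 1)
  expect_equal(sort(fit$binaries[[1]]$alpha), sort(ora$alpha), tolerance = 1e-3)
})

test_that("dual feasibility and KKT hold after training on random problems", {
  set.seed(10)
  for (trial in 1:4) {
    n <- 30
    X <- matrix(stats::rnorm(2 * n), n, 2)
    y <- ifelse(X[, 1] + 0.5 * X[, 2] + stats::rnorm(n, 0, 0.3) > 0, "a", "b")
    if (length(unique(y)) < 2) next
    kern <- if (trial %% 2) kernel_spec("linear") else kernel_spec("rbf", gamma = 0.7)
    fit <- train_svm(X, y, kern, C = 1)
    b <- fit$binaries[[1]]
    expect_true(all(b$alpha >= -1e-9 & b$alpha <= 1 + 1e-9))
    expect_lt(abs(sum(b$coef)), 1e-9)  # sum alpha_i y_i = 0
    # margin support vectors sit at |f| = 1 within tolerance
    dec <- predict(fit, b$sv, type = "decision")[, 1]
    margin <- b$alpha > 1e-6 & b$alpha < 1 - 1e-6
    if (any(margin))
      expect_lt(max(abs(abs(dec[margin]) - 1)), 0.02)
  }
})

test_that("small problems match the brute-force dual oracle in decision values", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(4:6, 1)
    X <- matrix(stats::rnorm(2 * n, sd = 2), n, 2)
    y <- c(rep(1, 2), rep(-1, n - 2))
    lab <- ifelse(y > 0, "a", "b")
    K <- gaitpress:::kernel_matrix(kernel_spec("linear"), X)
    ora <- svm_dual_oracle(K, y, C = 1)
    fit <- train_svm(X, lab, kernel_spec("linear"), C = 1, tol = 1e-6,
                     max_passes = 50)
    Xt <- matrix(stats::rnorm(20, sd = 2), 10, 2)
    got <- as.numeric(predict(fit, Xt, type = "decision"))
    Kt <- gaitpress:::kernel_matrix(kernel_spec("linear"), Xt, X)
    expect_equal(got, ora$decision(Kt), tolerance = 1e-4)
  }
})

test_that("prediction is a kernel sum, stable to duplicated rows, and permutation-equivariant", {
  set.seed(12)
  X <- matrix(stats::rnorm(60), 30, 2)
  y <- rep(c("normal", "toe_in", "flat"), each = 10)
  X[y == "toe_in", 1] <- X[y == "toe_in", 1] + 3
  X[y == "flat", 2] <- X[y == "flat", 2] + 3
  fit <- train_svm(X, y, kernel_spec("rbf", gamma = 0.5))
  Xt <- matrix(stats::rnorm(20), 10, 2)
  # brute-force kernel-sum oracle per binary problem
  dec <- predict(fit, Xt, type = "decision")
  for (k in seq_along(fit$binaries)) {
    b <- fit$binaries[[k]]
    manual <- vapply(seq_len(nrow(Xt)), function(i) {
      sum(b$coef * exp(-fit$gamma * colSums((t(b$sv) - Xt[i, ])^2))) + b$b
    }, numeric(1))
    expect_equal(dec[, k], manual, tolerance = 1e-10)
  }
  # duplicated test row leaves other predictions unchanged
  p1 <- predict(fit, Xt)
  p2 <- predict(fit, rbind(Xt, Xt[1, ]))
  expect_equal(as.character(p2[1:10]), as.character(p1))
  # renaming classes permutes predictions accordingly
  remap <- c(normal = "toe_out", toe_in = "normal", flat = "toe_in")
  fit2 <- train_svm(X, unname(remap[y]), kernel_spec("rbf", gamma = 0.5))
  expect_equal(as.character(unname(remap[as.character(p1)])),
               as.character(predict(fit2, Xt)))
})

test_that("gamma defaults to 1 / (features x pooled variance) and C defaults to 1", {
  set.seed(13)
  X <- matrix(stats::rnorm(80, sd = 3), 40, 2)
  y <- rep(c("a", "b"), 20)
  fit <- train_svm(X, y, kernel_spec("rbf"))
  expect_equal(fit$gamma, 1 / (2 * stats::var(as.vector(X))))
  expect_equal(fit$C, 1)
  expect_error(train_svm(X, rep("a", 40)), "2 classes")
  expect_error(train_svm(matrix(c(1, NA), 2, 1), c("a", "b")), "non-finite")
})

test_that("the feed-forward net learns separable blobs and is seed-deterministic", {
  set.seed(14)
  X <- rbind(matrix(stats::rnorm(60, -2, 0.3), 30, 2),
             matrix(stats::rnorm(60, 2, 0.3), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  nn <- train_nn(X, y, seed = 5)
  expect_equal(mean(predict(nn, X) == y), 1)
  expect_equal(nn$hidden, 10L)
  nn2 <- train_nn(X, y, seed = 5)
  expect_identical(nn$W1, nn2$W1)
  expect_identical(nn$W2, nn2$W2)
  nn3 <- train_nn(X, y, seed = 6)
  expect_false(identical(nn$W1, nn3$W1))
})

test_that("network forward pass matches the explicit matrix recurrence and softmax sums to 1", {
  set.seed(15)
  X <- matrix(stats::rnorm(30), 10, 3)
  nn <- train_nn(X, rep(c("a", "b"), 5), epochs = 5)
  prob <- predict(nn, X, type = "prob")
  expect_equal(rowSums(prob), rep(1, 10), tolerance = 1e-12)
  # hand-rolled two-layer computation
  a1 <- 1 / (1 + exp(-(X %*% nn$W1 + matrix(nn$b1, 10, 10, byrow = TRUE))))
  z2 <- a1 %*% nn$W2 + matrix(nn$b2, 10, 2, byrow = TRUE)
  ref <- exp(z2) / rowSums(exp(z2))
  expect_equal(unname(prob), unname(ref), tolerance = 1e-12)
  # all-zero weights give uniform scores and first-class ties
  nn$W1[] <- 0; nn$b1[] <- 0; nn$W2[] <- 0; nn$b2[] <- 0
  pz <- predict(nn, X, type = "prob")
  expect_equal(unname(pz), matrix(0.5, 10, 2))
  expect_true(all(predict(nn, X) == "a"))
})
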