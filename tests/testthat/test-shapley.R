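test_that("kernel weights follow the Shapley kernel", {
  expect_equal(shapley_kernel_weight(3, 1), 1 / 3)
  for (s in 1:9) {
    expect_equal(shapley_kernel_weight(10, s), shapley_kernel_weight(10, 10 - s))
  }
  total <- sum(vapply(1:9, function(s) {
    choose(10, s) * shapley_kernel_weight(10, s)
  }, numeric(1)))
  expect_true(is.finite(total) && total > 0)
  expect_error(shapley_kernel_weight(5, 0), "0 < s < M")
})

test_that("exact Shapley reproduces the 2-player closed form", {
  # v({1}) = 1, v({2}) = 2, v({1,2}) = 4, v(empty) = 0
  model <- function(X) X[, 1] + 2 * X[, 2] + X[, 1] * X[, 2]
  att <- exact_shapley(model, x = c(1, 1), background = matrix(0, 1, 2))
  expect_equal(unname(att$phi), c(1.5, 2.5), tolerance = 1e-12)
  expect_equal(att$base_value, 0)
  expect_equal(att$fx, 4)
})

test_that("exact Shapley satisfies symmetry, efficiency and null player", {
  set.seed(1)
  bg <- matrix(rnorm(20 * 4), 20, 4)
  model <- function(X) sin(X[, 1]) + sin(X[, 2]) + X[, 3]^2  # feature 4 null
  x <- c(0.7, 0.7, -1.2, 5)
  att <- exact_shapley(model, x, bg)
  expect_equal(sum(att$phi), att$fx - att$base_value, tolerance = 1e-12)
  expect_lt(abs(att$phi[4]), 1e-6)
  # features 1 and 2 enter identically and share the same value here
  bg_sym <- bg; bg_sym[, 2] <- bg_sym[, 1]
  att_sym <- exact_shapley(model, c(0.7, 0.7, -1.2, 5), bg_sym)
  expect_equal(att_sym$phi[1], att_sym$phi[2], tolerance = 1e-10)
  expect_error(exact_shapley(model, rnorm(16), bg), "M > 15")
})

test_that("additive models attribute a_i * (x_i - mean background_i)", {
  set.seed(2)
  a <- c(2, -1, 0.5, 3)
  model <- function(X) X %*% a + 1
  bg <- matrix(rnorm(200 * 4), 200, 4)
  x <- c(1, 2, 3, 4)
  att <- kernel_shap(model, x, bg, n_coalitions = 2^4)
  expect_equal(unname(att$phi), unname(a * (x - colMeans(bg))),
               tolerance = 1e-3)
  const_model <- function(X) rep(3.3, nrow(X))
  att0 <- exact_shapley(const_model, x, bg)
  expect_true(all(abs(att0$phi) < 1e-12))
  expect_equal(att0$base_value, 3.3)
})

test_that("fully enumerated Kernel SHAP equals the exact oracle", {
  set.seed(3)
  M <- 6
  bg <- matrix(rnorm(15 * M), 15, M)
  model <- function(X) tanh(X[, 1] * X[, 2]) + 0.3 * X[, 3] - X[, 4]^2 +
    0.1 * X[, 5] * X[, 6]
  x <- rnorm(M)
  exact <- exact_shapley(model, x, bg)
  ks <- kernel_shap(model, x, bg, n_coalitions = 2^M)
  expect_equal(ks$phi, exact$phi, tolerance = 1e-6)
  expect_equal(ks$base_value, exact$base_value, tolerance = 1e-10)
  expect_equal(sum(ks$phi), ks$fx - ks$base_value, tolerance = 1e-10)
})

test_that("sampled attributions approach the oracle as the budget grows", {
  set.seed(4)
  M <- 8
  bg <- matrix(rnorm(10 * M), 10, M)
  model <- function(X) X[, 1] * X[, 2] + X[, 3] - 0.5 * X[, 4]
  x <- rnorm(M)
  exact <- exact_shapley(model, x, bg)
  err_at <- function(budget) {
    e <- vapply(1:5, function(s) {
      ks <- kernel_shap(model, x, bg, n_coalitions = budget, seed = s)
      max(abs(ks$phi - exact$phi))
    }, numeric(1))
    mean(e)
  }
  expect_lt(err_at(180), err_at(30))
})

test_that("attribution summaries rank, group and stay order-invariant", {
  set.seed(5)
  n <- 30
  phi <- cbind(a = rnorm(n, sd = 2), b = rnorm(n, sd = 0.2),
               c = rnorm(n, sd = 1))
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- sample(c(-1, 1), n, replace = TRUE)
  preds <- sample(c(-1, 1), n, replace = TRUE)
  s <- shap_summary(phi, X, labels, preds)
  expect_equal(s$importance$feature[1], "a")  # largest mean |phi|
  expect_equal(nrow(s$by_class), 6)           # 2 groups x 3 features
  perm <- sample(n)
  s2 <- shap_summary(phi[perm, ], X[perm, ], labels[perm], preds[perm])
  expect_equal(s$importance, s2$importance)
  expect_equal(s$by_class, s2$by_class)
  expect_equal(s$by_correctness, s2$by_correctness)
  # single attribution: the ranking is that sample's |phi|
  s1 <- shap_summary(phi[1, , drop = FALSE], X[1, , drop = FALSE],
                     labels[1], preds[1])
  expect_equal(s1$importance$mean_abs_phi,
               sort(abs(phi[1, ]), decreasing = TRUE), ignore_attr = TRUE)
})
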