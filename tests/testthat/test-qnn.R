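test_that("reduce_and_pad yields non-negative unit-norm uncorrelated encodings", {
  set.seed(1)
  X <- matrix(rnorm(60 * 10), 60, 10)
  enc <- reduce_and_pad(X)
  expect_true(all(abs(sqrt(rowSums(enc$alpha^2)) - 1) < 1e-10))
  expect_true(all(enc$alpha >= 0))
  expect_equal(dim(enc$alpha), c(60, 4))
  # fitted projection scores are centered and uncorrelated on fit rows
  sc <- sweep(X, 2, enc$transform$center) %*% enc$transform$rotation
  expect_true(all(abs(colMeans(sc)) < 1e-8))
  cc <- crossprod(sweep(sc, 2, colMeans(sc)))
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-6))

  # rows identical in the projected space encode identically
  x_extra <- X[1, ] + rnorm(10)
  proj <- function(x) t(enc$transform$rotation) %*% (x - enc$transform$center)
  x_adj <- x_extra - as.vector(enc$transform$rotation %*%
                                 (proj(x_extra) - proj(X[1, ])))
  a <- apply_amplitude_transform(enc$transform, rbind(X[1, ], x_adj))
  expect_equal(a[1, ], a[2, ], tolerance = 1e-8)

  expect_error(reduce_and_pad(X[1:3, ]), "4 fit rows")
  low_rank <- cbind(X[, 1], 2 * X[, 1], 3 * X[, 1])
  expect_error(reduce_and_pad(low_rank), "rank")
})

test_that("encoding angles match the closed-form cases", {
  a <- encoding_angles(c(1, 0, 0, 0))
  expect_equal(unlist(a), c(beta1_2 = 0, beta1_1 = 0, beta2_1 = 0))
  b <- encoding_angles(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(b$beta1_2, pi / 2, tolerance = 1e-12)
  expect_equal(b$beta1_1, pi / 2, tolerance = 1e-12)
  expect_equal(b$beta2_1, pi / 2, tolerance = 1e-12)
  expect_error(encoding_angles(c(1, 1, 0, 0)), "unit norm")
})

test_that("state preparation reproduces amplitudes exactly", {
  expect_equal(prepare_state(c(1, 0, 0, 0)), c(1, 0, 0, 0) + 0i,
               tolerance = 1e-12)
  s <- prepare_state(c(0, 0, 1, 0))
  expect_equal(Mod(s), c(0, 0, 1, 0), tolerance = 1e-10)
  set.seed(2)
  worst <- 0
  for (i in 1:100) {
    a <- random_amplitude()
    s <- prepare_state(a)
    worst <- max(worst, max(Mod(s - a)))
  }
  expect_lt(worst, 1e-10)
})

test_that("every gate application preserves the state norm", {
  set.seed(3)
  state <- prepare_state(random_amplitude())
  for (i in 1:20) {
    U <- qradbrain:::gate_rot(runif(1, -pi, pi), runif(1, -pi, pi),
                              runif(1, -pi, pi))
    q <- sample(2, 1)
    state <- qradbrain:::apply_single(state, U, q, 2)
    expect_lt(abs(sum(Mod(state)^2) - 1), 1e-12)
    state <- qradbrain:::apply_cnot(state, 1, 2, 2)
    expect_lt(abs(sum(Mod(state)^2) - 1), 1e-12)
  }
})

test_that("the zero-parameter circuit reduces to the closed-form readout", {
  params <- circuit_params()  # all-zero angles, 6 layers
  expect_equal(circuit_expectation(c(1, 0, 0, 0), params), 1,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- random_amplitude()
    expect_equal(circuit_expectation(a + 0i, params),
                 a[1]^2 + a[2]^2 - a[3]^2 - a[4]^2, tolerance = 1e-10)
  }
})

test_that("expectations stay within [-1, 1] for random parameters", {
  set.seed(5)
  for (i in 1:20) {
    params <- circuit_params(array(runif(36, -pi, pi), c(6, 2, 3)))
    e <- circuit_expectation(prepare_state(random_amplitude()), params)
    expect_lte(abs(e), 1 + 1e-10)
  }
})

test_that("parameter-shift gradients match central finite differences", {
  set.seed(6)
  a <- random_amplitude()
  angles <- array(rnorm(36, sd = 0.5), c(6, 2, 3))
  eps <- 1e-5
  for (j in sample(36, 8)) {
    shifted <- function(delta) {
      ang <- angles; ang[j] <- ang[j] + delta
      Re(qradbrain:::batch_expectation(matrix(a, 1), circuit_params(ang)))
    }
    grad_ps <- (shifted(pi / 2) - shifted(-pi / 2)) / 2
    grad_fd <- (shifted(eps) - shifted(-eps)) / (2 * eps)
    expect_equal(grad_ps, grad_fd, tolerance = 1e-6)
  }
})

test_that("prediction applies the documented decision rule deterministically", {
  set.seed(7)
  d <- gen_separable_table(n = 40, seed = 1)
  enc <- reduce_and_pad(d$X)
  params <- circuit_params(array(rnorm(36, sd = 0.1), c(6, 2, 3)), bias = 2)
  pred <- predict_qnn(d$X, params, enc$transform)
  expect_true(all(pred$label == 1))    # bias 2 forces positive scores
  expect_true(all(pred$score >= 1))
  params0 <- circuit_params(params$angles, bias = 0)
  p1 <- predict_qnn(d$X, params0, enc$transform)
  p2 <- predict_qnn(d$X, params0, enc$transform)
  expect_identical(p1, p2)
  # a score of exactly zero maps to +1
  expect_equal(ifelse(0 < 0, -1, 1), 1)
  expect_error(predict_qnn(d$X, params0, list()), "amplitude_transform")
})

test_that("training reaches high balanced accuracy on separable data", {
  final_bacc <- vapply(1:2, function(s) {
    d <- gen_separable_table(n = 200, seed = s)
    fit <- train_qnn(d$X, d$y, epochs = 100, seed = s)
    # trailing moving-average loss is non-increasing
    ma <- stats::filter(fit$history$loss, rep(1 / 10, 10), sides = 1)
    ma <- ma[!is.na(ma)]
    expect_lt(ma[length(ma)], ma[1])
    tail(fit$history$bacc, 1)
  }, numeric(1))
  expect_true(all(final_bacc >= 0.9))
})

test_that("zero-epoch training returns the seeded initialization unchanged", {
  d <- gen_separable_table(n = 50, seed = 3)
  fit <- train_qnn(d$X, d$y, epochs = 0, seed = 42)
  ref <- qradbrain:::with_seed(42, array(rnorm(36, sd = 0.01), c(6, 2, 3)))
  expect_equal(fit$params$angles, ref, tolerance = 1e-15)
  expect_equal(fit$params$bias, 0)
  expect_equal(nrow(fit$history), 0)
})
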