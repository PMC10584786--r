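test_that("standardization is exact on fit rows and idempotent", {
  tab <- gen_feature_table(synthetic_table_spec(n_samples = 100, seed = 1))
  std <- standardize(tab)
  expect_true(all(abs(colMeans(std$table$values)) < 1e-12))
  expect_true(all(abs(apply(std$table$values, 2, sd) - 1) < 1e-12))
  again <- standardize(std$table)
  expect_equal(again$table$values, std$table$values, tolerance = 1e-12)
})

test_that("standardization parameters come from fit rows only", {
  tab <- gen_feature_table(synthetic_table_spec(n_samples = 100, seed = 2))
  fit_idx <- 1:70
  std1 <- standardize(tab, fit_idx)
  tab2 <- tab
  tab2$values[71:100, ] <- tab2$values[71:100, ] + 100  # perturb held-out rows
  std2 <- standardize(tab2, fit_idx)
  expect_equal(std1$center, std2$center)
  expect_equal(std1$scale, std2$scale)
  expect_equal(std1$table$values[fit_idx, ], std2$table$values[fit_idx, ])
})

test_that("constant columns are dropped with a warning", {
  tab <- gen_feature_table(synthetic_table_spec(n_samples = 50, seed = 3))
  tab$values[, 2] <- 7
  expect_warning(std <- standardize(tab), "zero-variance")
  expect_false(colnames(tab$values)[2] %in% colnames(std$table$values))
})

test_that("stratified split reproduces the cohort arithmetic", {
  labels <- c(rep(-1, 129), rep(1, 72))
  sp <- stratified_split(labels, fraction = 0.7, seed = 1)
  expect_equal(sum(labels[sp$train_idx] == -1), 90)  # round(0.7 * 129)
  expect_equal(sum(labels[sp$train_idx] == 1), 50)   # round(0.7 * 72)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), seq_along(labels))
  expect_identical(sp, stratified_split(labels, fraction = 0.7, seed = 1))
  expect_false(identical(sp$train_idx,
                         stratified_split(labels, seed = 2)$train_idx))
  expect_error(stratified_split(labels, fraction = 1), "strictly")
  expect_error(stratified_split(c(-1, 1, 1, 1), fraction = 0.5), "2 members")
})

test_that("resampling interpolates within the minority class", {
  set.seed(1)
  X <- rbind(matrix(rnorm(200 * 3), 200, 3),
             matrix(rnorm(30 * 3, mean = 3), 30, 3))
  y <- c(rep(-1, 200), rep(1, 30))
  res <- resample_balance(X, y, seed = 4)
  # synthetic minority points lie within the minority bounding box
  synth <- res$X[res$synthetic, , drop = FALSE]
  lo <- apply(X[y == 1, ], 2, min); hi <- apply(X[y == 1, ], 2, max)
  expect_true(all(sweep(synth, 2, lo, `>=`) & sweep(synth, 2, hi, `<=`)))

  # identical minority points produce identical synthetic points
  X2 <- rbind(matrix(rnorm(50 * 2), 50, 2),
              matrix(1.5, 10, 2))
  y2 <- c(rep(-1, 50), rep(1, 10))
  res2 <- resample_balance(X2, y2, seed = 1)
  expect_true(all(abs(res2$X[res2$synthetic, ] - 1.5) < 1e-12))
})

test_that("meet-in-the-middle sizing hits the target ratio", {
  set.seed(2)
  X <- matrix(rnorm(130 * 2), 130, 2)
  y <- c(rep(-1, 100), rep(1, 30))
  res <- resample_balance(X, y, target_ratio = 1, seed = 9)
  expect_equal(sum(res$y == 1), 60)   # minority doubled
  expect_equal(sum(res$y == -1), 60)  # majority undersampled to match
  expect_error(resample_balance(X[1:103, ], y[1:103], k_neighbors = 5),
               "exceed")
})

test_that("correlation pruning removes monotone copies and keeps the rest", {
  set.seed(5)
  x1 <- rnorm(300)
  X <- cbind(a = x1, b = 2 * x1, c = x1 + 5 * rnorm(300), d = rnorm(300))
  kept <- spearman_prune(X, threshold = 0.8)
  expect_length(intersect(kept, 1:2), 1)  # one of the exact pair dropped
  expect_true(all(c(3, 4) %in% kept))
  rho <- abs(cor(X[, kept], method = "spearman"))
  expect_true(all(rho[upper.tri(rho)] <= 0.8))
  expect_identical(kept, spearman_prune(X, threshold = 0.8))

  # MI priority keeps the informative member of a redundant pair
  y <- sign(x1 + 0.5 * rnorm(300))
  Xr <- cbind(informative = x1, copy = x1 + 0.1 * rnorm(300))
  kept_mi <- spearman_prune(Xr, threshold = 0.8, y = y)
  expect_identical(kept_mi, 1L)
})

test_that("sparse margin selection finds planted separators and ignores noise", {
  set.seed(6)
  n <- 500
  y <- rep(c(-1, 1), length.out = n)
  X <- cbind(sep = y * 2 + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 9), n, 9))
  sel <- suppressWarnings(linear_margin_select(scale(X), y))
  expect_true(1 %in% sel)

  # duplicated informative feature: at least one copy survives
  Xd <- cbind(X[, 1], X[, 1], matrix(rnorm(n * 4), n, 4))
  seld <- suppressWarnings(linear_margin_select(scale(Xd), y))
  expect_true(any(c(1, 2) %in% seld))

  # pure noise under a strong penalty: very few selections across seeds
  fp <- vapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(200 * 8), 200, 8)
    yn <- rep(c(-1, 1), each = 100)
    length(suppressWarnings(
      linear_margin_select(scale(Xn), yn, penalty_strength = 0.25)))
  }, numeric(1))
  expect_lte(mean(fp), 1)
})

test_that("MI ranking surfaces informative features above interactions", {
  tab <- gen_feature_table(synthetic_table_spec(seed = 11))
  X <- tab$values; y <- tab$labels
  informative <- which(tab$relevance$role == "informative")
  interacting <- which(tab$relevance$role == "interacting")
  r <- mi_rank(X, y, top_m = ncol(X))
  expect_setequal(r, seq_len(ncol(X)))
  pos <- match(seq_len(ncol(X)), r)
  expect_true(all(pos[informative] < min(pos[interacting])))
  top5 <- mi_rank(X, y, top_m = 5)
  expect_gte(length(intersect(top5, informative)), 4)
  expect_error(mi_rank(X, y, top_m = ncol(X) + 1), "exceeds")
})
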