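# small separable feature table fixture: two Gaussian clouds in 2-D
toy_data <- function(n_per = 10, gap = 6, seed = 1) {
  set.seed(seed)
  x1 <- matrix(stats::rnorm(2 * n_per), ncol = 2) + gap / 2
  x2 <- matrix(stats::rnorm(2 * n_per), ncol = 2) - gap / 2
  data.frame(label = rep(c("cancerous", "healthy"), each = n_per),
             f1 = c(x1[, 1], x2[, 1]), f2 = c(x1[, 2], x2[, 2]))
}

test_that("the linear SVM separates well-separated clouds exactly", {
  d <- toy_data()
  m <- train_svm(d)
  expect_equal(predict(m, d), as_signed_label(d$label))
  expect_gt(m$support_vector_count, 0)
  expect_error(train_svm(d[d$label == "healthy", ]), "single class")
})

test_that("flipping labels negates the SVM decision function", {
  d <- toy_data(seed = 2)
  m1 <- train_svm(d)
  d2 <- d
  d2$label <- ifelse(d$label == "cancerous", "healthy", "cancerous")
  m2 <- train_svm(d2)
  X <- as.matrix(d[, c("f1", "f2")])
  f1 <- drop(osteotex:::apply_scaler(X, m1$scaler) %*% m1$weights) + m1$bias
  f2 <- drop(osteotex:::apply_scaler(X, m2$scaler) %*% m2$weights) + m2$bias
  expect_equal(f1, -f2, tolerance = 1e-6)
})

test_that("a point exactly on the hyperplane is classified cancerous", {
  d <- toy_data(seed = 3)
  m <- train_svm(d)
  # construct a raw-space point whose scaled decision value is exactly 0
  w_raw <- m$weights / m$scaler$scale
  b_raw <- m$bias - sum(m$weights * m$scaler$center / m$scaler$scale)
  x0 <- c(0, (-b_raw - 0) / w_raw[2])   # f1 = 0, solve f2
  expect_equal(sum(w_raw * x0) + b_raw, 0, tolerance = 1e-12)
  expect_equal(unname(predict(m, matrix(x0, 1))), 1L)
})

test_that("training is deterministic and duplication-stable", {
  d <- toy_data(seed = 4)
  m1 <- train_svm(d); m2 <- train_svm(d)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_svm(rbind(d, d))
  expect_equal(predict(m3, d), predict(m1, d))
})

test_that("prediction rejects feature-dimension mismatches", {
  m <- train_svm(toy_data())
  expect_error(predict(m, matrix(1, 2, 5)), "expects 2, got 5")
})

test_that("prediction is invariant to affine rescaling of raw features", {
  d <- toy_data(seed = 5)
  m1 <- train_svm(d)
  d2 <- d
  d2$f1 <- 100 * d$f1 - 7
  d2$f2 <- 0.01 * d$f2 + 3
  m2 <- train_svm(d2)
  expect_equal(predict(m1, d), predict(m2, d2))
})

test_that("the random forest votes by majority with ties to cancerous", {
  d <- toy_data(seed = 6)
  m <- train_random_forest(d, seed = 9)
  expect_equal(predict(m, d), as_signed_label(d$label))
  m2 <- train_random_forest(d, seed = 9)
  expect_equal(predict(m2, d), predict(m, d))   # seeded determinism
  expect_equal(m$model$ntree, 100)
  expect_equal(m$model$mtry, 1)                 # floor(sqrt(2))
})

test_that("stratified k-fold predicts every example exactly once", {
  d <- toy_data(n_per = 12, gap = 8, seed = 7)
  res <- kfold_cv(d, k = 5, "linear_svm", seed = 3)
  expect_length(res$predictions, nrow(d))
  expect_true(all(res$predictions %in% c(-1L, 1L)))
  # stratification: per-class fold sizes differ by at most 1
  for (cls in c("cancerous", "healthy")) {
    sizes <- table(res$folds[d$label == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # separable fixture: pooled accuracy 100
  expect_equal(res$metrics$accuracy, 100)
  # leave-one-out at k = class size also partitions exactly
  d2 <- toy_data(n_per = 6, gap = 8, seed = 8)
  res2 <- kfold_cv(d2, k = 6, "linear_svm", seed = 1)
  expect_equal(sum(res2$confusion$tp + res2$confusion$fn +
                   res2$confusion$fp + res2$confusion$tn), nrow(d2))
  expect_error(kfold_cv(d2, k = 7, "linear_svm"), "at least k")
})

test_that("no test-fold example influences its fold's scaler or model", {
  d <- toy_data(n_per = 10, seed = 9)
  res <- kfold_cv(d, k = 5, "linear_svm", seed = 11)
  f <- 1
  train <- d[res$folds != f, ]
  m_ref <- train_svm(train)
  # perturb a held-out example wildly; retrained fold model is identical
  d_mut <- d
  idx <- which(res$folds == f)[1]
  d_mut[idx, c("f1", "f2")] <- c(1e3, -1e3)
  m_mut <- train_svm(d_mut[res$folds != f, ])
  expect_identical(m_ref$weights, m_mut$weights)
  expect_identical(m_ref$scaler, m_mut$scaler)
})
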