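embed_line <- function(n, d = 15) {
  # points on a 1-D line embedded in d dims
  t <- seq_len(n)
  outer(t, rnorm(d)) + matrix(rnorm(n * d, sd = 0), n, d)
}

test_that("PCA contribution ratios detect degenerate and isotropic structure", {
  set.seed(1)
  X <- embed_line(10)
  p <- pca_project(X)
  expect_equal(p$contribution_ratios, c(1, 0, 0), tolerance = 1e-9)
  # isotropic 3-D cloud embedded in 15-D: three ratios near 1/3
  set.seed(2)
  basis <- qr.Q(qr(matrix(rnorm(45), 15, 3)))
  X3 <- matrix(rnorm(600 * 3), 600, 3) %*% t(basis)
  p3 <- pca_project(X3)
  expect_true(all(abs(p3$contribution_ratios - 1 / 3) < 1 / 3 * 0.2))
  expect_true(all(diff(p3$contribution_ratios) <= 1e-12))
})

test_that("PCA scores have diagonal covariance equal to the top eigenvalues", {
  set.seed(3)
  X <- matrix(rnorm(20 * 15), 20, 15) %*% diag(seq(1, 3, length.out = 15))
  p <- pca_project(X)
  ev <- eigen(cov(X), symmetric = TRUE)$values   # independent oracle
  cv <- cov(p$scores)
  expect_equal(diag(cv), ev[1:3], tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_equal(p$contribution_ratios, ev[1:3] / sum(ev), tolerance = 1e-8)
})

test_that("linear SVM places the max-margin boundary at the midpoint in 1-D", {
  fit <- train_linear_svm(matrix(c(0, 1), ncol = 1), c("A", "B"))
  boundary <- -fit$bias / fit$weights
  expect_equal(unname(boundary), 0.5, tolerance = 1e-6)
  expect_identical(predict_svm(fit, matrix(c(-0.2, 0.3, 0.7, 2), ncol = 1)),
                   c("A", "A", "B", "B"))
})

test_that("duplicated features share weight and label swap flips the rule", {
  set.seed(4)
  x <- rnorm(20)
  X <- cbind(f1 = x, f2 = x)
  y <- ifelse(x > 0, "pos", "neg")
  fit <- train_linear_svm(X, y)
  expect_equal(unname(fit$weights["f1"]), unname(fit$weights["f2"]),
               tolerance = 1e-6)
  # swapping labels negates the decision rule
  fit2 <- train_linear_svm(X, ifelse(x > 0, "neg", "pos"))
  expect_equal(unname(fit2$weights), -unname(fit$weights), tolerance = 1e-6)
  expect_equal(fit2$bias, -fit$bias, tolerance = 1e-6)
  expect_error(train_linear_svm(X, rep("pos", 20)), "two classes")
})

test_that("SVM decisions are invariant to feature reordering", {
  set.seed(5)
  X <- matrix(rnorm(12 * 15), 12, 15, dimnames = list(NULL, region_pairs()$pair))
  y <- rep(c("susceptible", "resilient"), 6)
  perm <- sample(15)
  fit <- train_linear_svm(X, y)
  fitp <- train_linear_svm(X[, perm], y)
  expect_equal(unname(fitp$weights), unname(fit$weights[perm]), tolerance = 1e-6)
  expect_identical(predict_svm(fit, X), predict_svm(fitp, X[, perm]))
})

test_that("LOOCV failure is 0 on separated clusters and quantized to 100/n", {
  set.seed(6)
  n <- 11
  X <- rbind(matrix(rnorm(5 * 15, mean = 0, sd = 0.1), 5, 15),
             matrix(rnorm(6 * 15, mean = 3, sd = 0.1), 6, 15))
  y <- c(rep("susceptible", 5), rep("resilient", 6))
  cv <- loocv_failure(X, y)
  expect_equal(cv$failure_percent, 0)
  # any failure percentage is a multiple of 100/n
  set.seed(7)
  Xr <- matrix(rnorm(n * 15), n, 15)
  cvr <- loocv_failure(Xr, sample(y))
  k <- cvr$failure_percent * n / 100
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("LOOCV on label-randomized structureless clouds averages near chance", {
  set.seed(8)
  X <- matrix(rnorm(11 * 15), 11, 15)
  fails <- vapply(1:100, function(i) {
    y <- sample(c(rep("susceptible", 5), rep("resilient", 6)))
    loocv_failure(X, y)$failure_percent
  }, numeric(1))
  expect_lt(abs(mean(fails) - 50), 10)
})

test_that("single-class training folds fall back to the majority class", {
  # 3 rats, one lone susceptible: its fold is single-class
  X <- matrix(c(0, 0, 10, 1, 1, 11), 3, 2)
  y <- c("resilient", "resilient", "susceptible")
  cv <- loocv_failure(X, y)
  expect_identical(cv$predicted[3], "resilient")
  expect_equal(cv$failure_percent, 100 / 3, tolerance = 1e-9)
})
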