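# PCA (NIPALS + cross-validated Q2) and the linear-SVM machinery.

test_that("a rank-1 matrix is fully explained by one component", {
  set.seed(1)
  x <- outer(rnorm(20), rnorm(8))
  x <- scale(x)  # centering/scaling keeps rank low enough
  m <- fit_pca(x, 1)
  expect_equal(m$r2x[1], 1, tolerance = 1e-8)
})

test_that("NIPALS agrees with a direct SVD and recomputed residual R2X", {
  set.seed(3)
  x <- scale(matrix(rnorm(50 * 40), 50, 40))
  m <- fit_pca(x, 3)
  sv <- svd(x)
  # component 1 equals the dominant singular triple up to sign
  expect_lt(max(abs(abs(m$loadings[, 1]) - abs(sv$v[, 1]))), 1e-6)
  expect_lt(max(abs(abs(m$scores[, 1]) - abs(sv$u[, 1] * sv$d[1]))), 1e-6)
  # r2x is 1 - ||residual||_F^2 / ||X||_F^2, independently recomputed
  for (k in 1:3) {
    res <- x - tcrossprod(m$scores[, 1:k, drop = FALSE],
                          m$loadings[, 1:k, drop = FALSE])
    expect_equal(m$r2x[k], 1 - sum(res^2) / sum(x^2), tolerance = 1e-10)
  }
  # loadings orthonormal, scores orthogonal, r2x nondecreasing
  expect_lt(max(abs(crossprod(m$loadings) - diag(3))), 1e-8)
  cross <- crossprod(m$scores)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-6)
  expect_true(all(diff(m$r2x) >= 0) && all(m$r2x <= 1))
})

test_that("predicted variance collapses on structureless data", {
  set.seed(8)
  x <- scale(matrix(rnorm(50 * 40), 50, 40))
  m <- fit_pca(x, 1)
  expect_lte(m$q2[1], 0.05)
})

test_that("the linear SVM separates, is sign-symmetric and weight-splitting", {
  # 1-D separable points
  x1 <- cbind(f = c(-1, -1.2, 1, 1.2))
  y1 <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  fit <- fit_linear_svm(x1, y1)
  expect_gt(fit$weights[["f"]], 0)
  dv <- svm_decision_values(fit, x1)
  expect_true(all(sign(dv) == c(-1, -1, 1, 1)))

  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(rep(c("a", "b"), each = 20))
  x[y == "b", 1:2] <- x[y == "b", 1:2] + 2
  fit <- fit_linear_svm(x, y)

  # label flip: w -> -w, b -> -b
  yf <- factor(ifelse(y == "a", "b", "a"), levels = c("a", "b"))
  fitf <- fit_linear_svm(x, yf)
  expect_equal(fitf$weights, -fit$weights, tolerance = 1e-6)
  expect_equal(fitf$bias, -fit$bias, tolerance = 1e-6)

  # duplicating a feature splits its weight evenly between the copies, and
  # the fit is exactly equivalent to scaling that feature by sqrt(2)
  # (duplication halves the effective norm penalty on the shared weight)
  xd <- cbind(x, f1dup = x[, "f1"])
  fitd <- fit_linear_svm(xd, y)
  expect_equal(fitd$weights[["f1dup"]], fitd$weights[["f1"]],
               tolerance = 1e-4)
  xs2 <- x
  xs2[, "f1"] <- xs2[, "f1"] * sqrt(2)
  fits2 <- fit_linear_svm(xs2, y)
  expect_equal(svm_decision_values(fitd, xd), svm_decision_values(fits2, xs2),
               tolerance = 1e-4)
  expect_equal(fitd$weights[["f1"]] + fitd$weights[["f1dup"]],
               sqrt(2) * fits2$weights[["f1"]], tolerance = 1e-4)

  # one class only is an error
  expect_error(fit_linear_svm(x, rep("a", 40)), "2 classes")
})

test_that("RFE removes floor(5%) per iteration and visits every subset size", {
  set.seed(6)
  y <- factor(rep(c("a", "b"), each = 15))
  x20 <- matrix(rnorm(30 * 20), 30, 20)
  x20[y == "b", 1:3] <- x20[y == "b", 1:3] + 2
  path <- rfe_path(x20, y, drop_fraction = 0.05, seed = 1)
  sizes <- lengths(path$subsets)
  # 5% of <=20 floors to 0 -> one feature removed per iteration
  expect_equal(sizes, 20:1)
  expect_true(all(diff(sizes) < 0))

  x100 <- matrix(rnorm(30 * 100), 30, 100)
  path100 <- rfe_path(x100, y, drop_fraction = 0.05, seed = 1)
  sizes100 <- lengths(path100$subsets)
  expect_equal(sizes100[1:2], c(100, 95))  # floor(0.05 * 100) = 5 removed
  expect_equal(sizes100[length(sizes100)], 1L)
})

test_that("strong planted features survive to the end of the RFE path", {
  # 2 planted features (effect = 3 noise SDs) among 30 noise features
  last4_hits <- 0L
  n_runs <- 50
  for (seed in seq_len(n_runs)) {
    set.seed(seed + 1000)
    y <- factor(rep(c("a", "b"), each = 30))
    x <- matrix(rnorm(60 * 32), 60, 32,
                dimnames = list(NULL, c(paste0("sig", 1:2), paste0("n", 1:30))))
    x[y == "b", 1:2] <- x[y == "b", 1:2] + 3
    path <- rfe_path(x, y, seed = seed)
    last4 <- path$subsets[[length(path$subsets) - 3L]]
    if (all(c("sig1", "sig2") %in% last4)) last4_hits <- last4_hits + 1L
  }
  expect_gte(last4_hits / n_runs, 0.9)
})

test_that("complete separation gives total selection at perfect accuracy", {
  set.seed(2)
  y <- factor(rep(c("a", "b"), each = 12))
  x <- matrix(rnorm(24 * 10), 24, 10)
  x[y == "b", ] <- x[y == "b", ] + 8   # every feature separates
  sel <- stability_select(x, y, n_repeats = 12, seed = 3)
  expect_true(all(sel$frequency == 1))
  expect_length(sel$selected, 10L)
  expect_identical(sel$accuracy_mean, 100)
  expect_identical(sel$accuracy_sd, 0)
})

test_that("selection frequencies are reproducible and order-invariant", {
  set.seed(10)
  y <- factor(rep(c("a", "b"), each = 15))
  x <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[y == "b", c(2, 5)] <- x[y == "b", c(2, 5)] + 2.5
  a <- stability_select(x, y, n_repeats = 10, seed = 7)
  b <- stability_select(x, y, n_repeats = 10, seed = 7)
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$accuracy_mean, b$accuracy_mean)
  # frequencies are multiples of 1/n_repeats
  expect_true(all(abs(a$frequency * 10 - round(a$frequency * 10)) < 1e-12))
  # permuting columns permutes frequencies but not the selected set
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  p <- stability_select(x[, perm], y, n_repeats = 10, seed = 7)
  expect_equal(p$frequency[colnames(x)], a$frequency)
  expect_setequal(p$selected, a$selected)
})

test_that("pure-noise data selects at most a small residue of lucky features", {
  # on a fixed null dataset a couple of chance-correlated features can stay
  # frequent under any resampling; the selected set must stay far below the
  # complete-separation case in every meta-repeat
  set.seed(9)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rep(c("a", "b"), each = 20)
  frac <- vapply(1:5, function(s) {
    sel <- stability_select(x, y, n_repeats = 15, seed = s)
    length(sel$selected) / ncol(x)
  }, numeric(1))
  expect_true(all(frac <= 0.15))
})
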