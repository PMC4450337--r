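test_that("correlation: perfect, inverted, and the enumerated Kendall example", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  for (k in c("pearson", "spearman", "kendall")) {
    expect_equal(correlation(x, x, k), 1)
    expect_equal(correlation(x, -x, k), -1)
  }
  expect_equal(correlation(c(1, 2, 3), c(1, 3, 2), "kendall"), 1 / 3)
  expect_error(correlation(rep(1, 5), x, "pearson"), "variance")
  expect_error(correlation(1:2, 1:2, "pearson"), "at least 3")
})

test_that("Kendall tau-a matches the all-pairs enumeration oracle (n <= 50)", {
  brute <- function(x, y) {
    s <- 0; n <- length(x)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign((x[j] - x[i]) * (y[j] - y[i]))
    s / (n * (n - 1) / 2)
  }
  set.seed(4)
  for (n in c(5, 17, 50)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(correlation(x, y, "kendall"), brute(x, y))
    # with ties (tau-a: tied pairs count zero, no denominator correction)
    xt <- sample(1:4, n, TRUE); yt <- sample(1:4, n, TRUE)
    expect_equal(correlation(xt, yt, "kendall"), brute(xt, yt))
  }
})

test_that("rank correlations are invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40); y <- x + rnorm(40, sd = 0.5)
  for (k in c("spearman", "kendall")) {
    r0 <- correlation(x, y, k)
    expect_equal(correlation(exp(x), y, k), r0)
    expect_equal(correlation(x, y^3, k), r0)
  }
})

test_that("pca_fit: rank-1 data, orthonormality, covariance-direction oracle", {
  set.seed(6)
  t1 <- rnorm(20)
  X <- outer(t1, c(1, 2, 3)) + 5
  b <- pca_fit(X, 2)
  expect_gt(b$var_explained[1], 1 - 1e-12)
  expect_equal(crossprod(b$components), diag(2), tolerance = 1e-8)
  expect_true(all(diff(b$var_all) <= 1e-12))
  # anisotropic cloud: first direction along x within 5 degrees
  Y <- cbind(rnorm(1000, sd = 2), rnorm(1000, sd = 1))
  b <- pca_fit(Y, 2)
  ev <- eigen(cov(Y))$vectors[, 1]
  ang <- acos(abs(sum(b$components[, 1] * ev))) * 180 / pi
  expect_lt(ang, 1e-6)    # must agree with the eigen oracle
  expect_lt(acos(abs(b$components[1, 1])) * 180 / pi, 5)
  expect_error(pca_fit(Y, 5), "k exceeds")
})

test_that("reconstruction error is non-increasing in k", {
  set.seed(8)
  X <- matrix(rnorm(30 * 12), 30, 12) %*% diag(c(6:1, rep(0.3, 6)))
  errs <- vapply(1:6, function(k) {
    b <- pca_fit(X, k)
    sc <- pca_project(b, X)
    rec <- sweep(sc %*% t(b$components), 2, b$mean, "+")
    sum((X - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("2D PCA similarity: self-similarity and affine-intensity invariance", {
  f <- cached_phantom("brainlike", 64, 10)
  expect_equal(pca_similarity_2d(f, f, "pearson"), 1)
  expect_equal(pca_similarity_2d(f, f, "pca-ssd"), 0)
  expect_equal(pca_similarity_2d(f, f + 0.1, "pca-pearson"), 1, tolerance = 1e-9)
  expect_equal(pca_similarity_2d(f, 0.7 * f + 0.2, "pca-pearson"), 1,
               tolerance = 1e-9)
})

test_that("3D triplanar PCA similarity: self cases and slice-order invariance", {
  v <- make_3d_phantom(c(32, 32, 32), 3)
  expect_equal(pca_similarity_3d(v, v, "pearson"), 1, tolerance = 1e-9)
  expect_equal(pca_similarity_3d(v, v, "ssd"), 0, tolerance = 1e-9)
  m <- 0.8 * v + 0.05
  s0 <- pca_similarity_3d(v, m, "pearson", k = 4)
  perm <- sample(32)
  s1 <- pca_similarity_3d(v[perm, , ], m[perm, , ], "pearson", k = 4)
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("similarity_metric dispatches plain and pca variants consistently", {
  f <- cached_phantom("blobs", 32, 11)
  m <- cached_phantom("blobs", 32, 12)
  expect_equal(similarity_metric(f, m, "ssd"), ssd(f, m))
  expect_equal(similarity_metric(f, m, "pearson"),
               cor(as.vector(f), as.vector(m)))
  expect_equal(similarity_metric(f, m, "pca-ssd"),
               pca_similarity_2d(f, m, "ssd"))
  expect_error(similarity_metric(f, m, "mutual-info"), "unknown metric")
})
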