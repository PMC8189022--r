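test_that("pairwise distances are Euclidean with a zero diagonal", {
  expect_equal(pairwise_distance_matrix(c(0, 1)),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(pairwise_distance_matrix(matrix(1, 3, 2)),
               matrix(0, 3, 3))
  B <- pairwise_distance_matrix(rbind(c(0, 0), c(3, 4)))
  expect_equal(B[1, 2], 5)
  bad <- matrix(c(1, NA, 2, 3), 2)
  expect_error(pairwise_distance_matrix(bad), "row 2, column 1")
})

test_that("double centring zeroes every row and column sum", {
  expect_equal(double_center(matrix(c(0, 1, 1, 0), 2)),
               matrix(c(-0.5, 0.5, 0.5, -0.5), 2))
  expect_equal(double_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(31)
  for (n in c(4, 17, 60)) {
    A <- double_center(pairwise_distance_matrix(matrix(rnorm(n * 3), n)))
    expect_lt(max(abs(rowSums(A))), 1e-10)
    expect_lt(max(abs(colSums(A))), 1e-10)
  }
})

test_that("distance covariance matches the printed sum and a naive oracle", {
  expect_equal(dcov2(c(0, 1), c(0, 1)), 1)
  expect_equal(dcov2(rep(2, 5), rnorm(5)), 0)
  expect_error(dcov2(1:3, 1:4), "mismatch")
  # dual route: raw sum equals n^2 times the conventionally scaled estimator
  set.seed(77)
  for (r in 1:10) {
    n <- sample(5:40, 1)
    p <- sample(1:4, 1)
    Y <- matrix(rnorm(n * 2), n); X <- matrix(rnorm(n * p), n)
    expect_equal(dcov2(Y, X), n^2 * naive_dcov2_conventional(Y, X),
                 tolerance = 1e-10)
    expect_gte(dcov2(Y, X), -1e-8)
  }
})

test_that("distance correlation agrees with a naive oracle on random data", {
  set.seed(123)
  for (r in 1:25) {
    n <- sample(5:50, 1)
    p <- sample(1:4, 1)
    Y <- matrix(rnorm(n), n)
    X <- matrix(rnorm(n * p), n) + if (r %% 2) Y[, 1] else 0
    expect_equal(dcor(Y, X), naive_dcor(Y, X), tolerance = 1e-10)
  }
})

test_that("distance correlation hits its boundary cases and range", {
  expect_equal(dcor(1:3, 1:3), 1)
  expect_equal(dcor(rnorm(5), rep(1, 5)), 0)
  sup <- xor_support(25)
  expect_equal(dcor(sup$y, sup$X), xor_population_dcor(), tolerance = 1e-10)
  expect_lt(abs(dcor(sup$y, sup$X[, 1])), 1e-10)
  expect_lt(abs(dcov2(sup$y, sup$X[, 1])), 1e-10 * nrow(sup$X)^2)
  set.seed(9)
  for (r in 1:10) {
    v <- dcor(rnorm(20), rnorm(20))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("distance correlation is invariant to the transformations it should be", {
  set.seed(42)
  n <- 80
  Y <- matrix(rnorm(n), n)
  X <- matrix(rnorm(n * 2), n) + Y[, 1]
  base <- dcor(Y, X)
  # joint row permutation
  idx <- sample(n)
  expect_equal(dcor(Y[idx, , drop = FALSE], X[idx, , drop = FALSE]), base,
               tolerance = 1e-10)
  # translation, orthogonal rotation, separate positive rescaling
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(dcor(Y + 3, X %*% Q + 1), base, tolerance = 1e-8)
  expect_equal(dcor(2.5 * Y, 0.3 * X), base, tolerance = 1e-8)
})

test_that("large-sample path agrees with the n x n matrix formula", {
  # n above the in-memory threshold of the R reference route used here
  set.seed(6)
  n <- 600
  y <- rnorm(n); x <- y^2 + rnorm(n)
  Ay <- double_center(pairwise_distance_matrix(y))
  Ax <- double_center(pairwise_distance_matrix(x))
  ref <- sum(Ay * Ax) / sqrt(sum(Ay^2) * sum(Ax^2))
  expect_equal(dcor(y, x, squared = TRUE), ref, tolerance = 1e-10)
})

test_that("affine-invariant distance correlation is affine invariant", {
  set.seed(55)
  n <- 200
  Y <- matrix(rnorm(n), n)
  X <- matrix(rnorm(n * 3), n); X[, 1] <- X[, 1] + Y[, 1]^2
  base <- aidc(Y, X)
  for (r in 1:20) {
    repeat {
      M <- matrix(rnorm(9), 3)
      if (abs(det(M)) > 0.1) break
    }
    b <- rnorm(3)
    expect_equal(aidc(Y, sweep(X %*% M, 2, -b)), base, tolerance = 1e-8)
  }
  # identity-covariance inputs reduce to the plain distance correlation
  W <- matrix(rnorm(n * 2), n)
  Wy <- matrix(rnorm(n), n)
  Ww <- sunnies:::whiten(W); Wyw <- sunnies:::whiten(Wy)
  expect_equal(aidc(Wyw, Ww), dcor(Wyw, Ww), tolerance = 1e-8)
  expect_error(aidc(Y, cbind(X, X[, 1])), "singular")
  expect_error(aidc(Y, cbind(X, 1)), "singular")
})

test_that("median bandwidth follows the heuristic and its fallbacks", {
  expect_equal(median_bandwidth(c(0, 1)), 1)
  expect_equal(median_bandwidth(rep(4, 6)), 1)
  quartet <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  expect_equal(median_bandwidth(quartet), 1)  # distances {1 x4, sqrt(2) x2}
  # heavily tied but not constant: mean of the positive distances
  w <- c(0, 0, 0, 0, 2)
  expect_equal(median_bandwidth(w), 2)
})

test_that("HSIC matches the centred-trace identity and degenerates to zero", {
  set.seed(14)
  n <- 40
  Y <- matrix(rnorm(n), n); X <- matrix(rnorm(n * 2), n) + Y[, 1]
  k <- kernel_spec("fixed", bandwidth = 1.3)
  K <- gaussian_gram(X, 1.3); L <- gaussian_gram(Y, 1.3)
  expect_equal(hsic(Y, X, kernel = k), naive_hsic_trace(K, L),
               tolerance = 1e-10)
  expect_equal(hsic(rep(1, 10), matrix(rnorm(20), 10)), 0, tolerance = 1e-12)
  expect_gt(hsic(Y, Y), 0)
  expect_gte(hsic(matrix(rnorm(30), 30), matrix(rnorm(30), 30)), -1e-12)
  expect_error(kernel_spec("fixed"), "bandwidth")
})

test_that("multiple correlation equals OLS R-squared and flags degeneracy", {
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 3), n)
  y <- X %*% c(1, -2, 0.5) + rnorm(n)
  expect_equal(r2_multiple(y, X), summary(lm(y ~ X))$r.squared,
               tolerance = 1e-10)
  expect_equal(r2_multiple(y, X[, 1]), as.numeric(cor(y, X[, 1]))^2,
               tolerance = 1e-10)
  exact <- X %*% c(2, 1, 1)
  expect_equal(r2_multiple(exact, X), 1, tolerance = 1e-10)
  expect_error(r2_multiple(rep(1, n), X), "zero variance")
  expect_error(r2_multiple(y, cbind(X, X[, 1])), "singular")
})

test_that("dependence games evaluate lazily with the empty-set convention", {
  sup <- xor_support(10)
  C <- make_characteristic("dcor", sup$y, sup$X)
  expect_identical(cf_eval(C, integer(0)), 0)
  expect_lt(abs(cf_eval(C, 1L)), 1e-8)
  expect_equal(cf_eval(C, 1:2), dcor(sup$y, sup$X), tolerance = 1e-12)
  expect_equal(cf_eval(C, 1:2), xor_population_dcor(), tolerance = 1e-10)

  # appended constant column: exact null player for distance-based games
  Xc <- cbind(sup$X, 5)
  for (meas in c("dcor", "hsic")) {
    dec <- shapley_exact(make_characteristic(meas, sup$y, Xc))
    expect_identical(dec$values[3], 0)
  }
})

test_that("the quadratic process is visible to dcor but not to R-squared", {
  dc <- r2 <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_quadratic(1000, seed = 100 + s)
    dc[s] <- dcor(sim$y, sim$X)
    r2[s] <- r2_multiple(sim$y, sim$X)
  }
  expect_gt(mean(dc), 0.1)
  expect_lt(mean(r2), 0.02)
})
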