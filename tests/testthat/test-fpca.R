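test_that("identical curves give a zero-variance model with mu = the curve", {
  tr <- sin(seq(0, 3, length.out = 40))
  fit <- fpca(matrix(tr, 5, 40, byrow = TRUE))
  expect_length(fit$eigenvalues, 0L)
  expect_equal(fit$mean_fn, tr)
  expect_error(fraction_variance(fit), "undefined")
  expect_equal(fitted(fit, k = 0), matrix(tr, 5, 40, byrow = TRUE))
})

test_that("a rank-1 construction is recovered exactly", {
  n_t <- 60L
  w <- rep(1, n_t)                        # dt = 1 grid
  s <- orthonormal_shapes(n_t, w)[, 1]
  mu <- 0.3 * cos(seq(0, 1, length.out = n_t))
  ci <- c(-1, 1, -1, 1, 1, -1)
  x <- sweep(outer(ci, s), 2, mu, "+")
  fit <- fpca(x)
  expect_length(fit$eigenvalues, 1L)
  expect_equal(fraction_variance(fit)$fve, 1)
  expect_lt(min(max(abs(fit$eigenfunctions[, 1] - s)),
                max(abs(fit$eigenfunctions[, 1] + s))), 1e-8)
  expect_equal(reconstruct(fit, 1), x, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("uniform-grid fPCA equals scaled matrix PCA (eigendecomposition oracle)", {
  set.seed(42)
  dt <- 0.5
  for (rep in 1:20) {
    x <- matrix(rnorm(10 * 50), 10, 50)
    time_s <- seq(0, by = dt, length.out = 50)
    fit <- fpca(x, time_s = time_s)
    eo <- eigen(stats::cov(x), symmetric = TRUE)
    k <- length(fit$eigenvalues)
    expect_lt(max(abs(fit$eigenvalues - dt * eo$values[seq_len(k)])), 1e-8)
    sc_oracle <- sweep(x, 2, colMeans(x)) %*%
      eo$vectors[, seq_len(k), drop = FALSE] * sqrt(dt)
    expect_lt(max(abs(abs(fit$scores) - abs(sc_oracle))), 1e-8)

    # orthonormality under the quadrature inner product
    gram <- t(fit$eigenfunctions) %*% (fit$eigenfunctions * fit$weights)
    expect_lt(max(abs(gram - diag(k))), 1e-8)
    # variance conservation
    expect_lt(abs(sum(fit$eigenvalues) -
                    sum(fit$weights * apply(x, 2, stats::var))), 1e-8)
    # centered scores
    expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  }
})

test_that("eigenvalue arithmetic gives the expected variance fractions", {
  # 4 curves on 2 time points with sample covariance diag(3, 1)
  s1 <- c(-1.5, -1.5, 1.5, 1.5)
  s2 <- sqrt(3) / 2 * c(-1, 1, 1, -1)
  fit <- fpca(cbind(s1, s2), time_s = c(0, 1))
  expect_equal(fit$eigenvalues, c(3, 1))
  fv <- fraction_variance(fit)
  expect_equal(fv$fve, c(0.75, 0.25))
  expect_equal(fv$cumulative, c(0.75, 1))
})

test_that("component selection honors the cumulative-FVE threshold", {
  fve <- c(0.73, 0.086, 0.027, rep((1 - 0.843) / 16, 16))
  expect_identical(select_k(fve, 0.80), 2L)
  expect_gte(select_k(fve, 0.85), 4L)
  expect_identical(select_k(c(1), 0.5), 1L)
  expect_identical(select_k(c(1), 1), 1L)
  expect_identical(select_k(c(0.6, 0.4, 0, 0), 1), 2L)
  expect_error(select_k(fve, 0), "threshold")
  expect_error(select_k(fve, 1.2), "threshold")
})

test_that("reconstruction is complete at K_max and monotone in K", {
  set.seed(7)
  x <- matrix(rnorm(12 * 30), 12, 30)
  fit <- fpca(x)
  k_max <- length(fit$eigenvalues)
  expect_lt(max(abs(fitted(fit, k_max) - x)), 1e-8)
  err <- vapply(seq_len(k_max), function(k)
    sum((fitted(fit, k) - x)^2), numeric(1))
  expect_true(all(diff(err) <= 1e-10))
  expect_error(reconstruct(fit, 0), "between")
  expect_error(reconstruct(fit, k_max + 1), "between")
})

test_that("generating shapes are recovered from noisy mixtures", {
  set.seed(12)
  n <- 200L; n_t <- 100L
  w <- rep(1, n_t)
  shapes <- orthonormal_shapes(n_t, w)
  xi <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 0.5))
  x <- xi %*% t(shapes) + matrix(rnorm(n * n_t, 0, 0.05), n)
  fit <- fpca(x)
  for (k in 1:2) {
    ip <- sum(fit$weights * fit$eigenfunctions[, k] * shapes[, k])
    expect_gte(abs(ip), 0.99)
  }
})

test_that("scores of new curves match training scores", {
  set.seed(3)
  x <- matrix(rnorm(8 * 25), 8, 25)
  fit <- fpca(x)
  expect_equal(predict(fit, x), fit$scores, ignore_attr = TRUE)
})

test_that("a non-uniform grid falls back to trapezoid weights with a warning", {
  x <- matrix(rnorm(6 * 10), 6, 10)
  expect_warning(fit <- fpca(x, time_s = c(0:8, 10.5)), "trapezoid")
  expect_equal(sum(fit$weights), 10.5 - 0)
  expect_error(fpca(x[1, , drop = FALSE]), "at least 2")
})
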