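test_that("ard_rbf matches its closed form and degenerate cases", {
  # zero distance returns the amplitude
  expect_equal(ard_rbf(matrix(0, 1, 2), matrix(0, 1, 2),
                       ard_kernel(2.5, c(3, 7))),
               matrix(2.5, 1, 1))
  # zero ARD weight removes a dimension's influence entirely
  X <- matrix(rnorm(10), 5, 2)
  X2 <- matrix(rnorm(6), 3, 2)
  expect_equal(ard_rbf(X, X2, ard_kernel(1, c(0, 0))), matrix(1, 5, 3))
  # direct hand evaluation: w = 2, d = 1 -> exp(-1)
  expect_equal(ard_rbf(matrix(0, 1, 1), matrix(1, 1, 1), ard_kernel(1, 2)),
               matrix(exp(-1), 1, 1))
  expect_error(ard_rbf(X, X2, ard_kernel(1, 1)), "latent dimension")
  expect_error(ard_kernel(-1, 1), "nonnegative")
  expect_error(ard_kernel(1, c(1, -2)), "nonnegative")
})

test_that("ard_rbf is translation invariant and decreasing in distance", {
  set.seed(11)
  X <- matrix(rnorm(8), 4, 2)
  X2 <- matrix(rnorm(6), 3, 2)
  k <- ard_kernel(1.3, c(0.7, 2))
  shift <- matrix(rnorm(2), 1)
  expect_equal(ard_rbf(X, X2, k),
               ard_rbf(sweep(X, 2, shift), sweep(X2, 2, shift), k))
  d <- seq(0, 3, by = 0.25)
  vals <- ard_rbf(matrix(0, 1, 1), matrix(d, ncol = 1), ard_kernel(1, 1.5))
  expect_true(all(diff(as.vector(vals)) < 0))
})

test_that("square kernel matrices are symmetric and numerically PSD", {
  set.seed(21)
  for (rep in 1:10) {
    X <- matrix(rnorm(12), 6, 2)
    K <- ard_rbf(X, NULL, ard_kernel(runif(1, 0.5, 2), runif(2, 0.1, 3)))
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("coreg_kernel_full obeys Kronecker identities and the guard", {
  KB <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(coreg_kernel_full(matrix(1), KB), KB)
  blockdiag <- coreg_kernel_full(diag(2), KB)
  expect_equal(blockdiag, rbind(cbind(KB, matrix(0, 2, 2)),
                                cbind(matrix(0, 2, 2), KB)))
  # eigenvalues of the Kronecker product are all pairwise products
  set.seed(5)
  XA <- matrix(rnorm(6), 3, 2); XB <- matrix(rnorm(4), 2, 2)
  KA <- ard_rbf(XA, NULL, ard_kernel(1.2, c(1, 0.5)))
  KB2 <- ard_rbf(XB, NULL, ard_kernel(0.8, c(2, 1)))
  ev <- eigen(coreg_kernel_full(KA, KB2), only.values = TRUE)$values
  prods <- sort(as.vector(outer(eigen(KA, only.values = TRUE)$values,
                                eigen(KB2, only.values = TRUE)$values)),
                decreasing = TRUE)
  expect_equal(sort(ev, decreasing = TRUE), prods, tolerance = 1e-10)
  expect_error(coreg_kernel_full(diag(200), diag(200)), "oracle")
})

test_that("Hadamard cross-covariances equal Kronecker entries on matched pairs", {
  set.seed(31)
  for (rep in 1:20) {
    I <- sample(2:6, 1); J <- sample(2:6, 1); m <- sample(1:4, 1)
    r1 <- sample(1:3, 1); r2 <- sample(1:3, 1)
    A <- matrix(rnorm(I * r1), I, r1); B <- matrix(rnorm(J * r2), J, r2)
    kA <- ard_kernel(runif(1, 0.5, 2), runif(r1, 0.2, 2))
    kB <- ard_kernel(runif(1, 0.5, 2), runif(r2, 0.2, 2))
    ci <- sample(I, m, replace = TRUE); fi <- sample(J, m, replace = TRUE)
    Kfull <- coreg_kernel_full(ard_rbf(A, NULL, kA), ard_rbf(B, NULL, kB))
    # every observed triple, cell-major order
    ti <- rep(seq_len(I), each = J); tj <- rep(seq_len(J), times = I)
    Kuf <- coreg_cross_cov(A[ti, , drop = FALSE], B[tj, , drop = FALSE],
                           A[ci, , drop = FALSE], B[fi, , drop = FALSE],
                           kA, kB)
    rows <- (ci - 1) * J + fi
    expect_equal(Kuf, Kfull[rows, , drop = FALSE], tolerance = 1e-12,
                 ignore_attr = TRUE)
    # inducing-vs-inducing block agrees too
    Kuu <- ard_rbf(A[ci, , drop = FALSE], NULL, kA) *
      ard_rbf(B[fi, , drop = FALSE], NULL, kB)
    expect_equal(Kuu, Kfull[rows, rows, drop = FALSE], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("coreg_cross_cov validates inputs and annihilates with zero variance", {
  A <- matrix(rnorm(4), 2, 2); B <- matrix(rnorm(4), 2, 2)
  kA <- ard_kernel(1, c(1, 1)); kB0 <- ard_kernel(0, c(1, 1))
  expect_equal(coreg_cross_cov(A, B, A, B, kA, kB0), matrix(0, 2, 2))
  expect_equal(coreg_cross_cov(A[1, , drop = FALSE], B[1, , drop = FALSE],
                               A[1, , drop = FALSE], B[1, , drop = FALSE],
                               ard_kernel(1, c(1, 1)), ard_kernel(1, c(1, 1))),
               matrix(1, 1, 1))
  expect_error(coreg_cross_cov(A, B, A, B[1, , drop = FALSE], kA, kA),
               "same number m")
})
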