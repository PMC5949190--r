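test_that("polynomial, RBF and mixed kernels match their closed forms", {
  expect_equal(poly_kernel(c(0, 0), c(0, 0), d = 2), 1)
  expect_equal(poly_kernel(c(1, 1), c(1, 1), d = 2), 9)
  expect_equal(poly_kernel(c(1, 0), c(0, 1), d = 3), 1)
  expect_error(poly_kernel(c(1, 2), c(1, 2, 3), d = 2), "dimension")

  expect_equal(rbf_kernel(c(0.3, -1), c(0.3, -1), g = 2), 1)
  expect_equal(rbf_kernel(c(0, 0), c(2, 0), g = sqrt(2)), exp(-1))
  expect_equal(rbf_kernel(0, 3, g = 1.5), exp(-2))
  expect_error(rbf_kernel(0, 1, g = 0), "positive")

  p1 <- kernel_params(m = 1, d = 2, g = 1)
  p0 <- kernel_params(m = 0, d = 2, g = 1)
  x <- c(0.4, -1.2); y <- c(2, 0.5)
  expect_equal(mixed_kernel(x, y, p1), poly_kernel(x, y, 2))
  expect_equal(mixed_kernel(x, y, p0), rbf_kernel(x, y, 1))
  expect_equal(mixed_kernel(c(0, 0), c(0, 0),
                            kernel_params(0.8, 2, 1)), 1)
})

test_that("the gamma convention reinterprets g and converts to width", {
  x <- c(1, 0); y <- c(0, 2)
  r2 <- sum((x - y)^2)
  pg <- kernel_params(m = 0, d = 2, g = 0.3, g_as = "gamma")
  expect_equal(mixed_kernel(x, y, pg), exp(-0.3 * r2))
  # conversion round-trips and the two conventions agree after it
  g <- 19.0653
  pw <- kernel_params(m = 0, d = 2, g = g, g_as = "width")
  pe <- kernel_params(m = 0, d = 2, g = gamma_from_width(g), g_as = "gamma")
  expect_equal(mixed_kernel(x, y, pw), mixed_kernel(x, y, pe))
  expect_equal(width_from_gamma(gamma_from_width(g)), g)
})

test_that("mixed kernel is symmetric, linear in m, and positive on the diagonal", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(4); y <- rnorm(4)
    m <- runif(1, 0.05, 0.95); d <- sample(2:3, 1); g <- runif(1, 0.2, 5)
    p <- kernel_params(m, d, g)
    expect_identical(mixed_kernel(x, y, p), mixed_kernel(y, x, p))
    v1 <- mixed_kernel(x, y, kernel_params(1, d, g))
    v0 <- mixed_kernel(x, y, kernel_params(0, d, g))
    expect_equal(mixed_kernel(x, y, p), m * v1 + (1 - m) * v0)
    expect_equal(mixed_kernel(x, x, p), m * (sum(x * x) + 1)^d + (1 - m))
    expect_gte(mixed_kernel(x, x, p), 1 - m)
  }
})

test_that("convex kernel combinations validate weights and reduce correctly", {
  expect_equal(combine_kernels(3.0, 1.0), 3.0)
  expect_equal(combine_kernels(c(2, 4), c(0.5, 0.5)), 3.0)
  expect_equal(combine_kernels(c(1, 2, 3), c(0.2, 0.3, 0.5)), 2.3)
  expect_error(combine_kernels(c(1, 2), c(0.5, 0.6)), "sum to 1")
  expect_error(combine_kernels(c(1, 2), c(1.2, -0.2)), "weight")
  expect_error(combine_kernels(c(1, 2, 3), c(0.5, 0.5)), "length")
  # the two-kernel mixture is the U = 2 special case
  p <- kernel_params(0.7, 2, 1.3)
  x <- c(1, -0.5); y <- c(0.2, 0.8)
  expect_equal(
    combine_kernels(c(poly_kernel(x, y, 2), rbf_kernel(x, y, 1.3)),
                    c(0.7, 0.3)),
    mixed_kernel(x, y, p))
})

test_that("gram_matrix assembles pairwise mixed-kernel values", {
  set.seed(7)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(9), 3, 3)
  p <- kernel_params(0.5, 2, 1)
  K <- gram_matrix(A, B, p)
  expect_equal(dim(K), c(5L, 3L))
  for (i in 1:5) for (j in 1:3)
    expect_equal(K[i, j], mixed_kernel(A[i, ], B[j, ], p))
  # self-Gram: symmetric, unit 1x1 reduction
  Ks <- gram_matrix(A, params = p)
  expect_lt(max(abs(Ks - t(Ks))), 1e-12)
  x <- matrix(c(1, 2), 1)
  expect_equal(gram_matrix(x, params = p)[1, 1], mixed_kernel(c(1, 2), c(1, 2), p))
  expect_error(gram_matrix(A, matrix(0, 2, 2), p), "feature dimension")
})

test_that("self-Gram matrices of the mixed kernel are positive semidefinite", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    X <- matrix(rnorm(n * sample(2:6, 1), sd = runif(1, 0.5, 3)), n)
    p <- kernel_params(runif(1, 0.01, 0.99), sample(2:3, 1),
                       runif(1, 0.05, 30))
    res <- check_psd(gram_matrix(X, params = p))
    expect_true(res$is_psd)
  }
})

test_that("check_psd reports the smallest eigenvalue and rejects bad input", {
  res <- check_psd(diag(3))
  expect_true(res$is_psd)
  expect_equal(res$min_eigenvalue, 1)
  res <- check_psd(matrix(c(1, 2, 2, 1), 2), tol = 1e-8)
  expect_false(res$is_psd)
  expect_equal(res$min_eigenvalue, -1)
  expect_error(check_psd(matrix(0, 2, 3)), "square")
  expect_error(check_psd(matrix(c(1, 5, 2, 1), 2)), "symmetric")
})
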