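test_that("sigmoid basis has the logistic form and saturates", {
  expect_equal(sigmoid_basis(0, 1), 0.5)
  expect_equal(sigmoid_basis(0, 7.3), 0.5)
  expect_equal(sigmoid_basis(1, 1), 1 / (1 + exp(-1)))
  expect_equal(sigmoid_basis(50, 1), 1, tolerance = 1e-10)
  expect_error(sigmoid_basis(Inf, 1), "finite")
  expect_error(sigmoid_basis(NaN, 1), "finite")
  expect_error(sigmoid_basis(0, 0), "positive")
  expect_error(sigmoid_basis(0, -1), "positive")
})

test_that("sigmoid basis stays in (0,1) and is monotone in x", {
  set.seed(42)
  for (i in 1:25) {
    mu <- stats::runif(1, 0.05, 3)
    x <- sort(stats::runif(50, -8, 8))
    y <- sigmoid_basis(x, mu)
    expect_true(all(y > 0 & y < 1))
    expect_true(all(diff(y) > 0))
  }
})

test_that("propagation reduces to the bias with no interactions", {
  p <- gene_network_params(matrix(0, 3, 3), matrix(0, 3, 3),
                           sigmoid_params = rep(1, 3),
                           biases = c(-1, 0, 2.5), process_noise_var = 0)
  expect_equal(propagate_expression(c(5, -2, 0.3), p), c(-1, 0, 2.5))
})

test_that("propagation matches hand-computed two-gene dynamics", {
  p <- two_gene_params()
  x1 <- propagate_expression(c(1, 0), p)
  expect_equal(x1[2], 0.7 * 1 + 0.5 / (1 + exp(-1)))
  expect_equal(x1[1], 0)
  # deleting the regulator removes every gene-1 term
  x1_ko <- propagate_expression(c(1, 0), p, deleted = 1)
  expect_equal(x1_ko, c(0, 0))
})

test_that("propagation is exactly additive in the noise argument", {
  set.seed(1)
  p <- random_params(4, seed = 2)
  for (i in 1:10) {
    x <- stats::rnorm(4)
    v <- stats::rnorm(4)
    expect_equal(propagate_expression(x, p, noise = v) -
                   propagate_expression(x, p), v, tolerance = 1e-12)
  }
})

test_that("linear-only propagation equals the affine map A x + I", {
  set.seed(3)
  n <- 5
  A <- matrix(stats::rnorm(n * n, sd = 0.3), n, n)
  p <- gene_network_params(A, matrix(0, n, n), rep(1, n),
                           biases = stats::rnorm(n), process_noise_var = 0)
  for (i in 1:5) {
    x <- stats::rnorm(n)
    expect_equal(propagate_expression(x, p), drop(A %*% x) + p$biases,
                 tolerance = 1e-12)
  }
})

test_that("knockout masking zeroes row, column, bias and clamps the state", {
  p <- random_params(4, seed = 7)
  m <- apply_knockout(p, 2)
  expect_equal(m$linear_coefs[2, ], rep(0, 4))
  expect_equal(m$linear_coefs[, 2], rep(0, 4))
  expect_equal(m$nonlinear_coefs[2, ], rep(0, 4))
  expect_equal(m$nonlinear_coefs[, 2], rep(0, 4))
  expect_equal(m$biases[2], 0)
  # untouched entries survive
  expect_equal(m$linear_coefs[-2, -2], p$linear_coefs[-2, -2])
  # deleted gene's state is clamped to zero on propagation
  x <- propagate_expression(c(1, 1, 1, 1), p, deleted = 2)
  expect_equal(x[2], 0)
})

test_that("knockout is idempotent, commutes over disjoint sets, and can empty the network", {
  p <- random_params(5, seed = 11)
  expect_identical(apply_knockout(p, integer(0)), p)
  once <- apply_knockout(p, c(1, 3))
  expect_identical(apply_knockout(once, c(1, 3)), once)
  ab <- apply_knockout(apply_knockout(p, 1), c(4, 5))
  ba <- apply_knockout(apply_knockout(p, c(4, 5)), 1)
  expect_identical(ab, ba)
  all_ko <- apply_knockout(p, 1:5)
  expect_equal(all_ko$linear_coefs, matrix(0, 5, 5))
  expect_equal(all_ko$nonlinear_coefs, matrix(0, 5, 5))
  expect_error(apply_knockout(p, 6), "indices")
  expect_error(apply_knockout(p, 0), "indices")
})

test_that("parameter constructor validates shapes and PSD noise", {
  A <- matrix(0, 2, 2)
  expect_error(gene_network_params(matrix(0, 2, 3), A, c(1, 1), c(0, 0), 0),
               "square")
  expect_error(gene_network_params(A, matrix(0, 3, 3), c(1, 1), c(0, 0), 0),
               "match")
  expect_error(gene_network_params(A, A, c(1, -1), c(0, 0), 0), "positive")
  expect_error(gene_network_params(A, A, c(1, 1), c(0, 0),
                                   matrix(c(1, 2, 2, 1), 2, 2)),
               "semi-definite")
})
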