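test_that("sigma points have the closed form in one dimension", {
  # lambda = alpha^2 (L + kappa) - L = 2 with alpha = 1, kappa = 2, L = 1
  sp <- ukf_sigma_points(gaussian_belief(0, matrix(1)),
                         ukf_scaling(alpha = 1, beta = 2, kappa = 2))
  expect_equal(sp$lambda, 2)
  expect_equal(sort(drop(sp$points)), sort(c(0, sqrt(3), -sqrt(3))))
  expect_equal(sum(sp$mean_weights), 1)
})

test_that("sigma point weights normalize and the count is 2L+1", {
  set.seed(17)
  for (L in c(2, 5, 9)) {
    M <- matrix(stats::rnorm(L * L), L, L)
    bel <- gaussian_belief(stats::rnorm(L), crossprod(M) + diag(L))
    sp <- ukf_sigma_points(bel)
    expect_equal(ncol(sp$points), 2 * L + 1)
    expect_equal(sum(sp$mean_weights), 1)
  }
})

test_that("a near-degenerate covariance collapses points onto the mean", {
  bel <- gaussian_belief(c(1, 2), diag(1e-18, 2))
  sp <- ukf_sigma_points(bel)
  expect_lt(max(abs(sp$points - c(1, 2))), 1e-3)
})

test_that("the unscented transform is exact for identity and affine maps", {
  set.seed(23)
  for (i in 1:10) {
    L <- sample(2:6, 1)
    M <- matrix(stats::rnorm(L * L), L, L)
    P <- crossprod(M) + 0.5 * diag(L)
    bel <- gaussian_belief(stats::rnorm(L), P)
    sp <- ukf_sigma_points(bel)
    ident <- unscented_transform(sp, function(z) z)
    expect_equal(ident$mean, bel$mean, tolerance = 1e-8)
    expect_equal(ident$cov, bel$cov, tolerance = 1e-8)
    A <- matrix(stats::rnorm(3 * L), 3, L)
    b <- stats::rnorm(3)
    aff <- unscented_transform(sp, function(z) drop(A %*% z) + b)
    expect_equal(aff$mean, drop(A %*% bel$mean) + b, tolerance = 1e-8)
    expect_equal(aff$cov, A %*% bel$cov %*% t(A), tolerance = 1e-8)
  }
})

test_that("the transform of x^2 under N(0,1) matches Monte Carlo", {
  sp <- ukf_sigma_points(gaussian_belief(0, matrix(1)))
  sq <- unscented_transform(sp, function(z) z^2)
  set.seed(99)
  mc <- stats::rnorm(1e5)^2
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(sq$mean - mean(mc)), 3 * se)
})

test_that("one UKF step equals the closed-form Kalman step on a linear model", {
  set.seed(5)
  L <- 3
  A <- matrix(stats::rnorm(L * L, sd = 0.4), L, L)
  H <- matrix(stats::rnorm(L), 1, L)
  Q <- diag(stats::runif(L, 0.01, 0.1))
  R <- 0.04
  m <- stats::rnorm(L); P <- diag(L)
  y <- 0.7
  kf <- kf_step(m, P, A, H, Q, R, y)
  post <- ukf_step(gaussian_belief(m, P),
                   function(z) drop(A %*% z), function(z) drop(H %*% z),
                   y, Q, R)
  expect_equal(post$mean, kf$mean, tolerance = 1e-10)
  expect_equal(post$cov, kf$cov, tolerance = 1e-10)
})

test_that("uninformative or overwhelmed measurements leave the prediction", {
  set.seed(6)
  L <- 4
  bel <- gaussian_belief(stats::rnorm(L), diag(L))
  dyn <- function(z) z
  # constant observation function: zero gain
  post <- ukf_step(bel, dyn, function(z) 5, 5, diag(0.01, L), 0.1)
  expect_equal(post$mean, bel$mean, tolerance = 1e-12)
  # enormous observation noise: update collapses to the prediction
  post2 <- ukf_step(bel, dyn, function(z) sum(z), 100, diag(0.01, L), 1e12)
  pred_only <- bel$mean
  expect_equal(post2$mean, pred_only, tolerance = 1e-6)
})

test_that("conditioning never inflates the covariance trace", {
  set.seed(27)
  for (i in 1:10) {
    L <- sample(2:6, 1)
    M <- matrix(stats::rnorm(L * L), L, L)
    bel <- gaussian_belief(stats::rnorm(L), crossprod(M) / L + diag(L))
    A <- matrix(stats::rnorm(L * L, sd = 0.3), L, L)
    H <- stats::rnorm(L)
    Q <- diag(0.01, L)
    post <- ukf_step(bel, function(z) drop(A %*% z),
                     function(z) sum(H * z), stats::rnorm(1), Q, 0.05)
    d <- attr(post, "diagnostics")
    expect_lte(d$post_trace, d$pred_trace + 1e-8)
    expect_lt(max(abs(post$cov - t(post$cov))), 1e-10)
    expect_gte(min(eigen(post$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("invalid observations and degenerate inputs are rejected", {
  bel <- gaussian_belief(0, matrix(1))
  expect_error(ukf_step(bel, identity, identity, NaN, matrix(0.01), 0.1),
               "finite")
  expect_error(gaussian_belief(c(0, 0), matrix(c(1, 0.5, 0.49, 1), 2, 2)),
               "symmetric")
})
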