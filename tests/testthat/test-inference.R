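test_that("the augmented layout partitions the state vector exactly", {
  lay <- augmented_layout(5, 5)
  all_idx <- c(lay$x, lay$linear, lay$nonlinear, lay$mu, lay$bias, lay$rbf)
  expect_equal(sort(all_idx), seq_len(lay$length))
  expect_equal(lay$length, 2 * 25 + 3 * 5 + 5)
  expect_equal(anyDuplicated(all_idx), 0L)
})

test_that("thresholding keeps entries at or above the fraction of the max", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1.091; A[1, 3] <- 0.5; A[2, 3] <- 0.3; A[3, 1] <- -0.44
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.2
  net <- threshold_network(A, B, fraction = 0.4)
  expect_equal(net$threshold_linear, 0.4 * 1.091)
  # 0.5 and |-0.44| survive at threshold 0.4364; 0.3 does not
  lin <- net$typed_edges[net$typed_edges$type == "linear", ]
  expect_setequal(paste(lin$source, lin$target), c("2 1", "3 1", "1 3"))
  # the argmax entry always survives
  expect_true(any(lin$source == 2 & lin$target == 1))
  # fraction 0 keeps every nonzero estimate
  net0 <- threshold_network(A, B, fraction = 0)
  expect_equal(nrow(net0$typed_edges), 5)
  expect_warning(threshold_network(matrix(0, 2, 2), matrix(0, 2, 2)),
                 "zero")
})

test_that("diagonal entries set the scale only through off-diagonal maxima", {
  A <- diag(c(5, 5))        # large self terms must not drive the threshold
  A[1, 2] <- 0.6
  net <- threshold_network(A, matrix(0, 2, 2), fraction = 0.4)
  expect_equal(net$threshold_linear, 0.24)
  expect_equal(nrow(net$typed_edges), 1)
  expect_equal(net$typed_edges$source, 2)
})

test_that("infer_network validates the feeding order", {
  ref <- cached_reference()
  d <- simulate_knockout_dataset(ref$params, ref$fitness_model, rounds = 2,
                                 seed = 3, settle_steps = 20)
  expect_error(infer_network(d, ref$fitness_model, order = c(1, 1, 2, 3, 4)),
               "permutation")
  expect_error(infer_network(d, ref$fitness_model, order = "bogus"),
               "unknown order")
})

test_that("inference is bit-reproducible given the same data and config", {
  ref <- cached_reference()
  d <- simulate_knockout_dataset(ref$params, ref$fitness_model, rounds = 4,
                                 seed = 11, settle_steps = 20)
  n1 <- infer_network(d, ref$fitness_model, order = "correlation")
  n2 <- infer_network(d, ref$fitness_model, order = "correlation")
  expect_identical(n1$linear_estimates, n2$linear_estimates)
  expect_identical(n1$nonlinear_estimates, n2$nonlinear_estimates)
  expect_identical(n1$typed_edges, n2$typed_edges)
})

test_that("a strain's predicted fitness ignores its own masked coefficients", {
  ref <- cached_reference()
  lay <- augmented_layout(5, 5)
  ctl <- infer_control()
  d <- 3L
  dyn <- fitnessGRN:::make_augmented_dynamics(d, 5, lay, ctl)
  obs <- fitnessGRN:::make_augmented_observation(
    lay, ref$fitness_model$centres, ref$fitness_model$shape_const)
  set.seed(33)
  z <- stats::rnorm(lay$length, sd = 0.5)
  base_pred <- obs(dyn(z))
  # perturb every linear/nonlinear coefficient touching gene d, its bias,
  # and its expression entry
  z2 <- z
  Aidx <- matrix(lay$linear, 5, 5)
  Bidx <- matrix(lay$nonlinear, 5, 5)
  touched <- c(Aidx[d, ], Aidx[, d], Bidx[d, ], Bidx[, d],
               lay$bias[d], lay$x[d])
  z2[touched] <- z2[touched] + stats::rnorm(length(touched))
  expect_equal(obs(dyn(z2)), base_pred, tolerance = 1e-12)
})

test_that("true linear edges outrank non-edges on average across seeds", {
  ref <- cached_reference()
  A_true <- ref$params$linear_coefs
  off <- !diag(TRUE, 5)
  is_edge <- A_true != 0
  margin <- numeric(0)
  for (s in 1:10) {
    d <- simulate_knockout_dataset(ref$params, ref$fitness_model,
                                   rounds = 10, seed = s, settle_steps = 20)
    net <- infer_network(d, ref$fitness_model, order = "correlation")
    est <- net$linear_estimates
    margin <- c(margin, mean(est[is_edge]) - mean(est[off & !is_edge]))
  }
  expect_gt(mean(margin), 0)
  expect_gt(mean(margin > 0), 0.5)
})

test_that("data from an empty network yields only small coefficient estimates", {
  n <- 5
  p0 <- gene_network_params(matrix(0, n, n), matrix(0, n, n), rep(1, n),
                            biases = rep(0.2, n), process_noise_var = 1e-4)
  ref <- cached_reference()
  fit <- rbf_fitness_model(ref$fitness_model$centres,
                           ref$fitness_model$coefficients,
                           ref$fitness_model$shape_const,
                           obs_noise_var = 1e-4)
  d <- simulate_knockout_dataset(p0, fit, rounds = 10, seed = 21,
                                 settle_steps = 20)
  net <- infer_network(d, fit, order = "correlation")
  expect_lt(max(abs(net$linear_estimates)), 0.35)
  expect_lt(max(abs(net$nonlinear_estimates)), 0.35)
})
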