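# End-to-end estimator: augmented state over expression levels and all
# model parameters, filtered sequentially over knockout observations.

#' Index layout of the augmented state vector
#'
#' The filter estimates expression levels and every model parameter jointly
#' in one vector `z = [x; vec(A); vec(B); mu; bias; c]` (column-major
#' matrix vectorization). The layout maps slice names to index ranges.
#'
#' @param n_genes number of genes n.
#' @param n_bases number of fitness basis functions K.
#' @return List of integer index vectors `x`, `linear`, `nonlinear`, `mu`,
#'   `bias`, `rbf`, plus `length` (total dimension `2n^2 + 3n + K`).
#' @export
augmented_layout <- function(n_genes, n_bases) {
  n <- n_genes
  cuts <- cumsum(c(n, n * n, n * n, n, n, n_bases))
  starts <- c(1L, utils::head(cuts, -1L) + 1L)
  out <- list(x = starts[1]:cuts[1],
              linear = starts[2]:cuts[2],
              nonlinear = starts[3]:cuts[3],
              mu = starts[4]:cuts[4],
              bias = starts[5]:cuts[5],
              rbf = starts[6]:cuts[6],
              length = cuts[6])
  out
}

#' Control settings for network inference
#'
#' @param settle_steps dynamics applications per observation inside the
#'   filter (default 1: one model step per measurement).
#' @param q_expr process-noise variance per expression level inside the
#'   filter (default 0.01).
#' @param q_param random-walk variance per parameter per step (default
#'   1e-4; keeps the parameter covariance from collapsing in sequential
#'   mode).
#' @param prior_x_mean,prior_x_var initial belief over expression levels
#'   (defaults 0.5 and 1).
#' @param prior_coef_var initial variance of regulation coefficients and
#'   biases (mean 0; default 1).
#' @param prior_mu_mean,prior_mu_var initial belief over sigmoid steepness
#'   (defaults 1 and 0.25; values are soft-clipped at `mu_floor` when
#'   used).
#' @param prior_rbf_var initial variance of the fitness basis coefficients
#'   (mean 0; default 1).
#' @param mu_floor lower clip applied to steepness draws (default 1e-3).
#' @param reset_expression if `TRUE`, the expression slice of the belief is
#'   re-initialized to (`prior_x_mean`, `prior_x_var`) before every
#'   observation, mirroring an assay protocol in which each strain grows
#'   from the same initial condition; if `FALSE` (default) the expression
#'   belief carries over from strain to strain.
#' @param scaling a [ukf_scaling()].
#' @return List of class `"infer_control"`.
#' @export
infer_control <- function(settle_steps = 1, q_expr = 0.01, q_param = 1e-4,
                          prior_x_mean = 0.5, prior_x_var = 1,
                          prior_coef_var = 1,
                          prior_mu_mean = 1, prior_mu_var = 0.25,
                          prior_rbf_var = 1, mu_floor = 1e-3,
                          reset_expression = FALSE,
                          scaling = ukf_scaling()) {
  stopifnot(settle_steps >= 1, q_expr >= 0, q_param >= 0)
  structure(list(settle_steps = settle_steps, q_expr = q_expr,
                 q_param = q_param, prior_x_mean = prior_x_mean,
                 prior_x_var = prior_x_var, prior_coef_var = prior_coef_var,
                 prior_mu_mean = prior_mu_mean, prior_mu_var = prior_mu_var,
                 prior_rbf_var = prior_rbf_var, mu_floor = mu_floor,
                 reset_expression = isTRUE(reset_expression),
                 scaling = scaling),
            class = "infer_control")
}

# initial augmented belief from the control priors
initial_belief <- function(n, K, control) {
  lay <- augmented_layout(n, K)
  m <- numeric(lay$length)
  v <- numeric(lay$length)
  m[lay$x] <- control$prior_x_mean
  v[lay$x] <- control$prior_x_var
  v[lay$linear] <- control$prior_coef_var
  v[lay$nonlinear] <- control$prior_coef_var
  m[lay$mu] <- control$prior_mu_mean
  v[lay$mu] <- control$prior_mu_var
  v[lay$bias] <- control$prior_coef_var
  v[lay$rbf] <- control$prior_rbf_var
  gaussian_belief(m, diag(v))
}

# dynamics of the augmented state for the strain with gene d deleted:
# masked one-or-more-step regulation update on the expression slice,
# identity on all parameter slices
make_augmented_dynamics <- function(d, n, lay, control) {
  steps <- control$settle_steps
  mu_floor <- control$mu_floor
  function(z) {
    x <- z[lay$x]
    A <- matrix(z[lay$linear], n, n)
    B <- matrix(z[lay$nonlinear], n, n)
    mu <- pmax(z[lay$mu], mu_floor)
    bias <- z[lay$bias]
    A[d, ] <- 0; A[, d] <- 0
    B[d, ] <- 0; B[, d] <- 0
    bias[d] <- 0
    x[d] <- 0
    for (s in seq_len(steps)) {
      x <- drop(A %*% x) + drop(B %*% (1 / (1 + exp(-mu * x)))) + bias
      x[d] <- 0
    }
    z[lay$x] <- x
    z
  }
}

# scalar fitness prediction from the augmented state via the fixed centres
make_augmented_observation <- function(lay, centres, h) {
  tc <- t(centres)
  h2 <- h^2
  function(z) {
    x <- z[lay$x]
    sum(z[lay$rbf] * sqrt(colSums((tc - x)^2) + h2))
  }
}

#' Infer a gene regulatory network from knockout fitness data
#'
#' Runs the unscented Kalman filter over the knockout observations: the
#' augmented state (expression levels plus all regulation parameters,
#' sigmoid steepnesses, biases and fitness basis coefficients) is predicted
#' through the knockout-masked dynamics of the current strain and updated
#' with its scalar fitness measurement. Observations are consumed round by
#' round, genes within a round in the feeding order. The posterior-mean
#' coefficient matrices after the last observation are thresholded into a
#' typed edge set.
#'
#' @param data a [fitness_dataset()].
#' @param fitness_basis an [rbf_fitness_model()] supplying the a-priori
#'   basis centres and shape constant (its coefficients, if any, are
#'   ignored — they are estimated).
#' @param order `"correlation"` (default) for the correlation-score feeding
#'   order, `"given"` with `permutation` supplied, or an integer permutation
#'   of `1:n` directly.
#' @param permutation explicit feeding order when `order = "given"`.
#' @param threshold_fraction edges are kept when their coefficient
#'   magnitude is at least this fraction of the largest off-diagonal
#'   magnitude of their type (default 0.4).
#' @param control an [infer_control()].
#' @return An `"inferred_network"` object: estimate matrices, thresholds,
#'   surviving `typed_edges`, the feeding order used, per-step innovation
#'   diagnostics, and the final posterior belief.
#' @export
infer_network <- function(data, fitness_basis, order = "correlation",
                          permutation = NULL, threshold_fraction = 0.4,
                          control = infer_control()) {
  stopifnot(inherits(data, "fitness_dataset"),
            inherits(fitness_basis, "rbf_fitness_model"),
            inherits(control, "infer_control"))
  n <- data$n_genes
  if (fitness_basis$n_genes != n)
    stop("fitness basis dimension does not match the dataset", call. = FALSE)
  K <- fitness_basis$n_bases
  lay <- augmented_layout(n, K)

  if (is.numeric(order)) {
    permutation <- as.integer(order)
    order <- "given"
  }
  perm <- switch(order,
    correlation = feeding_order(correlation_score(data))$permutation,
    given = as.integer(permutation),
    stop("unknown order '", order, "'", call. = FALSE))
  if (!identical(sort(perm), seq_len(n)))
    stop("feeding order is not a permutation of 1:", n, call. = FALSE)

  belief <- initial_belief(n, K, control)
  q_diag <- numeric(lay$length)
  q_diag[-lay$x] <- control$q_param
  obs_fn <- make_augmented_observation(lay, fitness_basis$centres,
                                       fitness_basis$shape_const)
  dyn_fns <- lapply(seq_len(n), make_augmented_dynamics,
                    n = n, lay = lay, control = control)
  R_obs <- fitness_basis$obs_noise_var
  innov <- numeric(0)
  step_i <- 0L
  for (r in seq_len(data$rounds)) {
    for (d in perm) {
      step_i <- step_i + 1L
      q_step <- q_diag
      q_step[lay$x] <- control$q_expr
      q_step[lay$x][d] <- 0
      if (control$reset_expression) {
        m <- belief$mean
        P <- belief$cov
        m[lay$x] <- control$prior_x_mean
        P[lay$x, ] <- 0
        P[, lay$x] <- 0
        P[cbind(lay$x, lay$x)] <- control$prior_x_var
        belief <- gaussian_belief(m, P)
      }
      belief <- tryCatch(
        ukf_step(belief, dyn_fns[[d]], obs_fn,
                 observation = data$values[r, d],
                 process_noise_var = q_step, obs_noise_var = R_obs,
                 scaling = control$scaling),
        error = function(e)
          stop("filter diverged at step ", step_i, " (round ", r,
               ", strain ", d, "): ", conditionMessage(e), call. = FALSE))
      innov <- c(innov, attr(belief, "diagnostics")$innovation)
    }
  }
  A_hat <- matrix(belief$mean[lay$linear], n, n)
  B_hat <- matrix(belief$mean[lay$nonlinear], n, n)
  net <- threshold_network(A_hat, B_hat, fraction = threshold_fraction,
                           genes = data$genes)
  net$order <- perm
  net$innovations <- innov
  net$posterior <- belief
  net$layout <- lay
  net
}

#' Threshold estimated coefficient matrices into a typed edge set
#'
#' Per coefficient type, the threshold is `fraction` times the maximal
#' variation of the estimates — the largest absolute off-diagonal estimate
#' of that type. Off-diagonal entries with magnitude at or above their
#' type's threshold become typed edges (self-regulation entries are not
#' extracted).
#'
#' @param linear_estimates,nonlinear_estimates n x n estimate matrices
#'   (entry `[i, j]` = effect of gene `j` on gene `i`).
#' @param fraction threshold fraction in \[0, 1\] (default 0.4).
#' @param genes optional gene labels.
#' @return An `"inferred_network"`: the estimate matrices, per-type
#'   thresholds, and a `typed_edges` data frame (`source`, `target`,
#'   `type`, `estimate`), ordered by source, target, type.
#' @export
threshold_network <- function(linear_estimates, nonlinear_estimates,
                              fraction = 0.4, genes = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  A <- as.matrix(linear_estimates)
  B <- as.matrix(nonlinear_estimates)
  n <- nrow(A)
  stopifnot(identical(dim(A), dim(B)), ncol(A) == n)
  off <- !diag(TRUE, n)
  max_l <- max(abs(A[off]))
  max_n <- max(abs(B[off]))
  if (max_l == 0 && max_n == 0)
    warning("all coefficient estimates are zero; thresholds are 0")
  thr_l <- fraction * max_l
  thr_n <- fraction * max_n
  edge_rows <- function(M, thr, type) {
    keep <- which(abs(M) >= thr & off & M != 0, arr.ind = TRUE)
    if (nrow(keep) == 0L)
      return(data.frame(source = integer(0), target = integer(0),
                        type = character(0), estimate = numeric(0)))
    data.frame(source = keep[, 2], target = keep[, 1], type = type,
               estimate = M[keep])
  }
  edges <- rbind(edge_rows(A, thr_l, "linear"),
                 edge_rows(B, thr_n, "nonlinear"))
  edges <- edges[order(edges$source, edges$target, edges$type), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(linear_estimates = A, nonlinear_estimates = B,
         threshold_linear = thr_l, threshold_nonlinear = thr_n,
         threshold_fraction = fraction,
         typed_edges = edges,
         genes = if (is.null(genes)) paste0("g", seq_len(n)) else genes,
         n_genes = n),
    class = "inferred_network")
}

#' @export
print.inferred_network <- function(x, ...) {
  cat("Inferred network:", nrow(x$typed_edges), "typed edges over",
      x$n_genes, "genes (thresholds: linear",
      signif(x$threshold_linear, 3), ", nonlinear",
      signif(x$threshold_nonlinear, 3), ")\n")
  if (nrow(x$typed_edges)) print(x$typed_edges)
  invisible(x)
}
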