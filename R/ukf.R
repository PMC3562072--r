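# Unscented Kalman filtering: sigma points, unscented transform, and
# predict/update steps for additive-noise nonlinear state-space models.

#' Gaussian belief over a state vector
#'
#' @param mean length-L numeric vector.
#' @param cov L x L covariance matrix; symmetrized, and repaired with a tiny
#'   diagonal jitter if slightly indefinite (eigenvalues below `-1e-10` are
#'   an error).
#' @return Object of class `"gaussian_belief"` with elements `mean`, `cov`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  L <- length(mean)
  if (!identical(dim(cov), c(L, L)))
    stop("'cov' must be ", L, " x ", L, call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(cov)))
    stop("belief must be finite", call. = FALSE)
  asym <- max(abs(cov - t(cov)))
  if (asym > 1e-8)
    stop("'cov' is not symmetric (max asymmetry ", format(asym), ")",
         call. = FALSE)
  cov <- (cov + t(cov)) / 2
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' UKF scaling parameters
#'
#' Defaults `alpha = 1`, `beta = 2`, `kappa = 0` (Gaussian-optimal `beta`;
#' `lambda = alpha^2 (L + kappa) - L` is then 0, the classical spread
#' `sqrt(L) * sigma`).
#'
#' @param alpha sigma-point spread parameter (> 0).
#' @param beta prior-distribution parameter (2 is optimal for Gaussians).
#' @param kappa secondary scaling parameter.
#' @return List with class `"ukf_scaling"`.
#' @export
ukf_scaling <- function(alpha = 1, beta = 2, kappa = 0) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "ukf_scaling")
}

# Lower-triangular factor of a PSD matrix, with escalating diagonal jitter:
# 1e-9 * (trace/L), doubled up to 6 times, then an error.
chol_psd_lower <- function(P) {
  L <- nrow(P)
  jit <- 1e-9 * max(sum(diag(P)) / L, .Machine$double.eps)
  attempt <- suppressWarnings(tryCatch(chol(P), error = function(e) NULL))
  tries <- 0L
  while (is.null(attempt) && tries < 6L) {
    P <- P + diag(jit, L)
    jit <- jit * 2
    tries <- tries + 1L
    attempt <- suppressWarnings(tryCatch(chol(P), error = function(e) NULL))
  }
  if (is.null(attempt))
    stop("covariance-degenerate: matrix square root failed after maximum ",
         "jitter", call. = FALSE)
  t(attempt)
}

#' Sigma points of a Gaussian belief
#'
#' The `2L + 1` deterministically placed points
#' \eqn{S_0 = m}, \eqn{S_i = m \pm [\sqrt{(L+\lambda) P}]_i} with
#' \eqn{\lambda = \alpha^2 (L + \kappa) - L}, and weights
#' \eqn{W_0^m = \lambda/(L+\lambda)}, \eqn{W_0^c = W_0^m + 1 - \alpha^2 +
#' \beta}, \eqn{W_i = 1 / (2(L+\lambda))}.
#'
#' @param belief a [gaussian_belief()].
#' @param scaling a [ukf_scaling()].
#' @return List of class `"sigma_points"`: `points` (L x (2L+1) matrix,
#'   first column the mean), `mean_weights`, `cov_weights`, `lambda`.
#' @export
ukf_sigma_points <- function(belief, scaling = ukf_scaling()) {
  stopifnot(inherits(belief, "gaussian_belief"))
  L <- length(belief$mean)
  lambda <- scaling$alpha^2 * (L + scaling$kappa) - L
  c_scale <- L + lambda
  if (c_scale <= 0)
    stop("alpha^2 * (L + kappa) must be positive", call. = FALSE)
  S <- chol_psd_lower(c_scale * belief$cov)
  pts <- matrix(belief$mean, L, 2L * L + 1L)
  pts[, 1L + seq_len(L)] <- pts[, 1L + seq_len(L)] + S
  pts[, 1L + L + seq_len(L)] <- pts[, 1L + L + seq_len(L)] - S
  wm <- c(lambda / c_scale, rep(1 / (2 * c_scale), 2L * L))
  wc <- wm
  wc[1L] <- wm[1L] + (1 - scaling$alpha^2 + scaling$beta)
  structure(list(points = pts, mean_weights = wm, cov_weights = wc,
                 lambda = lambda),
            class = "sigma_points")
}

#' Unscented transform of a sigma-point set
#'
#' Pushes every sigma point through `fn` and returns the weighted mean and
#' (symmetrized) weighted covariance of the images, plus the transformed
#' points themselves for cross-covariance computations.
#'
#' @param sp a [ukf_sigma_points()] result.
#' @param fn function mapping a numeric vector to a numeric vector (constant
#'   output length).
#' @return List with `mean`, `cov`, `transformed` (matrix of transformed
#'   points, one column per sigma point).
#' @export
unscented_transform <- function(sp, fn) {
  stopifnot(inherits(sp, "sigma_points"))
  first <- fn(sp$points[, 1L])
  m <- length(first)
  np <- ncol(sp$points)
  Y <- matrix(NA_real_, m, np)
  Y[, 1L] <- first
  for (i in 2L:np) Y[, i] <- fn(sp$points[, i])
  if (any(!is.finite(Y)))
    stop("transform produced non-finite values", call. = FALSE)
  mean_y <- drop(Y %*% sp$mean_weights)
  D <- Y - mean_y
  cov_y <- D %*% (sp$cov_weights * t(D))
  cov_y <- (cov_y + t(cov_y)) / 2
  list(mean = mean_y, cov = cov_y, transformed = Y)
}

#' One predict/update cycle of the unscented Kalman filter
#'
#' Additive-noise formulation for a scalar observation: the belief is
#' propagated through `dynamics_fn` by the unscented transform and the
#' process-noise covariance added; sigma points are then re-drawn from the
#' predicted belief and pushed through `observation_fn` to obtain the
#' predicted observation mean, variance and state-observation
#' cross-covariance (re-drawing keeps the filter exactly equivalent to the
#' closed-form Kalman recursion on linear-Gaussian models); and the Kalman
#' gain \eqn{K = P_{xy} / (P_{yy} + R)} corrects the mean by the innovation
#' and shrinks the covariance by \eqn{K S K^T} (with \eqn{S} the total
#' innovation variance).
#'
#' @param belief prior [gaussian_belief()].
#' @param dynamics_fn state-transition function (vector to vector, same
#'   length).
#' @param observation_fn function mapping a state vector to a single
#'   predicted observation.
#' @param observation observed scalar (finite).
#' @param process_noise_var additive process-noise covariance (L x L matrix,
#'   or a length-L vector taken as a diagonal).
#' @param obs_noise_var scalar observation-noise variance (> 0).
#' @param scaling a [ukf_scaling()].
#' @return Posterior [gaussian_belief()] with attribute `"diagnostics"`
#'   (innovation, predicted observation variance, gain norm, predicted and
#'   posterior covariance traces).
#' @export
ukf_step <- function(belief, dynamics_fn, observation_fn, observation,
                     process_noise_var, obs_noise_var,
                     scaling = ukf_scaling()) {
  if (!is.finite(observation) || length(observation) != 1L)
    stop("'observation' must be a finite scalar", call. = FALSE)
  L <- length(belief$mean)
  if (is.vector(process_noise_var) && length(process_noise_var) == L)
    process_noise_var <- diag(process_noise_var, L)
  sp <- ukf_sigma_points(belief, scaling)
  pred <- unscented_transform(sp, dynamics_fn)
  x_pred <- pred$mean
  P_pred <- pred$cov + process_noise_var
  P_pred <- (P_pred + t(P_pred)) / 2
  # re-draw sigma points from the predicted belief for the update stage
  sp2 <- ukf_sigma_points(gaussian_belief(x_pred, P_pred), scaling)
  X <- sp2$points
  np <- ncol(X)
  yhat_pts <- numeric(np)
  for (i in seq_len(np)) yhat_pts[i] <- observation_fn(X[, i])
  if (any(!is.finite(yhat_pts)))
    stop("observation function produced non-finite values", call. = FALSE)
  y_pred <- sum(sp2$mean_weights * yhat_pts)
  dy <- yhat_pts - y_pred
  P_yy <- sum(sp2$cov_weights * dy * dy)
  P_yy <- max(P_yy, 0)
  Dx <- X - x_pred
  P_xy <- drop(Dx %*% (sp2$cov_weights * dy))
  S <- P_yy + obs_noise_var
  if (S <= 0) S <- obs_noise_var
  K <- P_xy / S
  innovation <- observation - y_pred
  mean_post <- x_pred + K * innovation
  P_post <- P_pred - S * tcrossprod(K)
  P_post <- (P_post + t(P_post)) / 2
  out <- gaussian_belief(mean_post, P_post)
  attr(out, "diagnostics") <- list(
    innovation = innovation, predicted_obs = y_pred, obs_var = P_yy,
    gain_norm = sqrt(sum(K^2)),
    pred_trace = sum(diag(P_pred)), post_trace = sum(diag(P_post)))
  out
}
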