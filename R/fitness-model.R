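# Scalar fitness observation model: radial-basis expansion of the
# hidden expression state.

#' Construct a radial-basis fitness model
#'
#' The fitness of a strain is modelled as
#' \deqn{F(x) = \sum_{k=1}^K c_k \, \phi(\|x - m_k\|)}
#' with \eqn{\phi(r) = \sqrt{r^2 + h^2}} the Hardy multiquadric of shape
#' constant \eqn{h}. The centres \eqn{m_k} and \eqn{h} are fixed a priori;
#' the coefficients \eqn{c_k} are unknown and estimated jointly with the
#' regulation parameters during inference.
#'
#' @param centres K x n numeric matrix, one basis centre per row.
#' @param coefficients length-K numeric vector of basis coefficients
#'   \eqn{c_k}. May be `NA` for a model whose coefficients are yet to be
#'   inferred.
#' @param shape_const positive multiquadric shape constant \eqn{h}.
#' @param obs_noise_var positive variance of the additive Gaussian
#'   measurement noise on observed fitness.
#' @return An object of class `"rbf_fitness_model"`.
#' @export
rbf_fitness_model <- function(centres, coefficients, shape_const,
                              obs_noise_var) {
  centres <- as.matrix(centres)
  K <- nrow(centres)
  if (K < 1L) stop("at least one basis centre is required", call. = FALSE)
  if (length(coefficients) != K)
    stop("'coefficients' must have length ", K, call. = FALSE)
  if (!is.finite(shape_const) || shape_const <= 0)
    stop("'shape_const' must be a positive number", call. = FALSE)
  if (!is.finite(obs_noise_var) || obs_noise_var <= 0)
    stop("'obs_noise_var' must be a positive number", call. = FALSE)
  structure(
    list(n_bases = K,
         n_genes = ncol(centres),
         centres = unname(centres),
         coefficients = as.numeric(coefficients),
         shape_const = as.numeric(shape_const),
         obs_noise_var = as.numeric(obs_noise_var)),
    class = "rbf_fitness_model")
}

#' @export
print.rbf_fitness_model <- function(x, ...) {
  cat("RBF fitness model:", x$n_bases, "Hardy multiquadric bases over",
      x$n_genes, "genes, shape constant", x$shape_const, "\n")
  invisible(x)
}

#' Hardy multiquadric radial basis function
#'
#' \eqn{\phi(x; m, h) = \sqrt{\|x - m\|^2 + h^2}}. The value is at least `h`,
#' with equality exactly at the centre, and depends on `x` only through its
#' distance from `m`.
#'
#' @param x numeric vector.
#' @param centre numeric vector of the same length.
#' @param h positive shape constant.
#' @return A single non-negative number.
#' @examples
#' hardy_multiquadric(c(3, 4), c(0, 0), 1)  # sqrt(26)
#' @export
hardy_multiquadric <- function(x, centre, h) {
  if (length(x) != length(centre))
    stop("'x' and 'centre' must have the same length", call. = FALSE)
  if (!is.finite(h) || h <= 0) stop("'h' must be positive", call. = FALSE)
  sqrt(sum((x - centre)^2) + h^2)
}

# K-vector of basis evaluations at one state; the design row of the expansion
rbf_design <- function(state, centres, h) {
  d2 <- colSums((t(centres) - state)^2)
  sqrt(d2 + h^2)
}

#' Evaluate the fitness expansion at an expression state
#'
#' Deterministic value \eqn{\sum_k c_k \phi(\|x - m_k\|)}; observation noise
#' is added by the simulator, not here.
#'
#' @param state length-n numeric expression state.
#' @param model an [rbf_fitness_model()] with finite coefficients.
#' @return A single number.
#' @export
fitness_eval <- function(state, model) {
  stopifnot(inherits(model, "rbf_fitness_model"))
  if (length(state) != model$n_genes)
    stop("'state' must have length ", model$n_genes, call. = FALSE)
  if (any(!is.finite(model$coefficients)))
    stop("fitness model coefficients are not set", call. = FALSE)
  sum(model$coefficients *
        rbf_design(state, model$centres, model$shape_const))
}

#' Place basis centres along the diagonal of the data range
#'
#' Default a-priori centre placement when none is supplied: `K` points evenly
#' spaced along the main diagonal of the hypercube spanned by the observed
#' (or expected) expression range. Reproducible and scale-aware; an explicit
#' centre matrix can always be given instead.
#'
#' @param n_genes number of genes (centre dimension).
#' @param n_bases number of centres K.
#' @param range length-2 numeric range to span (default `c(0, 1)`).
#' @return K x n matrix of centres.
#' @export
diagonal_centres <- function(n_genes, n_bases, range = c(0, 1)) {
  stopifnot(n_bases >= 1, n_genes >= 1, length(range) == 2)
  t_k <- seq(range[1], range[2], length.out = n_bases)
  outer(t_k, rep(1, n_genes))
}
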