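# Discrete-time nonlinear gene-regulation dynamics with knockout masking.

#' Construct a gene network parameter set
#'
#' Bundles the parameters of the discrete-time regulation model
#' \deqn{x_i(t+1) = \sum_j a_{ij} x_j(t) + \sum_j b_{ij} f_j(x_j(t)) + I_i + w_i(t)}
#' where \eqn{a_{ij}} is the linear and \eqn{b_{ij}} the nonlinear (sigmoidal)
#' regulation coefficient from gene \eqn{j} to gene \eqn{i}, \eqn{f_j} is the
#' logistic basis with steepness \eqn{\mu_j} (see [sigmoid_basis()]),
#' \eqn{I_i} is the system expression bias and \eqn{w(t)} is zero-mean
#' Gaussian process noise.
#'
#' @param linear_coefs n x n numeric matrix; entry `[i, j]` is the linear
#'   effect of gene `j` on gene `i`.
#' @param nonlinear_coefs n x n numeric matrix of sigmoidal-term coefficients,
#'   same orientation.
#' @param sigmoid_params length-n vector of strictly positive sigmoid
#'   steepness parameters, one per source gene.
#' @param biases length-n vector of expression biases.
#' @param process_noise_var either a single non-negative scalar (expanded to
#'   a diagonal matrix) or an n x n symmetric positive semi-definite matrix.
#' @param genes optional character vector of gene labels; defaults to
#'   `"g1" ... "gn"`.
#'
#' @return An object of class `"gene_network_params"`.
#' @seealso [propagate_expression()], [apply_knockout()]
#' @export
gene_network_params <- function(linear_coefs, nonlinear_coefs, sigmoid_params,
                                biases, process_noise_var, genes = NULL) {
  linear_coefs <- as.matrix(linear_coefs)
  nonlinear_coefs <- as.matrix(nonlinear_coefs)
  n <- nrow(linear_coefs)
  if (ncol(linear_coefs) != n)
    stop("'linear_coefs' must be a square matrix", call. = FALSE)
  if (!identical(dim(nonlinear_coefs), dim(linear_coefs)))
    stop("'nonlinear_coefs' must match the dimensions of 'linear_coefs'",
         call. = FALSE)
  if (length(sigmoid_params) != n || any(!is.finite(sigmoid_params)) ||
      any(sigmoid_params <= 0))
    stop("'sigmoid_params' must be ", n, " strictly positive finite values",
         call. = FALSE)
  if (length(biases) != n || any(!is.finite(biases)))
    stop("'biases' must be ", n, " finite values", call. = FALSE)
  if (length(process_noise_var) == 1L) {
    if (process_noise_var < 0)
      stop("'process_noise_var' must be non-negative", call. = FALSE)
    process_noise_var <- diag(as.numeric(process_noise_var), n)
  }
  process_noise_var <- as.matrix(process_noise_var)
  if (!identical(dim(process_noise_var), c(n, n)))
    stop("'process_noise_var' must be scalar or ", n, " x ", n, call. = FALSE)
  if (max(abs(process_noise_var - t(process_noise_var))) > 1e-10)
    stop("'process_noise_var' must be symmetric", call. = FALSE)
  if (min(eigen(process_noise_var, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stop("'process_noise_var' must be positive semi-definite", call. = FALSE)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (length(genes) != n) stop("'genes' must have length ", n, call. = FALSE)
  structure(
    list(n_genes = n,
         linear_coefs = unname(linear_coefs),
         nonlinear_coefs = unname(nonlinear_coefs),
         sigmoid_params = as.numeric(sigmoid_params),
         biases = as.numeric(biases),
         process_noise_var = unname(process_noise_var),
         genes = as.character(genes)),
    class = "gene_network_params")
}

#' @export
print.gene_network_params <- function(x, ...) {
  n_lin <- sum(x$linear_coefs != 0)
  n_non <- sum(x$nonlinear_coefs != 0)
  cat("Gene network parameters:", x$n_genes, "genes,",
      n_lin, "linear and", n_non, "nonlinear coefficients set\n")
  invisible(x)
}

#' Sigmoidal regulation basis
#'
#' The logistic nonlinearity \eqn{f(x) = 1 / (1 + e^{-\mu x})} used for the
#' nonlinear regulation terms. The steepness \eqn{\mu} is a per-gene model
#' parameter estimated alongside the regulation coefficients.
#'
#' @param x numeric vector of expression levels (finite).
#' @param mu positive steepness parameter(s), recycled against `x`.
#' @return Values strictly inside (0, 1), increasing in `x`.
#' @examples
#' sigmoid_basis(0, 1)    # 0.5
#' sigmoid_basis(1, 1)    # 1 / (1 + exp(-1))
#' @export
sigmoid_basis <- function(x, mu) {
  if (any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be strictly positive and finite", call. = FALSE)
  1 / (1 + exp(-mu * x))
}

#' Remove a set of genes from the network parameters
#'
#' Models a deletion strain: every deleted gene neither regulates other genes
#' nor is itself expressed. For each deleted index `d`, column `d` (outgoing
#' influence) and row `d` (its own update, including its bias) of both
#' coefficient matrices are set to zero. The input object is not modified.
#'
#' @param params a [gene_network_params()] object.
#' @param deleted integer vector of gene indices to delete (may be empty;
#'   multi-gene knockouts are supported).
#' @return A new `"gene_network_params"` with the masked coefficients.
#' @export
apply_knockout <- function(params, deleted) {
  stopifnot(inherits(params, "gene_network_params"))
  deleted <- as.integer(deleted)
  if (length(deleted) == 0L) return(params)
  if (any(is.na(deleted)) || any(deleted < 1L) || any(deleted > params$n_genes))
    stop("knockout indices must lie in [1, ", params$n_genes, "]",
         call. = FALSE)
  out <- params
  out$linear_coefs[deleted, ] <- 0
  out$linear_coefs[, deleted] <- 0
  out$nonlinear_coefs[deleted, ] <- 0
  out$nonlinear_coefs[, deleted] <- 0
  out$biases[deleted] <- 0
  out
}

#' One step of the regulation dynamics
#'
#' Advances the expression state one discrete time step under the (possibly
#' knockout-masked) regulation model. Deleted genes are clamped to zero
#' expression and all terms involving them are removed.
#'
#' @param levels length-n numeric vector of current expression levels.
#' @param params a [gene_network_params()] object.
#' @param deleted integer vector of deleted gene indices (default none).
#' @param noise length-n process-noise realization (default zero). The map is
#'   exactly additive in this argument.
#' @return length-n numeric vector of next-step expression levels.
#' @export
propagate_expression <- function(levels, params, deleted = integer(0),
                                 noise = numeric(length(levels))) {
  stopifnot(inherits(params, "gene_network_params"))
  n <- params$n_genes
  if (length(levels) != n) stop("'levels' must have length ", n, call. = FALSE)
  if (length(noise) != n) stop("'noise' must have length ", n, call. = FALSE)
  if (any(!is.finite(levels))) stop("'levels' must be finite", call. = FALSE)
  masked <- apply_knockout(params, deleted)
  nxt <- drop(masked$linear_coefs %*% levels) +
    drop(masked$nonlinear_coefs %*%
           sigmoid_basis(levels, masked$sigmoid_params)) +
    masked$biases + noise
  nxt[as.integer(deleted)] <- 0
  nxt
}
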