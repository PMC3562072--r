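# Forward simulator: knockout fitness datasets with known ground truth.

#' Construct a knockout fitness dataset
#'
#' Container for a round-by-gene matrix of scalar fitness observations from
#' a single-knockout library: entry `(r, i)` is the fitness measured for the
#' strain with gene `i` deleted in experimental round `r`.
#'
#' @param values numeric matrix, rounds x genes; all entries finite.
#' @param genes character vector of gene labels (the deleted gene of each
#'   column's strain).
#' @param condition_labels optional labels for the rounds; defaults to
#'   `"round1" ...`.
#' @param provenance optional list recording seed and generator settings.
#' @return An object of class `"fitness_dataset"`.
#' @export
fitness_dataset <- function(values, genes = NULL, condition_labels = NULL,
                            provenance = list()) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("fitness values must all be finite", call. = FALSE)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  if (length(genes) != ncol(values))
    stop("'genes' must have one label per column", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate strain (gene) labels", call. = FALSE)
  if (is.null(condition_labels))
    condition_labels <- paste0("round", seq_len(nrow(values)))
  if (length(condition_labels) != nrow(values))
    stop("'condition_labels' must have one label per row", call. = FALSE)
  dimnames(values) <- list(condition_labels, genes)
  structure(
    list(values = values,
         genes = as.character(genes),
         condition_labels = as.character(condition_labels),
         n_genes = ncol(values),
         rounds = nrow(values),
         provenance = provenance),
    class = "fitness_dataset")
}

#' @export
print.fitness_dataset <- function(x, ...) {
  cat("Knockout fitness dataset:", x$rounds, "rounds x", x$n_genes,
      "strains\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Ground-truth typed edge set
#'
#' A directed regulatory link is counted separately for its linear and its
#' nonlinear (sigmoidal) component, so a network edge carrying both
#' contributes two typed edges.
#'
#' @param edges data frame with columns `source`, `target`, `type`
#'   (`"linear"` or `"nonlinear"`).
#' @param n_genes number of genes in the network.
#' @return An object of class `"grn_truth"`.
#' @export
grn_truth <- function(edges, n_genes) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "type") %in% names(edges)))
  edges$type <- as.character(edges$type)
  if (!all(edges$type %in% c("linear", "nonlinear")))
    stop("edge type must be 'linear' or 'nonlinear'", call. = FALSE)
  key <- paste(edges$source, edges$target, edges$type)
  if (anyDuplicated(key)) stop("duplicate typed edges", call. = FALSE)
  structure(list(typed_edges = edges[order(edges$source, edges$target,
                                           edges$type), , drop = FALSE],
                 n_genes = as.integer(n_genes)),
            class = "grn_truth")
}

# Typed edges implied by nonzero coefficients of a parameter set
truth_from_params <- function(params) {
  idx_l <- which(params$linear_coefs != 0, arr.ind = TRUE)
  idx_n <- which(params$nonlinear_coefs != 0, arr.ind = TRUE)
  edges <- rbind(
    if (nrow(idx_l)) data.frame(source = idx_l[, 2], target = idx_l[, 1],
                                type = "linear"),
    if (nrow(idx_n)) data.frame(source = idx_n[, 2], target = idx_n[, 1],
                                type = "nonlinear"))
  grn_truth(edges, params$n_genes)
}

#' The 5-gene reference benchmark network
#'
#' Loads the packaged 5-gene benchmark: six directed regulatory interactions
#' (2->1, 3->1, 3->2, 3->4, 3->5, 4->2), each carrying a linear coefficient
#' of 0.7 and a nonlinear coefficient of 0.5 (12 typed edges in total), a
#' sigmoid steepness of 1 and bias 0.2 per gene, process-noise variance
#' 0.01 per gene, and a 5-basis Hardy multiquadric fitness model read from
#' a packaged fixture (see
#' `system.file("extdata", "reference_fitness_model_synthetic.yaml",
#' package = "fitnessGRN")` for its provenance).
#'
#' @return A list with components `params` ([gene_network_params()]),
#'   `fitness_model` ([rbf_fitness_model()]), `truth` ([grn_truth()]) and
#'   `sim` (list of simulation protocol settings: `rounds`, `settle_steps`,
#'   `init_level`).
#' @export
reference_network <- function() {
  edge_path <- system.file("extdata", "reference_network_edges.tsv",
                           package = "fitnessGRN", mustWork = TRUE)
  cfg_path <- system.file("extdata", "reference_network_config_synthetic.yaml",
                          package = "fitnessGRN", mustWork = TRUE)
  rbf_path <- system.file("extdata", "reference_fitness_model_synthetic.yaml",
                          package = "fitnessGRN", mustWork = TRUE)
  cfg <- yaml::read_yaml(cfg_path)
  n <- cfg$n_genes
  edges <- utils::read.delim(edge_path)
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  A[cbind(edges$target, edges$source)] <- edges$linear_coef
  B[cbind(edges$target, edges$source)] <- edges$nonlinear_coef
  params <- gene_network_params(
    linear_coefs = A, nonlinear_coefs = B,
    sigmoid_params = cfg$sigmoid_params, biases = cfg$biases,
    process_noise_var = cfg$process_noise_var)
  fit <- read_rbf_yaml(rbf_path)
  list(params = params,
       fitness_model = fit,
       truth = truth_from_params(params),
       sim = list(rounds = cfg$rounds, settle_steps = cfg$settle_steps,
                  init_level = cfg$init_level))
}

#' Simulate a single-knockout fitness dataset
#'
#' For every round and every gene, deletes that gene ([apply_knockout()]),
#' propagates the masked dynamics `settle_steps` times from the initial
#' state with process noise drawn each step, and records the fitness of the
#' final state plus observation noise. The settling horizon emulates
#' stationary-phase measurement of a deletion strain within the
#' discrete-time model; `settle_steps = 1` gives the strict one-step
#' reading.
#'
#' @param params a [gene_network_params()] object (the true network).
#' @param fitness_model an [rbf_fitness_model()] with known coefficients.
#' @param rounds number of experimental rounds (replicate conditions).
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @param settle_steps number of propagation steps per strain (default 20).
#' @param init_level initial expression level for every gene (default 0.5).
#' @return A [fitness_dataset()] of dimension `rounds` x `n_genes`.
#' @export
simulate_knockout_dataset <- function(params, fitness_model, rounds = 10,
                                      seed = NULL, settle_steps = 20,
                                      init_level = 0.5) {
  stopifnot(inherits(params, "gene_network_params"),
            inherits(fitness_model, "rbf_fitness_model"),
            rounds >= 1, settle_steps >= 1)
  n <- params$n_genes
  if (!is.null(seed)) set.seed(seed)
  Qr <- psd_sqrt(params$process_noise_var)
  obs_sd <- sqrt(fitness_model$obs_noise_var)
  vals <- matrix(NA_real_, rounds, n)
  for (r in seq_len(rounds)) {
    for (d in seq_len(n)) {
      masked <- apply_knockout(params, d)
      x <- rep(init_level, n)
      x[d] <- 0
      for (s in seq_len(settle_steps)) {
        w <- drop(Qr %*% stats::rnorm(n))
        x <- propagate_expression(x, masked, deleted = d, noise = w)
      }
      vals[r, d] <- fitness_eval(x, fitness_model) +
        stats::rnorm(1, sd = obs_sd)
    }
  }
  fitness_dataset(vals, genes = params$genes,
                  provenance = list(seed = seed, rounds = rounds,
                                    settle_steps = settle_steps,
                                    init_level = init_level))
}

# symmetric PSD square root (for drawing correlated process noise)
psd_sqrt <- function(V) {
  if (max(abs(V)) == 0) return(V)
  e <- eigen(V, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}
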