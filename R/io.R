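# Tab-separated file formats: fitness matrices, edge lists, model fixtures.
# TSV, UTF-8, Unix newlines, '.' decimal; gene labels are free strings so
# real compendium exports (gene names, locus tags) load unchanged.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a knockout fitness matrix from TSV
#'
#' Expected layout: header row of condition/round labels, first column the
#' deleted-gene label of each strain (rows = strains, columns = rounds).
#' Every data cell must be numeric and finite; offending cells are reported
#' with their row and column.
#'
#' @param path path to the TSV file.
#' @return A [fitness_dataset()] (internally rounds x genes).
#' @export
read_fitness_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 2L)
    stop("fitness TSV needs a strain column plus at least one round",
         call. = FALSE)
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate strain labels: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric or missing fitness value at row %d (strain '%s'), column '%s'",
      bad[1, 1], genes[bad[1, 1]], colnames(raw)[-1L][bad[1, 2]]),
      call. = FALSE)
  fitness_dataset(t(num), genes = genes,
                  condition_labels = colnames(raw)[-1L],
                  provenance = list(path = path))
}

#' Write a knockout fitness matrix to TSV
#'
#' Inverse of [read_fitness_tsv()]; the round trip is bit-exact for finite
#' values.
#'
#' @param data a [fitness_dataset()].
#' @param path output path.
#' @export
write_fitness_tsv <- function(data, path) {
  stopifnot(inherits(data, "fitness_dataset"))
  M <- t(data$values)  # strains x rounds
  lines <- c(paste(c("gene", data$condition_labels), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(data$genes[i], fmt_num(M[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a typed edge list to TSV
#'
#' One row per typed edge, columns `source`, `target`, `type`, `estimate`,
#' deterministically ordered by source, then target, then type.
#'
#' @param network an `"inferred_network"` (see [threshold_network()]).
#' @param path output path.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "inferred_network"))
  e <- network$typed_edges
  e <- e[order(e$source, e$target, e$type), , drop = FALSE]
  lines <- c("source\ttarget\ttype\testimate",
             if (nrow(e)) vapply(seq_len(nrow(e)), function(i)
               paste(e$source[i], e$target[i], e$type[i],
                     fmt_num(e$estimate[i]), sep = "\t"), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a typed edge list from TSV
#'
#' @param path TSV with columns `source`, `target`, `type` and optionally
#'   `estimate`.
#' @return Data frame of typed edges.
#' @export
read_edges_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  e <- utils::read.delim(path)
  need <- c("source", "target", "type")
  if (!all(need %in% names(e)))
    stop("edge TSV must have columns source, target, type", call. = FALSE)
  e
}

#' Read a ground-truth edge list
#'
#' Accepts either a typed list (`source`, `target`, `type`) or an untyped
#' parameter list (`source`, `target`, `linear_coef`, `nonlinear_coef`)
#' whose nonzero coefficients are expanded into typed edges.
#'
#' @param path TSV path.
#' @param n_genes number of genes in the network (defaults to the largest
#'   index mentioned).
#' @return A [grn_truth()].
#' @export
read_truth_tsv <- function(path, n_genes = NULL) {
  e <- utils::read.delim(path)
  if ("type" %in% names(e)) {
    edges <- e[, c("source", "target", "type")]
  } else if (all(c("linear_coef", "nonlinear_coef") %in% names(e))) {
    edges <- rbind(
      data.frame(source = e$source, target = e$target,
                 type = "linear")[e$linear_coef != 0, ],
      data.frame(source = e$source, target = e$target,
                 type = "nonlinear")[e$nonlinear_coef != 0, ])
  } else {
    stop("truth TSV must have a 'type' column or coefficient columns",
         call. = FALSE)
  }
  if (is.null(n_genes))
    n_genes <- max(as.integer(edges$source), as.integer(edges$target))
  grn_truth(edges, n_genes)
}

#' Read an RBF fitness model from a YAML fixture
#'
#' The fixture lists `n_bases`, `shape_const`, `obs_noise_var`, `centres`
#' (K rows of n values) and `coefficients` (K values, may be omitted for an
#' inference-only basis).
#'
#' @param path YAML path.
#' @return An [rbf_fitness_model()].
#' @export
read_rbf_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  centres <- do.call(rbind, cfg$centres)
  if (nrow(centres) != cfg$n_bases)
    stop("fixture declares ", cfg$n_bases, " bases but lists ",
         nrow(centres), " centres", call. = FALSE)
  coefs <- if (is.null(cfg$coefficients)) rep(NA_real_, cfg$n_bases)
    else as.numeric(cfg$coefficients)
  rbf_fitness_model(centres, coefs, cfg$shape_const, cfg$obs_noise_var)
}
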