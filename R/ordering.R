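# Correlation-score heuristic for the order in which knockout samples are
# fed to the sequential filter: most connected (highest scoring) genes first.

#' Correlation score of each knockout strain
#'
#' For strain \eqn{i} the score is the sum over rounds of its within-round
#' cross-products with every other strain,
#' \deqn{S_i = \sum_{r} \sum_{j \ne i} y_{r,i}\, y_{r,j},}
#' a measure of how strongly the strain's fitness co-varies with the rest of
#' the library. Deleting a highly connected gene perturbs the whole network,
#' which is reflected in these correlations, so high-scoring strains carry
#' the most information and are fed to the filter first.
#'
#' @param data a [fitness_dataset()].
#' @param centred if `TRUE`, fitness values are centred per round (across
#'   strains) before the cross-products, giving a covariance-style score.
#'   Default `FALSE` (raw cross-products).
#' @return Named numeric vector of per-gene scores.
#' @export
correlation_score <- function(data, centred = FALSE) {
  stopifnot(inherits(data, "fitness_dataset"))
  Y <- data$values
  if (nrow(Y) < 1L || ncol(Y) < 1L) stop("empty dataset", call. = FALSE)
  if (centred) Y <- Y - rowMeans(Y)
  # per round: y_i * (row total - y_i); summed over rounds
  s <- colSums(Y * (rowSums(Y) - Y))
  names(s) <- data$genes
  s
}

#' Feeding order from per-gene scores
#'
#' Genes sorted by descending score; ties are broken by ascending gene
#' index, so the result is a deterministic permutation.
#'
#' @param scores finite numeric vector of per-gene scores.
#' @return An object of class `"feeding_order"`: list with `permutation`
#'   (integer gene indices, highest score first) and `scores`.
#' @export
feeding_order <- function(scores) {
  if (any(is.na(scores)) || any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  perm <- order(-scores, seq_along(scores))
  structure(list(permutation = perm, scores = scores),
            class = "feeding_order")
}

#' @export
print.feeding_order <- function(x, ...) {
  cat("Feeding order:", paste(x$permutation, collapse = ", "), "\n")
  invisible(x)
}
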