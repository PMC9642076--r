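## Over-representation analysis of a selected protein/gene set against
## annotation sets: exact hypergeometric upper-tail p-values with
## Benjamini-Hochberg FDR control. The background universe is always
## explicit (e.g. all proteins with a defined destabilization index), since
## the background choice dominates over-representation results.

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) where X counts annotated identifiers in a draw of `n` from a
#' universe of `N` containing `K` annotated, computed by exact summation of
#' hypergeometric point masses (no normal approximation).
#'
#' @param N universe size.
#' @param K number of annotated identifiers in the universe.
#' @param n number of selected identifiers.
#' @param x observed overlap, `0 <= x <= min(K, n)`.
#' @return the upper-tail probability, a number in (0, 1\].
#' @examples
#' hypergeomPValue(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeomPValue <- function(N, K, n, x) {
  if (any(c(N, K, n, x) != round(c(N, K, n, x))) ||
      K > N || n > N || K < 0 || n < 0 || N < 0 ||
      x < 0 || x > min(K, n)) {
    stop("need integers with 0 <= x <= min(K, n) and K, n <= N")
  }
  if (x == 0) return(1)
  sum(stats::dhyper(seq.int(x, min(K, n)), K, N - K, n))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in the
#' p-value ordering; the result is returned in the input order (the
#' adjustment itself is order-invariant).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as the input.
#' @export
bhAdjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation of a selected set across annotation sets
#'
#' Tests each annotation set for enrichment in the selection by the
#' hypergeometric upper tail over the collection's explicit universe.
#' Annotation sets are intersected with the universe on construction of the
#' [GeneSetCollection-class]; sets with fewer than `min_set_size` members
#' after intersection are dropped as uninformative. By default only sets
#' overlapping the selection (x >= 1) are reported; q-values come from
#' [bhAdjust()] over the reported sets.
#'
#' @param selected character vector of selected identifiers; must be a
#'   non-empty subset of the universe.
#' @param sets a [GeneSetCollection-class].
#' @param min_set_size smallest annotated count K retained; default 2.
#' @param include_zero report sets with zero overlap too (default FALSE).
#' @return data.frame sorted by ascending p (ties by set name) with columns
#'   `set_name`, `universe_size`, `annotated`, `selected`, `overlap`,
#'   `expected`, `p_value`, `q_value`.
#' @export
enrichSets <- function(selected, sets, min_set_size = 2L,
                       include_zero = FALSE) {
  stopifnot(is(sets, "GeneSetCollection"))
  universe <- geneUniverse(sets)
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) stop("empty selection")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0L) {
    stop(sprintf("selected identifier(s) outside the universe: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(selected)
  keep <- vapply(geneSets(sets), length, integer(1)) >= min_set_size
  anno <- geneSets(sets)[keep]
  if (length(anno) == 0L) {
    return(data.frame(set_name = character(0), universe_size = integer(0),
                      annotated = integer(0), selected = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  K <- vapply(anno, length, integer(1))
  x <- vapply(anno, function(s) sum(selected %in% s), integer(1))
  res <- data.frame(
    set_name = names(anno),
    universe_size = N,
    annotated = as.integer(K),
    selected = n,
    overlap = as.integer(x),
    expected = n * K / N,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!include_zero) res <- res[res$overlap >= 1L, , drop = FALSE]
  res$p_value <- vapply(seq_len(nrow(res)), function(i)
    hypergeomPValue(N, res$annotated[i], n, res$overlap[i]), numeric(1))
  res$q_value <- bhAdjust(res$p_value)
  res[order(res$p_value, res$set_name, method = "radix"), , drop = FALSE]
}
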