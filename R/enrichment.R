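#' Over-representation analysis against a gene-set collection
#'
#' Upper-tail hypergeometric test per set: with a universe of size N, a
#' set holding K universe genes and a query of size n, the p-value is
#' `P(X >= k)` for the observed overlap k. Bonferroni correction across
#' the tested sets; a set is significant when `adj_p <= alpha`. Query
#' genes outside the universe are dropped with a warning, and every set
#' is intersected with the universe before testing. The natural universe
#' is the intersected gene list of the analysis, not the whole genome.
#'
#' @param query Character vector of query genes.
#' @param universe Character vector of background genes.
#' @param collection Gene-set collection from [read_gmt()] (or any list
#'   with a `sets` element).
#' @param alpha Experiment-wide significance level (default 0.05).
#' @return `data.frame` sorted by `adj_p`: `set`, `set_size`, `overlap`,
#'   `p`, `adj_p`, `significant`.
#' @export
ora <- function(query, universe, collection, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty after universe filtering")
  sets <- lapply(collection$sets, intersect, universe)
  n_tested <- length(sets)
  res <- data.frame(set = names(sets),
                    set_size = lengths(sets),
                    overlap = vapply(sets, function(s)
                      length(intersect(s, query)), integer(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  # P(X >= k), hypergeometric with |set| successes among |universe|
  res$p <- stats::phyper(res$overlap - 1L, res$set_size,
                         length(universe) - res$set_size, length(query),
                         lower.tail = FALSE)
  res$adj_p <- pmin(1, res$p * n_tested)
  res$significant <- res$adj_p <= alpha
  res[order(res$adj_p, res$p, res$set), , drop = FALSE]
}
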