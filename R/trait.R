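#' Gene significance: absolute correlation with the binary trait
#'
#' `GS = |cor(trait, expression)|` per gene, with the trait encoded 0/1
#' (any affine encoding gives the same absolute correlation). Constant
#' genes get GS 0 with a warning.
#'
#' @param ds An [expression_dataset()] with both phenotype classes.
#' @return Named numeric vector in \[0, 1\].
#' @export
gene_significance <- function(ds) {
  if (length(unique(ds$phenotype)) < 2L)
    stop("phenotype must contain both classes")
  sds <- apply(ds$values, 1L, stats::sd)
  gs <- numeric(length(ds$genes))
  names(gs) <- ds$genes
  if (any(sds == 0))
    warning(sprintf("%d constant gene(s); gene significance set to 0",
                    sum(sds == 0)))
  ok <- sds > 0
  gs[ok] <- abs(as.numeric(stats::cor(t(ds$values[ok, , drop = FALSE]),
                                      ds$phenotype)))
  gs
}

#' Intramodular connectivity: weighted degree within the own module
#'
#' `GC_i = sum_{j in module(i), j != i} a_ij`; unassigned genes are
#' scored against the unassigned set.
#'
#' @param adj A [gene_matrix()] with role `adjacency`.
#' @param partition A [module_partition()] over the same genes.
#' @return Named numeric vector of intramodular connectivities (>= 0).
#' @export
gene_connectivity <- function(adj, partition) {
  if (!identical(adj$genes, partition$genes))
    stop("adjacency and partition must cover the same genes")
  gc <- numeric(length(adj$genes))
  names(gc) <- adj$genes
  for (m in unique(partition$labels)) {
    idx <- partition$labels == m
    block <- adj$values[idx, idx, drop = FALSE]
    gc[idx] <- rowSums(block) - diag(block)
  }
  gc
}

#' Cross-tissue consensus gene scores
#'
#' Per gene, the median across tissues of gene significance and of
#' intramodular connectivity (separately); with an even number of
#' tissues the median is the midpoint of the two central values.
#'
#' @param gs_tables Named list tissue -> named GS vector.
#' @param gc_tables Named list tissue -> named GC vector (same genes).
#' @param partition A [module_partition()] over those genes.
#' @param meta_assignment Optional named vector module id (character) ->
#'   meta-module id; adds a `meta_module` column (0 for unassigned).
#' @return `data.frame` of class `gene_score_table`: `gene`, per-tissue
#'   columns, `gs_consensus`, `gc_consensus`, `module`, `meta_module`.
#' @export
consensus_scores <- function(gs_tables, gc_tables, partition,
                             meta_assignment = NULL) {
  if (!length(gs_tables)) stop("need at least one tissue")
  genes <- partition$genes
  gs_mat <- vapply(gs_tables, function(v) v[genes], numeric(length(genes)))
  gc_mat <- vapply(gc_tables, function(v) v[genes], numeric(length(genes)))
  gs_mat <- matrix(gs_mat, nrow = length(genes))
  gc_mat <- matrix(gc_mat, nrow = length(genes))
  if (anyNA(gs_mat) || anyNA(gc_mat))
    stop("score tables do not cover all partition genes")
  out <- data.frame(gene = genes,
                    gs_consensus = apply(gs_mat, 1L, stats::median),
                    gc_consensus = apply(gc_mat, 1L, stats::median),
                    module = unname(partition$labels),
                    stringsAsFactors = FALSE)
  if (!is.null(meta_assignment)) {
    mm <- rep(0L, length(genes))
    assigned <- out$module != 0L
    mm[assigned] <- as.integer(meta_assignment[as.character(out$module[assigned])])
    out$meta_module <- mm
  }
  class(out) <- c("gene_score_table", class(out))
  out
}

#' Correlation between gene significance and intramodular connectivity
#'
#' Pearson correlation of the consensus GS and GC inside one module or
#' meta-module, with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom. A positive correlation says the module's
#' hub genes are its most trait-correlated genes, the signature of a
#' disease-associated module.
#'
#' @param table A `gene_score_table` from [consensus_scores()].
#' @param group Meta-module id (uses `meta_module` column when present,
#'   otherwise `module`).
#' @return List `r`, `p`, `n`, `degenerate` (TRUE when either score is
#'   constant, in which case `r = 0`).
#' @export
gs_gc_correlation <- function(table, group) {
  col <- if ("meta_module" %in% names(table)) "meta_module" else "module"
  sel <- table[[col]] == group
  n <- sum(sel)
  if (n < 3L) stop("group needs at least 3 genes")
  gs <- table$gs_consensus[sel]; gc <- table$gc_consensus[sel]
  if (stats::sd(gs) == 0 || stats::sd(gc) == 0)
    return(list(r = 0, p = 1, n = n, degenerate = TRUE))
  r <- stats::cor(gs, gc)
  tstat <- r * sqrt((n - 2L) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  list(r = r, p = p, n = n, degenerate = FALSE)
}
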