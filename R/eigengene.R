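#' Module eigengene: first principal component of a module's expression
#'
#' Member genes are standardized to zero mean and unit variance across
#' samples; the first right singular vector of the resulting gene x
#' sample matrix gives the per-sample eigengene scores, rescaled to unit
#' variance. The sign is fixed so the average correlation with the member
#' genes is positive (exact ties resolved towards a positive first
#' loading). `variance_explained` is the share of total variance carried
#' by the leading component.
#'
#' @param ds An [expression_dataset()].
#' @param member_genes Character vector of >= 2 genes present in `ds`.
#' @return List of class `eigengene`: `tissue`, `scores` (named by
#'   sample, unit variance), `variance_explained`, `orientation`.
#' @export
module_eigengene <- function(ds, member_genes) {
  missing <- setdiff(member_genes, ds$genes)
  if (length(missing))
    stop(sprintf("member gene(s) absent from dataset: %s",
                 paste(missing, collapse = ", ")))
  if (length(member_genes) < 2L) stop("need at least 2 member genes")
  x <- ds$values[member_genes, , drop = FALSE]
  x <- t(scale(t(x)))               # standardize each gene across samples
  if (anyNA(x)) stop("constant member gene; cannot standardize")
  sv <- svd(x)
  scores <- sv$v[, 1L]
  var_expl <- sv$d[1L]^2 / sum(sv$d^2)
  avg_cor <- mean(stats::cor(scores, t(x)))
  orientation <- if (abs(avg_cor) > 1e-10) sign(avg_cor)
                 else if (sv$u[1L, 1L] >= 0) 1 else -1
  scores <- scores * orientation
  scores <- scores / stats::sd(scores)
  names(scores) <- ds$samples
  structure(list(tissue = ds$tissue_name, scores = scores,
                 variance_explained = var_expl,
                 orientation = orientation),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("<eigengene> tissue '%s', %d samples, %.1f%% variance explained\n",
              x$tissue, length(x$scores), 100 * x$variance_explained))
  invisible(x)
}

#' Signed co-expression network over a set of eigengenes
#'
#' The signed adjacency at power 1: `0.5 + 0.5 * cor(score_i, score_j)`,
#' unit diagonal.
#'
#' @param eigengenes Named list of `eigengene` objects from one tissue,
#'   sharing sample ids.
#' @return A [gene_matrix()] with role `eigengene_adjacency`; node names
#'   are the list names.
#' @export
eigengene_network <- function(eigengenes) {
  if (is.null(names(eigengenes)) || any(!nzchar(names(eigengenes))))
    stop("`eigengenes` must be a named list")
  samples <- names(eigengenes[[1L]]$scores)
  scores <- vapply(eigengenes, function(e) {
    if (!identical(names(e$scores), samples))
      stop("eigengenes do not share sample ids")
    e$scores
  }, numeric(length(samples)))
  a <- 0.5 + 0.5 * stats::cor(scores)
  a[a < 0] <- 0; a[a > 1] <- 1
  diag(a) <- 1
  dimnames(a) <- list(names(eigengenes), names(eigengenes))
  gene_matrix(a, "eigengene_adjacency")
}

#' Dissimilarity of the minimum consensus of eigengene networks
#'
#' `1 - min across tissues` of the eigengene adjacencies: module pairs
#' are consensus-similar only when every tissue co-expresses their
#' eigengenes. A single network is allowed (degenerate consensus).
#'
#' @param networks List of [gene_matrix()] objects with role
#'   `eigengene_adjacency`, identical module lists.
#' @return A [gene_matrix()] with role `dissimilarity`.
#' @export
consensus_dissimilarity <- function(networks) {
  if (!length(networks)) stop("need at least one network")
  genes <- networks[[1L]]$genes
  for (m in networks)
    if (!identical(m$genes, genes)) stop("module lists do not match")
  cons <- Reduce(pmin, lapply(networks, `[[`, "values"))
  d <- 1 - cons
  diag(d) <- 0
  gene_matrix(d, "dissimilarity")
}

#' Group modules into meta-modules via MDS plus k-means
#'
#' Classical (Torgerson) metric MDS embeds the module dissimilarities in
#' `mds_dims` coordinates; k-means with `n_restarts` restarts (best
#' within-cluster sum of squares kept) groups the modules into `k`
#' meta-modules. Deterministic given the seed.
#'
#' @param discons A [gene_matrix()] with role `dissimilarity` over
#'   modules, e.g. from [consensus_dissimilarity()].
#' @param k Number of meta-modules (default 6).
#' @param mds_dims Embedding dimension (default 2).
#' @param seed Integer seed.
#' @param n_restarts k-means restarts (default 50).
#' @return Named integer vector: module -> meta-module id (1..k).
#' @export
meta_modules <- function(discons, k = 6L, mds_dims = 2L, seed = 1L,
                         n_restarts = 50L) {
  n <- length(discons$genes)
  if (k > n) stop("k exceeds the number of modules")
  if (k == n) {
    out <- seq_len(n); names(out) <- discons$genes
    return(out)
  }
  mds_dims <- min(mds_dims, n - 1L)
  coords <- stats::cmdscale(stats::as.dist(discons$values), k = mds_dims)
  set.seed(as.integer(seed))
  km <- stats::kmeans(coords, centers = k, nstart = n_restarts)
  # canonical labels: clusters numbered by first appearance
  relab <- integer(k)
  relab[unique(km$cluster)] <- seq_len(k)
  out <- relab[km$cluster]
  names(out) <- discons$genes
  out
}

#' Preservation network of two or more adjacency matrices
#'
#' `Preserv_ij = 1 - (max_ij - min_ij)` over the input networks; for two
#' networks this is `1 - |a1 - a2|`. Entries near 1 mean the edge weight
#' agrees across all networks.
#'
#' @param adjs List of >= 2 [gene_matrix()] objects with entries in
#'   \[0, 1\], same node lists.
#' @return A [gene_matrix()] with role `preservation`.
#' @export
preservation_network <- function(adjs) {
  if (length(adjs) < 2L) stop("need at least two networks")
  genes <- adjs[[1L]]$genes
  for (m in adjs)
    if (!identical(m$genes, genes)) stop("node lists do not match")
  vals <- lapply(adjs, `[[`, "values")
  pres <- 1 - (Reduce(pmax, vals) - Reduce(pmin, vals))
  gene_matrix(pres, "preservation", check_range = FALSE)
}

#' Scaled connectivity of the pairwise preservation network
#'
#' `C_i = 1 - sum_{j != i} |a1_ij - a2_ij| / (n - 1)`: per-node agreement
#' of two networks, 1 meaning identical neighbourhoods.
#'
#' @param a1,a2 [gene_matrix()] objects over the same >= 2 nodes.
#' @return Named numeric vector of per-node scaled connectivities.
#' @export
scaled_connectivity <- function(a1, a2) {
  if (!identical(a1$genes, a2$genes)) stop("node lists do not match")
  n <- length(a1$genes)
  if (n < 2L) stop("need at least two nodes")
  ad <- abs(a1$values - a2$values)
  diag(ad) <- 0
  ci <- 1 - rowSums(ad) / (n - 1L)
  names(ci) <- a1$genes
  ci
}

#' Density of the pairwise preservation network
#'
#' `D = 1 - sum_i sum_{j != i} |a1_ij - a2_ij| / (n (n - 1))`, which is
#' algebraically the mean of the scaled connectivities.
#'
#' @param a1,a2 [gene_matrix()] objects over the same >= 2 nodes.
#' @return Density in \[0, 1\] for inputs in \[0, 1\].
#' @export
preservation_density <- function(a1, a2) {
  mean(scaled_connectivity(a1, a2))
}

#' Differential eigengene network analysis of meta-modules across tissues
#'
#' For every tissue a meta-module eigengene is computed from the union of
#' its member genes and the meta-module adjacency (signed, power 1) is
#' formed; every unordered tissue pair is then compared through the
#' pairwise preservation network, its per-meta-module scaled connectivity
#' C and density D.
#'
#' @param datasets List of [expression_dataset()] sharing a gene list.
#' @param partition A [module_partition()] over those genes.
#' @param meta_assignment Named vector module id (as character) ->
#'   meta-module id, e.g. from [meta_modules()].
#' @return List of class `eigengene_preservation`: `adjacencies`
#'   (per-tissue meta-module adjacency), `pairs` (per tissue pair:
#'   `tissues`, `preservation` network, `scaled_connectivity`,
#'   `density`).
#' @export
differential_eigengene_analysis <- function(datasets, partition,
                                            meta_assignment) {
  mm_ids <- sort(unique(meta_assignment))
  mm_members <- lapply(mm_ids, function(mm) {
    mods <- as.integer(names(meta_assignment)[meta_assignment == mm])
    unlist(lapply(mods, module_genes, partition = partition))
  })
  names(mm_members) <- paste0("MM", mm_ids)

  adjacencies <- lapply(datasets, function(ds) {
    egs <- lapply(mm_members, function(genes) module_eigengene(ds, genes))
    eigengene_network(egs)
  })
  names(adjacencies) <- vapply(datasets, `[[`, character(1L), "tissue_name")

  tissues <- names(adjacencies)
  pairs <- list()
  if (length(tissues) >= 2L) {
    for (i in seq_len(length(tissues) - 1L)) {
      for (j in (i + 1L):length(tissues)) {
        a1 <- adjacencies[[i]]; a2 <- adjacencies[[j]]
        key <- paste(tissues[i], tissues[j], sep = " vs ")
        pairs[[key]] <- list(tissues = c(tissues[i], tissues[j]),
                             preservation = preservation_network(list(a1, a2)),
                             scaled_connectivity = scaled_connectivity(a1, a2),
                             density = preservation_density(a1, a2))
      }
    }
  }
  structure(list(adjacencies = adjacencies, pairs = pairs,
                 meta_members = mm_members),
            class = "eigengene_preservation")
}

#' @export
print.eigengene_preservation <- function(x, ...) {
  cat(sprintf("<eigengene_preservation> %d tissues, %d meta-modules\n",
              length(x$adjacencies), length(x$meta_members)))
  for (key in names(x$pairs))
    cat(sprintf("  %s: D = %.3f\n", key, x$pairs[[key]]$density))
  invisible(x)
}
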