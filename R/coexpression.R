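#' Signed weighted adjacency from pairwise correlation
#'
#' `A_ij = (0.5 + 0.5 * cor(x_i, x_j))^beta` with Pearson correlation
#' across samples, so perfectly anticorrelated genes get adjacency 0 and
#' perfectly correlated genes adjacency 1 at any power. The soft power
#' beta suppresses weak correlations while keeping the network weighted.
#'
#' @param ds An [expression_dataset()] with no constant gene.
#' @param beta Positive soft-thresholding power.
#' @return A [gene_matrix()] with role `adjacency` (unit diagonal).
#' @export
signed_adjacency <- function(ds, beta) {
  if (beta <= 0) stop("beta must be positive")
  sds <- apply(ds$values, 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant gene(s): %s",
                 paste(ds$genes[sds == 0], collapse = ", ")))
  a <- (0.5 + 0.5 * stats::cor(t(ds$values)))^beta
  a[a < 0] <- 0; a[a > 1] <- 1
  diag(a) <- 1
  gene_matrix(a, "adjacency")
}

#' Weighted connectivity of every gene
#'
#' The weighted degree `k_i = sum_{u != i} a_iu` (diagonal excluded).
#'
#' @param adj A [gene_matrix()] with role `adjacency`.
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  stopifnot(inherits(adj, "gene_matrix"))
  if (adj$role != "adjacency") stop("connectivity expects an adjacency matrix")
  k <- rowSums(adj$values) - diag(adj$values)
  names(k) <- adj$genes
  k
}

.scale_free_r2 <- function(k, n_bins = 10L) {
  # R^2 of log10(freq) ~ log10(mean k) over equal-width connectivity bins
  if (max(k) == min(k)) return(0)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  meank <- vapply(seq_len(n_bins), function(b) mean(k[as.integer(bin) == b]),
                  numeric(1L))
  ok <- freq > 0 & meank > 0
  if (sum(ok) < 2L) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(meank[ok]))
  summary(fit)$r.squared
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned into
#' `n_bins` equal-width bins and log10(frequency) is regressed on
#' log10(mean connectivity); the model fit R^2 measures how closely the
#' network approaches a scale-free degree distribution. The chosen beta
#' is the smallest candidate reaching `r2_min`, or, if none does, the
#' candidate with the largest R^2 (flagged via `reached_threshold`).
#'
#' @param ds An [expression_dataset()] with at least 50 genes.
#' @param candidates Candidate powers (default 1:30).
#' @param r2_min Target model fit (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return List of class `scale_free_fit`: `beta`, `r_squared`,
#'   `mean_connectivity`, `reached_threshold`, and the per-candidate
#'   `table` (columns beta, r_squared, mean_k).
#' @export
pick_beta <- function(ds, candidates = 1:30, r2_min = 0.8, n_bins = 10L) {
  if (length(ds$genes) < 50L) stop("need at least 50 genes to fit topology")
  s <- 0.5 + 0.5 * stats::cor(t(ds$values))
  tab <- data.frame(beta = candidates, r_squared = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    a <- s^candidates[i]
    k <- rowSums(a) - diag(a)
    tab$r_squared[i] <- .scale_free_r2(k, n_bins)
    tab$mean_k[i] <- mean(k)
  }
  hit <- which(tab$r_squared >= r2_min)
  if (length(hit)) {
    pick <- hit[1L]; reached <- TRUE
  } else {
    pick <- which.max(tab$r_squared); reached <- FALSE
  }
  structure(list(beta = tab$beta[pick], r_squared = tab$r_squared[pick],
                 mean_connectivity = tab$mean_k[pick],
                 reached_threshold = reached, table = tab),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> beta = %g (R^2 = %.3f, mean k = %.2f)%s\n",
              x$beta, x$r_squared, x$mean_connectivity,
              if (x$reached_threshold) "" else " [threshold not reached]"))
  invisible(x)
}

#' Topological overlap matrix of a weighted adjacency
#'
#' `TOM_ij = (sum_u a_iu a_ju + a_ij) / (min(k_i, k_j) - a_ij + 1)` for
#' `i != j`, the sum running over shared neighbours `u` outside `{i, j}`,
#' with the weighted adjacency used throughout; diagonal 1. Gene pairs
#' that share many strong neighbours get high overlap even if their
#' direct link is modest.
#'
#' @param adj A [gene_matrix()] with role `adjacency`.
#' @return A [gene_matrix()] with role `tom`.
#' @export
tom <- function(adj) {
  stopifnot(inherits(adj, "gene_matrix"))
  if (adj$role != "adjacency") stop("tom expects an adjacency matrix")
  a <- adj$values
  diag(a) <- 0
  shared <- a %*% a           # (i,j): sum_u a_iu a_ju, u-terms at i and j vanish
  k <- rowSums(a)
  denom <- outer(k, k, pmin) - a + 1
  tm <- (shared + a) / denom
  diag(tm) <- 1
  tm[tm > 1] <- 1
  tm[tm < 0] <- 0
  gene_matrix(tm, "tom")
}

#' Dissimilarity transform of a TOM
#'
#' Elementwise `1 - TOM`, zero diagonal; this is the distance used for
#' module detection.
#'
#' @param t A [gene_matrix()] with role `tom` (or `consensus`, for a
#'   consensus of TOM similarities).
#' @return A [gene_matrix()] with role `dissimilarity`.
#' @export
tom_dissimilarity <- function(t) {
  stopifnot(inherits(t, "gene_matrix"))
  if (!t$role %in% c("tom", "consensus"))
    stop("tom_dissimilarity expects a tom or consensus matrix")
  d <- 1 - t$values
  diag(d) <- 0
  gene_matrix(d, "dissimilarity")
}

#' Elementwise consensus of several gene matrices
#'
#' Applies the chosen operator entry by entry across matrices sharing the
#' identical gene list. The default `min` on TOM similarities marks a
#' gene pair as consensus-co-expressed only when every tissue co-expresses
#' it; see [consensus_modules()] for the orientation used by the pipeline.
#'
#' @param matrices List of >= 2 [gene_matrix()] objects, identical gene
#'   lists and identical role.
#' @param operator `"min"` (default), `"median"`, `"mean"`, or
#'   `"quantile"` with probability `q`.
#' @param q Quantile probability when `operator = "quantile"`.
#' @return A [gene_matrix()] with role `consensus`.
#' @export
consensus_matrix <- function(matrices, operator = c("min", "median", "mean",
                                                    "quantile"), q = 0.1) {
  operator <- match.arg(operator)
  if (length(matrices) < 2L) stop("need at least two matrices")
  genes <- matrices[[1L]]$genes
  role <- matrices[[1L]]$role
  for (m in matrices) {
    if (!identical(m$genes, genes)) stop("gene lists do not match")
    if (!identical(m$role, role)) stop("matrix roles do not match")
  }
  vals <- lapply(matrices, `[[`, "values")
  cons <- switch(operator,
                 min = Reduce(pmin, vals),
                 mean = Reduce(`+`, vals) / length(vals),
                 median = ,
                 quantile = {
                   probs <- if (operator == "median") 0.5 else q
                   arr <- array(unlist(vals), dim = c(dim(vals[[1L]]),
                                                      length(vals)))
                   apply(arr, c(1L, 2L), stats::quantile, probs = probs,
                         names = FALSE)
                 })
  dimnames(cons) <- list(genes, genes)
  gene_matrix(cons, "consensus")
}

#' Detect modules by hybrid tree cut of a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity; branches
#' below `cut_height_fraction` times the maximum merge height are
#' candidate modules; candidates smaller than `min_module_size` are
#' dissolved into the unassigned pool. A partitioning-around-medoids
#' style stage then reassigns each unassigned gene to the module with the
#' smallest average dissimilarity to its members, provided that average
#' beats the gene's average dissimilarity to all assigned genes and lies
#' within the cut height (so genes far from every module stay grey).
#' Remaining genes keep the unassigned (grey) label 0. Modules are
#' relabelled 1, 2, ... by decreasing size; the procedure is
#' deterministic given its inputs.
#'
#' @param dissim A [gene_matrix()] with role `dissimilarity` (or
#'   `consensus` when the consensus was built on dissimilarities).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height_fraction Static cut as a fraction of the maximum
#'   merge height (default 0.995).
#' @param deep_split Reserved tuning knob of the hybrid cut, 0..4
#'   (default 2); retained for interface compatibility, the static cut
#'   used here does not consume it.
#' @return A [module_partition()].
#' @export
cluster_modules <- function(dissim, min_module_size = 30L,
                            cut_height_fraction = 0.995, deep_split = 2L) {
  stopifnot(inherits(dissim, "gene_matrix"))
  if (!dissim$role %in% c("dissimilarity", "consensus"))
    stop("cluster_modules expects a dissimilarity matrix")
  genes <- dissim$genes
  n <- length(genes)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(module_partition(genes, integer(n)))
  }
  d <- dissim$values
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cut_h <- cut_height_fraction * max(hc$height)
  raw <- stats::cutree(hc, h = cut_h)

  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(n)
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i

  # PAM-like reassignment of unassigned genes
  if (any(labels == 0L) && any(labels != 0L)) {
    assigned <- labels != 0L
    mods <- sort(unique(labels[assigned]))
    unidx <- which(!assigned)
    mean_to_mod <- vapply(mods, function(m)
      rowMeans(d[unidx, labels == m, drop = FALSE]), numeric(length(unidx)))
    mean_to_mod <- matrix(mean_to_mod, nrow = length(unidx))
    mean_to_all <- rowMeans(d[unidx, assigned, drop = FALSE])
    best <- apply(mean_to_mod, 1L, which.min)
    best_d <- mean_to_mod[cbind(seq_along(unidx), best)]
    # a gene joins its nearest module only if it beats the overall average
    # AND lies within the cut radius, so far-from-everything genes stay grey
    take <- best_d < mean_to_all & best_d <= cut_h
    labels[unidx[take]] <- mods[best[take]]
  }

  # relabel by decreasing size (ties: original label order)
  if (any(labels != 0L)) {
    sz <- table(labels[labels != 0L])
    ord <- as.integer(names(sort(sz, decreasing = TRUE)))
    relab <- integer(max(ord))
    relab[ord] <- seq_along(ord)
    labels[labels != 0L] <- relab[labels[labels != 0L]]
  }
  module_partition(genes, labels)
}

#' Consensus module detection across several tissues
#'
#' The full consensus co-expression workflow: one shared soft power is
#' chosen (the largest per-tissue pick, so the tissue with the worst
#' scale-free fit drives the choice), signed adjacencies and TOMs are
#' computed per tissue, the elementwise minimum of the TOM similarities
#' forms the consensus, and modules are cut from `1 - consensus`. Taking
#' the minimum on similarities keeps only gene pairs co-expressed in
#' every tissue; the `consensus_on_dissimilarity` flag instead applies the minimum to
#' the per-tissue dissimilarities (which marks pairs co-expressed in any
#' tissue) for comparison.
#'
#' @param datasets List of >= 2 [expression_dataset()] sharing a gene
#'   list (see [intersect_gene_sets()]).
#' @param beta Soft power; NULL (default) selects it via [pick_beta()].
#' @param min_module_size,cut_height_fraction,deep_split Passed to
#'   [cluster_modules()].
#' @param consensus_operator Operator for [consensus_matrix()].
#' @param consensus_on_dissimilarity Apply the consensus operator to dissimilarities
#'   instead of similarities (default FALSE).
#' @param r2_min,candidates Passed to [pick_beta()] when `beta` is NULL.
#' @return List of class `consensus_fit`: `partition`
#'   ([module_partition()]), `beta`, `fits` (per-tissue
#'   `scale_free_fit`, when selected), `consensus_dissim`
#'   ([gene_matrix()]), `toms` (per-tissue TOM list).
#' @export
consensus_modules <- function(datasets, beta = NULL, min_module_size = 30L,
                              cut_height_fraction = 0.995, deep_split = 2L,
                              consensus_operator = "min",
                              consensus_on_dissimilarity = FALSE,
                              r2_min = 0.8, candidates = 1:30) {
  if (length(datasets) < 2L) stop("need at least two tissues")
  genes <- datasets[[1L]]$genes
  for (ds in datasets)
    if (!identical(ds$genes, genes))
      stop("datasets must share an identical gene list; run intersect_gene_sets()")
  fits <- NULL
  if (is.null(beta)) {
    fits <- lapply(datasets, pick_beta, candidates = candidates,
                   r2_min = r2_min)
    beta <- max(vapply(fits, `[[`, numeric(1L), "beta"))
  }
  toms <- lapply(datasets, function(ds) tom(signed_adjacency(ds, beta)))
  if (consensus_on_dissimilarity) {
    diss <- lapply(toms, tom_dissimilarity)
    cons <- consensus_matrix(diss, operator = consensus_operator)
    cons_diss <- gene_matrix(cons$values, "consensus")
  } else {
    cons <- consensus_matrix(toms, operator = consensus_operator)
    d <- 1 - cons$values
    diag(d) <- 0
    cons_diss <- gene_matrix(d, "dissimilarity")
  }
  partition <- cluster_modules(cons_diss, min_module_size,
                               cut_height_fraction, deep_split)
  structure(list(partition = partition, beta = beta, fits = fits,
                 consensus_dissim = cons_diss, toms = toms),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf("<consensus_fit> beta = %g\n", x$beta))
  print(x$partition)
  invisible(x)
}
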