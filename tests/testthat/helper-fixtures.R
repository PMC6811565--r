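# Shared fixtures and independent oracles, all built in code.

# deterministic small expression dataset
make_tiny_ds <- function(n_genes = 6, n_samples = 8, seed = 101) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  pheno <- c(rep(0L, floor(n_samples / 2)), rep(1L, ceiling(n_samples / 2)))
  expression_dataset(x, pheno, "tiny")
}

# interactome that is a simple path n1 - n2 - ... - nn
make_path_interactome <- function(n = 6) {
  nm <- paste0("n", seq_len(n) - 1L)
  interactome_from_edges(nm[-n], nm[-1L])
}

# adjacency gene_matrix from an explicit symmetric matrix
make_adjacency <- function(a) {
  diag(a) <- 1
  gene_matrix(a, "adjacency")
}

# random adjacency with entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  make_adjacency(a)
}

# Oracle: triple-loop topological overlap
tom_brute_force <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[j, u]
    out[i, j] <- num / (min(k[i], k[j]) - a[i, j] + 1)
  }
  dimnames(out) <- dimnames(a)
  out
}

# Oracle: Benjamini-Hochberg step-up, written from the definition
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Oracle: breadth-first shortest-path distances from one source,
# written against the raw edge list (independent of igraph's solver)
bfs_dist_oracle <- function(edges, nodes, source) {
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
    adj[[edges[r, 2L]]] <- c(adj[[edges[r, 2L]]], edges[r, 1L])
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

# best-match Jaccard of a planted gene set against a detected partition
best_jaccard <- function(planted, partition) {
  labs <- setdiff(unique(partition$labels), 0L)
  if (!length(labs)) return(0)
  max(vapply(labs, function(b) {
    det <- module_genes(partition, b)
    length(intersect(planted, det)) / length(union(planted, det))
  }, numeric(1L)))
}
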