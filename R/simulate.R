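#' Simulate multi-tissue expression data with planted consensus modules
#'
#' Each planted module is a single-factor model: per tissue t and module m
#' a latent factor f is drawn per sample (standard normal), and gene g of
#' module m has expression `u_g * f + sqrt(1 - u_g^2) * noise`, so the
#' expected pairwise correlation inside a module is `u_g * u_g'`. Loadings
#' `u_g` are drawn once per gene, uniformly in
#' `[sqrt(within_cor) * 0.8, min(1, sqrt(within_cor) * 1.2)]`, and shared
#' across tissues, so module membership (and hub identity) is identical in
#' every tissue while the factors themselves are tissue-specific. For
#' disease modules the factor of class-1 samples is shifted by
#' `trait_shift`, which routes the trait effect through the latent factor:
#' high-loading (hub) genes become the most trait-correlated genes.
#' Background genes are pure standard-normal noise.
#'
#' @param n_tissues Number of tissues to simulate.
#' @param n_genes Total genes per tissue (planted plus background).
#' @param n_samples_per_class Samples per phenotype class per tissue.
#' @param module_sizes Integer vector of planted module sizes (each >= 3,
#'   summing to at most `n_genes`).
#' @param within_cor Target within-module correlation in (0, 1).
#' @param trait_shift Shift added to the latent factor of disease modules
#'   in class-1 samples (0 disables the disease signal).
#' @param disease_modules Indices (into `module_sizes`) of the modules
#'   that carry the trait shift; default the first module.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (module membership per gene with 0 = background, the disease
#'   module ids, and per-gene loadings `hub_strength`).
#' @export
simulate_multitissue <- function(n_tissues = 4, n_genes = 1000,
                                 n_samples_per_class = 20,
                                 module_sizes = c(50, 50, 50),
                                 within_cor = 0.6, trait_shift = 1,
                                 disease_modules = 1L, seed = 1L) {
  if (any(module_sizes < 3L)) stop("module sizes must be at least 3")
  if (sum(module_sizes) > n_genes)
    stop("module sizes exceed the number of genes")
  if (within_cor <= 0 || within_cor >= 1) stop("within_cor must lie in (0,1)")
  disease_modules <- as.integer(disease_modules)
  if (length(disease_modules) &&
      any(disease_modules < 1L | disease_modules > length(module_sizes)))
    stop("disease_modules out of range")
  set.seed(as.integer(seed))

  genes <- sprintf("g%05d", seq_len(n_genes))
  membership <- integer(n_genes)
  pos <- 1L
  for (m in seq_along(module_sizes)) {
    membership[pos:(pos + module_sizes[m] - 1L)] <- m
    pos <- pos + module_sizes[m]
  }
  names(membership) <- genes

  lo <- sqrt(within_cor) * 0.8
  hi <- min(1, sqrt(within_cor) * 1.2)
  u <- stats::runif(n_genes, lo, hi)
  u[membership == 0L] <- 0
  names(u) <- genes

  m_per_class <- as.integer(n_samples_per_class)
  n_samp <- 2L * m_per_class
  pheno <- rep(c(0L, 1L), each = m_per_class)

  datasets <- vector("list", n_tissues)
  for (t in seq_len(n_tissues)) {
    x <- matrix(stats::rnorm(n_genes * n_samp), n_genes, n_samp)
    for (m in seq_along(module_sizes)) {
      f <- stats::rnorm(n_samp)
      if (m %in% disease_modules) f <- f + trait_shift * pheno
      idx <- which(membership == m)
      x[idx, ] <- u[idx] %o% f +
        sqrt(1 - u[idx]^2) * matrix(stats::rnorm(length(idx) * n_samp),
                                    length(idx), n_samp)
    }
    dimnames(x) <- list(genes, sprintf("t%d_s%02d", t, seq_len(n_samp)))
    datasets[[t]] <- expression_dataset(x, pheno, sprintf("tissue%d", t))
  }

  truth <- list(module_membership = membership,
                disease_modules = disease_modules,
                hub_strength = u)
  list(datasets = datasets, truth = truth)
}

#' Simulate a scale-free interactome with a planted disease neighbourhood
#'
#' The graph grows by preferential attachment (Barabasi-Albert), giving
#' the heavy-tailed degree distribution typical of protein interaction
#' networks. The planted disease neighbourhood is a breadth-first ball
#' grown around a random high-degree node and truncated to
#' `neighborhood_size`, hence connected by construction.
#'
#' @param n_nodes Number of proteins.
#' @param edges_per_node Edges added per new node during growth.
#' @param neighborhood_size Size of the planted disease neighbourhood
#'   (must be at most `n_nodes / 2`).
#' @param seed Integer seed.
#' @return List with `interactome` (class `interactome`) and `truth`
#'   (element `disease_neighborhood`, a character vector of node names).
#' @export
simulate_interactome <- function(n_nodes = 5000, edges_per_node = 3,
                                 neighborhood_size = 25, seed = 1L) {
  if (neighborhood_size >= n_nodes) stop("neighborhood_size must be < n_nodes")
  if (n_nodes < neighborhood_size * 2L)
    stop("n_nodes must be at least twice neighborhood_size")
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("p%05d", seq_len(n_nodes))
  net <- structure(list(graph = g, restricted_to_lcc = TRUE),
                   class = "interactome")

  deg <- igraph::degree(g)
  top <- which(deg >= stats::quantile(deg, 0.95))
  root <- sample(top, 1L)
  order_ <- igraph::bfs(g, root = root, order = TRUE)$order
  neigh <- igraph::V(g)$name[as.integer(order_)[seq_len(neighborhood_size)]]

  list(interactome = net,
       truth = list(disease_neighborhood = neigh))
}

#' Simulate drug-target sets at controlled distance from the disease
#' neighbourhood
#'
#' Proximal drugs draw their targets from the planted disease
#' neighbourhood plus its direct neighbours; distal drugs draw targets
#' from nodes at shortest-path distance >= 3 from the neighbourhood
#' (falling back to a uniform draw with a warning if too few such nodes
#' exist).
#'
#' @param interactome An `interactome`.
#' @param truth Truth list from [simulate_interactome()] (needs
#'   `disease_neighborhood`).
#' @param n_proximal,n_distal Number of drugs per class.
#' @param targets_per_drug Targets per drug (> 0); the interactome must
#'   have at least 10x as many nodes.
#' @param seed Integer seed.
#' @return List with `drugs` (list of [drug_record()]) and `drug_class`
#'   (named character vector, "proximal"/"distal").
#' @export
simulate_drugs <- function(interactome, truth, n_proximal = 20,
                           n_distal = 20, targets_per_drug = 4, seed = 1L) {
  if (targets_per_drug < 1L) stop("targets_per_drug must be positive")
  g <- interactome$graph
  if (igraph::vcount(g) < 10L * targets_per_drug)
    stop("interactome too small for the requested targets_per_drug")
  set.seed(as.integer(seed))
  neigh <- truth$disease_neighborhood
  d_to_neigh <- apply(igraph::distances(g, v = neigh), 2L, min)
  names(d_to_neigh) <- igraph::V(g)$name
  prox_pool <- names(d_to_neigh)[d_to_neigh <= 1]
  dist_pool <- names(d_to_neigh)[d_to_neigh >= 3]
  if (length(dist_pool) < targets_per_drug) {
    warning("too few nodes at distance >= 3; distal targets drawn uniformly")
    dist_pool <- igraph::V(g)$name
  }
  drugs <- vector("list", n_proximal + n_distal)
  cls <- character(n_proximal + n_distal)
  for (i in seq_len(n_proximal)) {
    drugs[[i]] <- drug_record(sprintf("PROX%03d", i), sprintf("proximal-%d", i),
                              sample(prox_pool, targets_per_drug))
    cls[i] <- "proximal"
  }
  for (i in seq_len(n_distal)) {
    j <- n_proximal + i
    drugs[[j]] <- drug_record(sprintf("DIST%03d", i), sprintf("distal-%d", i),
                              sample(dist_pool, targets_per_drug))
    cls[j] <- "distal"
  }
  names(cls) <- vapply(drugs, `[[`, character(1L), "drug_id")
  list(drugs = drugs, drug_class = cls)
}
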