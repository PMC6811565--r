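#' Extract a disease signature by joint GS/GC quantile thresholds
#'
#' Within the chosen meta-module, genes passing the `quantile` cut on
#' BOTH consensus gene significance and consensus intramodular
#' connectivity (quantiles computed within the meta-module, linear
#' interpolation) form the requested signature; the mapped signature is
#' its intersection with the interactome nodes, and downstream analyses
#' use only the mapped part.
#'
#' @param table A `gene_score_table` from [consensus_scores()] (needs a
#'   `meta_module` column).
#' @param meta_module Meta-module id.
#' @param interactome An `interactome`.
#' @param quantile Joint quantile threshold (default 0.8).
#' @return List of class `signature`: `requested`, `mapped`,
#'   `provenance`.
#' @export
disease_signature <- function(table, meta_module, interactome,
                              quantile = 0.8) {
  if (!"meta_module" %in% names(table))
    stop("score table lacks a meta_module column")
  sel <- table$meta_module == meta_module
  if (!any(sel)) stop("meta-module is empty")
  gs <- table$gs_consensus[sel]; gc <- table$gc_consensus[sel]
  qs <- stats::quantile(gs, quantile, names = FALSE)
  qc <- stats::quantile(gc, quantile, names = FALSE)
  requested <- table$gene[sel][gs >= qs & gc >= qc]
  mapped <- intersect(requested, interactome_nodes(interactome))
  if (length(mapped) < 2L)
    stop(sprintf("signature maps to %d interactome node(s); need >= 2",
                 length(mapped)))
  structure(list(requested = requested, mapped = mapped,
                 provenance = sprintf("meta-module %s, %d%% quantile",
                                      meta_module, round(100 * quantile))),
            class = "signature")
}

#' Build a signature directly from a gene set
#'
#' @param genes Requested gene symbols.
#' @param interactome An `interactome` the genes are mapped onto.
#' @param provenance Free-text origin note.
#' @return A `signature` (see [disease_signature()]).
#' @export
signature_from_genes <- function(genes, interactome,
                                 provenance = "user-supplied") {
  mapped <- intersect(unique(genes), interactome_nodes(interactome))
  if (length(mapped) < 2L)
    stop("signature maps to fewer than 2 interactome nodes")
  structure(list(requested = unique(genes), mapped = mapped,
                 provenance = provenance),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %s: %d requested, %d mapped\n",
              x$provenance, length(x$requested), length(x$mapped)))
  invisible(x)
}

#' Size of the largest connected component induced by a signature
#'
#' The module size S: the largest number of signature proteins directly
#' connected to each other inside the interactome (induced-subgraph
#' semantics: paths through non-signature proteins do not count).
#'
#' @param g An `interactome`.
#' @param sig A `signature`.
#' @return Integer component size (1 if no two signature nodes are
#'   adjacent).
#' @export
lcc_size <- function(g, sig) {
  if (!length(sig$mapped)) stop("signature has no mapped nodes")
  sub <- igraph::induced_subgraph(g$graph, sig$mapped)
  max(igraph::components(sub)$csize)
}

.col_mins <- function(dm) {
  out <- dm[1L, ]
  if (nrow(dm) > 1L)
    for (r in 2L:nrow(dm)) out <- pmin(out, dm[r, ])
  out
}

.mean_nearest_within <- function(graph, nodes) {
  dm <- igraph::distances(graph, v = nodes, to = nodes)
  diag(dm) <- Inf
  nearest <- apply(dm, 1L, min)
  reachable <- is.finite(nearest)
  if (!any(reachable)) stop("no signature protein can reach another")
  if (!all(reachable))
    message(sprintf("%d protein(s) with no reachable partner excluded",
                    sum(!reachable)))
  mean(nearest[reachable])
}

#' Mean distance to the nearest other signature protein
#'
#' For each mapped signature protein, the unweighted shortest-path
#' distance to the closest OTHER signature protein; the statistic is the
#' mean over proteins (unreachable proteins excluded with a note).
#'
#' @param g An `interactome`.
#' @param sig A `signature` with >= 2 mapped nodes.
#' @return Mean nearest-neighbour distance (>= 1 unless duplicated).
#' @export
mean_shortest_distance_ds <- function(g, sig) {
  if (length(sig$mapped) < 2L) stop("need at least 2 mapped proteins")
  .mean_nearest_within(g$graph, sig$mapped)
}

# Degree bins: nodes sorted by degree, adjacent degree values merged until
# every bin holds >= min_bin_size nodes (last bin absorbs the remainder).
.degree_bins <- function(g, min_bin_size = 100L) {
  deg <- igraph::degree(g$graph)
  nm <- igraph::V(g$graph)$name
  ord <- order(deg)
  bins <- list()
  start <- 1L
  n <- length(deg)
  while (start <= n) {
    end <- min(n, start + min_bin_size - 1L)
    # extend so equal degrees never straddle a bin boundary
    while (end < n && deg[ord[end + 1L]] == deg[ord[end]]) end <- end + 1L
    bins[[length(bins) + 1L]] <- ord[start:end]
    start <- end + 1L
  }
  if (length(bins) > 1L &&
      length(bins[[length(bins)]]) < min_bin_size) {
    last <- bins[[length(bins)]]
    bins[[length(bins)]] <- NULL
    bins[[length(bins)]] <- c(bins[[length(bins)]], last)
  }
  node_bin <- integer(n)
  for (b in seq_along(bins)) node_bin[bins[[b]]] <- b
  names(node_bin) <- nm
  list(members = lapply(bins, function(i) nm[i]), node_bin = node_bin)
}

# One degree-matched draw given a precomputed binning; reference is a
# character vector of node names, the result has the same length.
.sample_from_bins <- function(bins, reference) {
  counts <- tabulate(bins$node_bin[reference], nbins = length(bins$members))
  out <- character(0)
  for (b in which(counts > 0L)) {
    pool <- bins$members[[b]]
    need <- counts[b]
    if (need > length(pool)) {  # exhausted bin: widen to neighbours
      warning("degree bin exhausted; widening to neighbouring bin")
      pool <- unique(c(pool, unlist(bins$members[max(1L, b - 1L):
                                                   min(length(bins$members),
                                                       b + 1L)])))
    }
    out <- c(out, if (need == length(pool)) pool
             else sample(pool, need))
  }
  out
}

#' Degree-preserving random node sample
#'
#' Nodes are binned by degree in increasing order, merging adjacent bins
#' until each holds at least `min_bin_size` nodes; each reference node is
#' then replaced by a uniform draw without replacement from its bin. The
#' returned set has `length(reference)` distinct nodes whose degree
#' profile matches the reference up to bin resolution (with
#' `min_bin_size = 1` the degree multiset is preserved exactly).
#'
#' @param g An `interactome`.
#' @param reference Character vector of node names to match.
#' @param seed Integer seed.
#' @param min_bin_size Minimum nodes per degree bin (default 100).
#' @return Character vector of sampled node names.
#' @export
degree_preserving_sample <- function(g, reference, seed = 1L,
                                     min_bin_size = 100L) {
  nodes <- interactome_nodes(g)
  if (!all(reference %in% nodes)) stop("reference nodes not in interactome")
  if (length(reference) > length(nodes))
    stop("reference larger than the interactome")
  set.seed(as.integer(seed))
  bins <- .degree_bins(g, min_bin_size)
  .sample_from_bins(bins, reference)
}

#' Null distribution container
#'
#' @param samples Numeric vector of null statistics (length >= 2).
#' @param statistic Name of the statistic.
#' @param seed Seed used to generate the samples (bookkeeping).
#' @return List of class `null_distribution`: `statistic`, `samples`,
#'   `mu`, `sigma` (population convention), `n_reps`, `seed`.
#' @export
null_distribution <- function(samples, statistic = "statistic", seed = NA) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("need at least 2 null samples for a standard deviation")
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  structure(list(statistic = statistic, samples = samples, mu = mu,
                 sigma = sigma, n_reps = length(samples), seed = seed),
            class = "null_distribution")
}

#' Standardize a statistic against its null distribution
#'
#' `z = (x - mu) / sigma` with the population-convention standard
#' deviation, plus the empirical p: the fraction of null samples at
#' least as extreme as `x` in the direction of the observed deviation.
#'
#' @param x Observed statistic.
#' @param null A [null_distribution()].
#' @return List `z`, `empirical_p`.
#' @export
zscore <- function(x, null) {
  if (null$sigma == 0) stop("null distribution has zero standard deviation")
  z <- (x - null$mu) / null$sigma
  p <- if (x >= null$mu) mean(null$samples >= x) else mean(null$samples <= x)
  list(z = z, empirical_p = p)
}

#' Agglomeration of a disease signature on the interactome
#'
#' Computes the module size S (largest connected signature component)
#' and the mean nearest-neighbour distance d_s of the mapped signature,
#' and standardizes both against degree-preserving random signatures of
#' the same size. An agglomerated (disease-like) signature has z(S) > 0
#' and z(d_s) < 0.
#'
#' @param g An `interactome`.
#' @param sig A `signature`.
#' @param n_reps Null repetitions (default 10000).
#' @param seed Integer seed.
#' @param min_bin_size Degree-bin size (default 100).
#' @return List of class `agglomeration`: `S`, `ds`, each holding
#'   `value`, `z`, `empirical_p`, `null`.
#' @export
signature_agglomeration <- function(g, sig, n_reps = 10000L, seed = 1L,
                                    min_bin_size = 100L) {
  if (n_reps < 2L) stop("need at least 2 null repetitions")
  s_obs <- lcc_size(g, sig)
  ds_obs <- mean_shortest_distance_ds(g, sig)
  set.seed(as.integer(seed))
  bins <- .degree_bins(g, min_bin_size)
  s_null <- numeric(n_reps); ds_null <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    samp <- .sample_from_bins(bins, sig$mapped)
    sub <- igraph::induced_subgraph(g$graph, samp)
    s_null[r] <- max(igraph::components(sub)$csize)
    ds_null[r] <- .mean_nearest_within(g$graph, samp)
  }
  s_stats <- zscore(s_obs, null_distribution(s_null, "S", seed))
  ds_stats <- zscore(ds_obs, null_distribution(ds_null, "d_s", seed))
  structure(list(S = c(list(value = s_obs), s_stats,
                       list(null = null_distribution(s_null, "S", seed))),
                 ds = c(list(value = ds_obs), ds_stats,
                        list(null = null_distribution(ds_null, "d_s", seed)))),
            class = "agglomeration")
}

#' @export
print.agglomeration <- function(x, ...) {
  cat(sprintf("<agglomeration> S = %d (z = %.2f), <d_s> = %.3f (z = %.2f)\n",
              x$S$value, x$S$z, x$ds$value, x$ds$z))
  invisible(x)
}

#' Closest-distance drug-disease proximity
#'
#' `<d_c>` is the mean over the drug's mapped targets of the
#' shortest-path distance to the nearest mapped disease protein; a
#' target that is itself a disease protein contributes 0. Unreachable
#' targets are excluded with a warning.
#'
#' @param g An `interactome`.
#' @param drug A [drug_record()].
#' @param sig A `signature`.
#' @return Mean closest distance (>= 0).
#' @export
drug_disease_proximity <- function(g, drug, sig) {
  mapped <- intersect(drug$targets, interactome_nodes(g))
  if (!length(mapped))
    stop(sprintf("drug '%s' has no targets in the interactome", drug$drug_id))
  dm <- igraph::distances(g$graph, v = sig$mapped, to = mapped)
  nearest <- .col_mins(dm)
  reachable <- is.finite(nearest)
  if (!any(reachable))
    stop(sprintf("all targets of drug '%s' unreachable", drug$drug_id))
  if (!all(reachable))
    warning(sprintf("%d unreachable target(s) of drug '%s' excluded",
                    sum(!reachable), drug$drug_id))
  mean(nearest[reachable])
}

#' Proximity screen of a drug catalogue against a disease signature
#'
#' For every drug the observed closest-distance proximity `<d_c>` is
#' standardized against a null in which BOTH the drug target set and the
#' disease signature are replaced by degree-preserving random node sets
#' of the same sizes (`n_reps` repetitions; within a repetition one
#' random signature is shared by all drugs). Drugs with no mapped
#' targets are excluded with a note.
#'
#' @param g An `interactome`.
#' @param drugs List of [drug_record()] objects.
#' @param sig A `signature`.
#' @param n_reps Null repetitions (default 1000).
#' @param seed Integer seed.
#' @param min_bin_size Degree-bin size (default 100).
#' @return `data.frame` of class `proximity_results`: `drug_id`, `name`,
#'   `d_c`, `z`, `empirical_p`, `n_mapped_targets`, `null_mu`,
#'   `null_sigma`.
#' @export
proximity_screen <- function(g, drugs, sig, n_reps = 1000L, seed = 1L,
                             min_bin_size = 100L) {
  if (n_reps < 2L) stop("need at least 2 null repetitions")
  nodes <- interactome_nodes(g)
  mapped_targets <- lapply(drugs, function(d) intersect(d$targets, nodes))
  keep <- lengths(mapped_targets) > 0L
  if (!all(keep))
    message(sprintf("%d drug(s) without mapped targets excluded",
                    sum(!keep)))
  drugs <- drugs[keep]
  mapped_targets <- mapped_targets[keep]
  if (!length(drugs)) stop("no drug has mapped targets")

  # observed: distance of every node to the nearest signature protein
  dm <- igraph::distances(g$graph, v = sig$mapped)
  dist_to_sig <- .col_mins(dm)
  names(dist_to_sig) <- nodes
  d_obs <- vapply(mapped_targets, function(tg) {
    d <- dist_to_sig[tg]
    mean(d[is.finite(d)])
  }, numeric(1L))

  set.seed(as.integer(seed))
  bins <- .degree_bins(g, min_bin_size)
  null_mat <- matrix(NA_real_, n_reps, length(drugs))
  for (r in seq_len(n_reps)) {
    sig_samp <- .sample_from_bins(bins, sig$mapped)
    dvec <- .col_mins(igraph::distances(g$graph, v = sig_samp))
    names(dvec) <- nodes
    for (j in seq_along(drugs)) {
      tg_samp <- .sample_from_bins(bins, mapped_targets[[j]])
      d <- dvec[tg_samp]
      null_mat[r, j] <- mean(d[is.finite(d)])
    }
  }
  res <- data.frame(drug_id = vapply(drugs, `[[`, character(1L), "drug_id"),
                    name = vapply(drugs, `[[`, character(1L), "name"),
                    d_c = unname(d_obs),
                    z = NA_real_, empirical_p = NA_real_,
                    n_mapped_targets = lengths(mapped_targets),
                    null_mu = NA_real_, null_sigma = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(drugs)) {
    nd <- null_distribution(null_mat[, j], "d_c", seed)
    zs <- zscore(d_obs[j], nd)
    res$z[j] <- zs$z
    res$empirical_p[j] <- zs$empirical_p
    res$null_mu[j] <- nd$mu
    res$null_sigma[j] <- nd$sigma
  }
  class(res) <- c("proximity_results", class(res))
  res
}

#' Rank screened drugs into top and bottom candidate lists
#'
#' Eligibility for the top list requires `d_c` at or below the
#' `dc_quantile` quantile of all screened proximities (or an absolute
#' cap when `dc_cap` is given); eligible drugs are sorted by z-score
#' ascending, ties broken by smaller `d_c` then by drug id. The bottom
#' list takes drugs with `d_c` at or above the `1 - dc_quantile`
#' quantile, also sorted by z ascending. The ranking is a total order,
#' independent of the input drug order.
#'
#' @param results A `proximity_results` data frame.
#' @param dc_quantile Proximity quantile for eligibility (default 0.05).
#' @param k List length (default 10; fewer returned with a warning when
#'   not enough drugs are eligible).
#' @param dc_cap Optional absolute `d_c` cap overriding the quantile.
#' @return List `top`, `bottom` (row subsets of `results` with a `rank`
#'   column), `dc_cutoff_low`, `dc_cutoff_high`.
#' @export
rank_drugs <- function(results, dc_quantile = 0.05, k = 10L, dc_cap = NULL) {
  if (nrow(results) < k)
    warning("fewer drugs than the requested list length")
  cut_low <- if (is.null(dc_cap))
    stats::quantile(results$d_c, dc_quantile, names = FALSE) else dc_cap
  cut_high <- stats::quantile(results$d_c, 1 - dc_quantile, names = FALSE)
  ord <- order(results$z, results$d_c, results$drug_id)
  sorted <- results[ord, , drop = FALSE]
  top <- sorted[sorted$d_c <= cut_low, , drop = FALSE]
  if (nrow(top) < k)
    warning(sprintf("only %d drug(s) eligible for the top list", nrow(top)))
  top <- utils::head(top, k)
  if (nrow(top)) top$rank <- seq_len(nrow(top))
  bottom <- sorted[sorted$d_c >= cut_high, , drop = FALSE]
  bottom <- utils::head(bottom, k)
  if (nrow(bottom)) bottom$rank <- seq_len(nrow(bottom))
  list(top = top, bottom = bottom,
       dc_cutoff_low = cut_low, dc_cutoff_high = cut_high)
}

#' Exact Fisher test of a 2x2 contingency table
#'
#' Full hypergeometric enumeration over all tables with the observed
#' margins: the two-sided p-value sums the probabilities of tables no
#' more probable than the observed one (with 1e-12 relative slack on the
#' comparison); the one-sided p-value is the upper tail of the top-left
#' cell.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise) of nonnegative
#'   counts with all margins positive.
#' @return List `p_two_sided`, `p_greater`.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, 2L,
                                         byrow = TRUE)
  if (any(table < 0)) stop("counts must be nonnegative")
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ])
  c1 <- sum(table[, 1L]); c2 <- sum(table[, 2L])
  if (min(r1, r2, c1, c2) == 0) stop("all margins must be positive")
  a_obs <- table[1L, 1L]
  a_range <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(a_obs, r1, r2, c1)
  list(p_two_sided = sum(pr[pr <= p_obs * (1 + 1e-12)]),
       p_greater = sum(pr[a_range >= a_obs]))
}

#' Validate ranked drug lists against external hit labels
#'
#' Builds the top-k and bottom-k lists from a proximity screen plus two
#' random-k control lists obtained by replacing the disease signature
#' with a degree-preserving random signature of the same size and
#' re-screening: one control takes the k drugs with the lowest `d_c`,
#' the other the k with the lowest z. Hit counts per list are compared
#' by exact Fisher tests: top-vs-random (2xk table) and
#' top-vs-catalogue, the latter using
#' `[[top hits, top misses], [catalogue-relevant, catalogue-rest]]`.
#'
#' @param g An `interactome`.
#' @param drugs List of [drug_record()] objects.
#' @param sig A `signature`.
#' @param hits Named logical vector drug_id -> externally curated hit.
#' @param results Optional precomputed `proximity_results` for `sig`
#'   (computed here when NULL).
#' @param n_reps Null repetitions for the screens (default 1000).
#' @param seed Integer seed.
#' @param k List length (default 10).
#' @param dc_quantile Eligibility quantile (default 0.05).
#' @param min_bin_size Degree-bin size (default 100).
#' @return List of class `validation_report`: `lists` (top, bottom,
#'   random_by_dc, random_by_z: drug ids), `hit_counts`,
#'   `fisher_top_vs_random_dc`, `fisher_top_vs_random_z`,
#'   `fisher_top_vs_catalogue`.
#' @export
validate_lists <- function(g, drugs, sig, hits, results = NULL,
                           n_reps = 1000L, seed = 1L, k = 10L,
                           dc_quantile = 0.05, min_bin_size = 100L) {
  if (is.null(results))
    results <- proximity_screen(g, drugs, sig, n_reps, seed, min_bin_size)
  ranked <- rank_drugs(results, dc_quantile, k)

  rand_sig_nodes <- degree_preserving_sample(g, sig$mapped,
                                             seed = as.integer(seed) + 101L,
                                             min_bin_size = min_bin_size)
  rand_sig <- signature_from_genes(rand_sig_nodes, g,
                                   provenance = "random degree-matched signature")
  rand_res <- proximity_screen(g, drugs, rand_sig, n_reps,
                               as.integer(seed) + 202L, min_bin_size)
  rand_by_dc <- rand_res[order(rand_res$d_c, rand_res$z,
                               rand_res$drug_id), ][seq_len(k), ]
  rand_by_z <- rand_res[order(rand_res$z, rand_res$d_c,
                              rand_res$drug_id), ][seq_len(k), ]

  # a table with a zero margin carries no contrast: report p = 1 rather
  # than propagating the strict-margin error of fisher_exact_2x2
  safe_fisher <- function(tab) {
    if (min(rowSums(tab), colSums(tab)) == 0)
      return(list(p_two_sided = 1, p_greater = 1))
    fisher_exact_2x2(tab)
  }
  lists <- list(top = ranked$top$drug_id, bottom = ranked$bottom$drug_id,
                random_by_dc = rand_by_dc$drug_id,
                random_by_z = rand_by_z$drug_id)
  hit_of <- function(ids) sum(hits[ids], na.rm = TRUE)
  hit_counts <- vapply(lists, hit_of, numeric(1L))

  n_top <- length(lists$top)
  catalogue_relevant <- sum(hits[results$drug_id], na.rm = TRUE)
  catalogue_rest <- nrow(results) - catalogue_relevant
  fisher_vs <- function(other_ids) {
    safe_fisher(matrix(c(hit_counts["top"], n_top - hit_counts["top"],
                              hit_of(other_ids),
                              length(other_ids) - hit_of(other_ids)),
                            2L, 2L, byrow = TRUE))
  }
  structure(list(lists = lists, hit_counts = hit_counts,
                 fisher_top_vs_random_dc = fisher_vs(lists$random_by_dc),
                 fisher_top_vs_random_z = fisher_vs(lists$random_by_z),
                 fisher_top_vs_catalogue = safe_fisher(
                   matrix(c(hit_counts["top"], n_top - hit_counts["top"],
                            catalogue_relevant, catalogue_rest),
                          2L, 2L, byrow = TRUE)),
                 results = results),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> hits per list:\n")
  for (nm in names(x$hit_counts))
    cat(sprintf("  %-14s %d / %d\n", nm, x$hit_counts[[nm]],
                length(x$lists[[nm]])))
  cat(sprintf("  top vs random (d_c): p = %.3g\n",
              x$fisher_top_vs_random_dc$p_two_sided))
  cat(sprintf("  top vs catalogue:    p = %.3g\n",
              x$fisher_top_vs_catalogue$p_two_sided))
  invisible(x)
}
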