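test_that("signature extraction applies the joint quantile rule", {
  genes <- paste0("g", 1:10)
  tab <- data.frame(gene = genes,
                    gs_consensus = seq(0.1, 1, length.out = 10),
                    gc_consensus = 2 * seq(0.1, 1, length.out = 10),
                    module = rep(1L, 10), meta_module = rep(1L, 10))
  g <- interactome_from_edges(genes[-10], genes[-1])
  sig <- disease_signature(tab, 1, g, quantile = 0.8)
  expect_setequal(sig$requested, c("g9", "g10"))   # top 2 pass at 80%
  sig0 <- disease_signature(tab, 1, g, quantile = 0)
  expect_setequal(sig0$requested, genes)
  # anti-ranked scores: no gene passes both thresholds
  tab$gc_consensus <- rev(tab$gc_consensus)
  expect_error(disease_signature(tab, 1, g, quantile = 0.8), "need >= 2")
})

test_that("induced-subgraph component size follows signature semantics", {
  pg <- make_path_interactome(3)  # n0 - n1 - n2
  expect_identical(lcc_size(pg, signature_from_genes(c("n0", "n1"), pg)), 2)
  expect_identical(lcc_size(pg, signature_from_genes(c("n0", "n2"), pg)), 1)
  g4 <- interactome_from_edges(c("a", "a", "a", "b", "b", "c"),
                               c("b", "c", "d", "c", "d", "d"))
  expect_identical(lcc_size(g4, signature_from_genes(c("a", "b", "c", "d"), g4)), 4)
})

test_that("mean nearest-neighbour distance evaluates exactly on small graphs", {
  pg <- make_path_interactome(3)
  expect_equal(mean_shortest_distance_ds(pg, signature_from_genes(c("n0", "n1"), pg)), 1)
  expect_equal(mean_shortest_distance_ds(pg, signature_from_genes(c("n0", "n2"), pg)), 2)
  clique <- interactome_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(mean_shortest_distance_ds(clique,
                                         signature_from_genes(c("a", "b", "c"), clique)), 1)
})

test_that("closest-distance proximity evaluates exactly on a path", {
  pg <- make_path_interactome(6)
  sig <- signature_from_genes(c("n0", "n1"), pg)
  drug <- drug_record("D", "d", c("n2", "n5"))
  expect_equal(drug_disease_proximity(pg, drug, sig), (1 + 4) / 2)
  inside <- drug_record("DI", "i", c("n0", "n1"))
  expect_equal(drug_disease_proximity(pg, inside, sig), 0)
  # adding a distance-zero target strictly decreases a positive proximity
  more <- drug_record("DM", "m", c("n2", "n5", "n0"))
  expect_lt(drug_disease_proximity(pg, more, sig),
            drug_disease_proximity(pg, drug, sig))
})

test_that("proximity statistics agree with an independent BFS oracle", {
  si <- simulate_interactome(n_nodes = 60, edges_per_node = 2,
                             neighborhood_size = 6, seed = 12)
  g <- si$interactome
  edges <- igraph::as_edgelist(g$graph)
  nodes <- interactome_nodes(g)
  sig <- signature_from_genes(si$truth$disease_neighborhood, g)
  drug <- drug_record("D", "d", sample(nodes, 5))
  dist_rows <- t(vapply(sig$mapped, function(s)
    bfs_dist_oracle(edges, nodes, s), setNames(numeric(length(nodes)), nodes)))
  # d_c oracle: per-target minimum over signature sources
  dc_oracle <- mean(apply(dist_rows[, drug$targets, drop = FALSE], 2, min))
  expect_equal(drug_disease_proximity(g, drug, sig), dc_oracle)
  # d_s oracle: per-protein nearest other signature protein
  within <- dist_rows[, sig$mapped]
  diag(within) <- Inf
  expect_equal(mean_shortest_distance_ds(g, sig), mean(apply(within, 1, min)))
})

test_that("degree-preserving sampling respects bins and degree profiles", {
  si <- simulate_interactome(n_nodes = 500, edges_per_node = 2,
                             neighborhood_size = 10, seed = 21)
  g <- si$interactome
  deg <- igraph::degree(g$graph)
  names(deg) <- interactome_nodes(g)
  ref <- sample(interactome_nodes(g), 20)
  # singleton bins preserve the exact degree multiset
  samp1 <- degree_preserving_sample(g, ref, seed = 2, min_bin_size = 1)
  expect_identical(sort(unname(deg[samp1])), sort(unname(deg[ref])))
  expect_false(anyDuplicated(samp1) > 0)
  # the whole node set maps to itself
  all_nodes <- interactome_nodes(g)
  expect_setequal(degree_preserving_sample(g, all_nodes, seed = 3), all_nodes)
  # repeated draws track the reference mean degree
  means <- vapply(1:1000, function(s) {
    mean(deg[degree_preserving_sample(g, ref, seed = s, min_bin_size = 25)])
  }, numeric(1))
  expect_lt(abs(mean(means) - mean(deg[ref])), 0.1 * mean(deg[ref]))
})

test_that("z-scores use the population standard deviation and empirical tails", {
  null <- null_distribution(c(1, 2, 3), "x")
  expect_equal(null$sigma, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(zscore(3, null)$z, (3 - 2) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(zscore(2, null)$z, 0)
  expect_equal(zscore(2 + 2 * null$sigma, null)$z, 2, tolerance = 1e-12)
  # a null concentrated on the statistic itself gives z = 0
  flat <- null_distribution(c(5, 5, 5, 5 + 1e-9), "x")
  expect_lt(abs(zscore(5, flat)$z), 1)
  expect_error(zscore(1, null_distribution(c(2, 2, 2), "x")), "zero standard")
  expect_error(null_distribution(3), "at least 2")
})

test_that("the planted neighbourhood is agglomerated; random signatures are not", {
  si <- simulate_interactome(n_nodes = 1500, edges_per_node = 3,
                             neighborhood_size = 15, seed = 31)
  g <- si$interactome
  sig <- signature_from_genes(si$truth$disease_neighborhood, g)
  agg <- signature_agglomeration(g, sig, n_reps = 300, seed = 41,
                                 min_bin_size = 50)
  expect_gt(agg$S$z, 2)
  expect_lt(agg$ds$z, 0)
  expect_error(signature_agglomeration(g, sig, n_reps = 1), "at least 2")
  # uniform signatures on a near-regular graph stay unremarkable
  set.seed(51)
  kreg <- igraph::sample_k_regular(400, 4)
  igraph::V(kreg)$name <- paste0("v", 1:400)
  gk <- structure(list(graph = kreg, restricted_to_lcc = FALSE),
                  class = "interactome")
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    rsig <- signature_from_genes(sample(paste0("v", 1:400), 15), gk)
    a <- signature_agglomeration(gk, rsig, n_reps = 200, seed = 60 + seed,
                                 min_bin_size = 50)
    if (abs(a$S$z) < 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the proximity screen separates planted proximal from distal drugs", {
  si <- simulate_interactome(n_nodes = 1200, edges_per_node = 3,
                             neighborhood_size = 12, seed = 71)
  g <- si$interactome
  sig <- signature_from_genes(si$truth$disease_neighborhood, g)
  dr <- simulate_drugs(g, si$truth, n_proximal = 6, n_distal = 6,
                       targets_per_drug = 3, seed = 72)
  res <- proximity_screen(g, dr$drugs, sig, n_reps = 200, seed = 73,
                          min_bin_size = 50)
  cls <- dr$drug_class[res$drug_id]
  expect_lt(mean(res$z[cls == "proximal"]), mean(res$z[cls == "distal"]))
  expect_true(all(res$z[cls == "proximal"] < 0))
  # determinism
  res2 <- proximity_screen(g, dr$drugs, sig, n_reps = 200, seed = 73,
                           min_bin_size = 50)
  expect_identical(res$z, res2$z)
})

test_that("drug ranking applies eligibility, ordering, and tie rules", {
  res <- data.frame(drug_id = sprintf("D%02d", 1:20),
                    name = sprintf("drug%02d", 1:20),
                    d_c = c(rep(0.5, 10), rep(3, 10)),
                    z = c(-10:-1, 1:10),
                    empirical_p = 0, n_mapped_targets = 2,
                    null_mu = 1, null_sigma = 1)
  rk <- rank_drugs(res, dc_quantile = 0.5, k = 5)
  expect_identical(rk$top$drug_id, sprintf("D%02d", 1:5))
  expect_identical(rk$bottom$drug_id, sprintf("D%02d", 11:15))
  # a drug with the smallest z but a large d_c is ineligible for the top list
  res$z[15] <- -100
  rk2 <- rank_drugs(res, dc_quantile = 0.5, k = 5)
  expect_false("D15" %in% rk2$top$drug_id)
  expect_identical(rk2$bottom$drug_id[1], "D15")
  # ties on z break by smaller d_c, then drug id; input order is irrelevant
  res$z[] <- 0; res$d_c <- c(rep(0.5, 10), rep(3, 10))
  res$d_c[2] <- 0.1
  rk3 <- rank_drugs(res, dc_quantile = 0.5, k = 3)
  expect_identical(rk3$top$drug_id[1], "D02")
  shuffled <- res[sample(nrow(res)), ]
  rk4 <- rank_drugs(shuffled, dc_quantile = 0.5, k = 3)
  expect_identical(rk3$top$drug_id, rk4$top$drug_id)
})

test_that("the exact 2x2 Fisher test matches enumeration and the stats oracle", {
  f <- fisher_exact_2x2(matrix(c(9, 1, 3, 7), 2, byrow = TRUE))
  expect_equal(f$p_two_sided, 0.0197666, tolerance = 1e-5)
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p_two_sided, 1)
  set.seed(61)
  for (rep in 1:300) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    while (sum(tab) > 60) tab <- matrix(rpois(4, 5) + 1, 2, 2)
    mine <- fisher_exact_2x2(tab)
    ref <- fisher.test(tab)
    ref_g <- fisher.test(tab, alternative = "greater")
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$p_greater, ref_g$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(c(0, 0, 1, 1)), "margins")
})

test_that("validation builds control lists and degenerate Fisher cases", {
  si <- simulate_interactome(n_nodes = 800, edges_per_node = 3,
                             neighborhood_size = 10, seed = 81)
  g <- si$interactome
  sig <- signature_from_genes(si$truth$disease_neighborhood, g)
  dr <- simulate_drugs(g, si$truth, n_proximal = 8, n_distal = 8,
                       targets_per_drug = 3, seed = 82)
  hits <- dr$drug_class == "proximal"
  names(hits) <- names(dr$drug_class)
  rep1 <- validate_lists(g, dr$drugs, sig, hits, n_reps = 100, seed = 83,
                         k = 6, dc_quantile = 0.4, min_bin_size = 50)
  expect_gte(rep1$hit_counts[["top"]],
             rep1$hit_counts[["random_by_dc"]])
  expect_identical(length(rep1$lists$top), 6L)
  # identical seeds reproduce the random lists exactly
  rep2 <- validate_lists(g, dr$drugs, sig, hits, n_reps = 100, seed = 83,
                         k = 6, dc_quantile = 0.4, min_bin_size = 50)
  expect_identical(rep1$lists, rep2$lists)
  # every drug a hit: no contrast, Fisher p = 1
  all_hits <- setNames(rep(TRUE, length(hits)), names(hits))
  rep3 <- validate_lists(g, dr$drugs, sig, all_hits, results = rep1$results,
                         n_reps = 50, seed = 84, k = 6, dc_quantile = 0.4,
                         min_bin_size = 50)
  expect_equal(rep3$fisher_top_vs_random_dc$p_two_sided, 1)
})
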