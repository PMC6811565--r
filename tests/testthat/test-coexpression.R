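test_that("signed adjacency maps correlation extremes to closed-form values", {
  set.seed(1)
  v <- rnorm(8)
  # an explicitly orthogonal partner gives the cor = 0 case exactly
  w <- residuals(lm(rnorm(8) ~ v))
  x <- rbind(v, v, -v, w)
  dimnames(x) <- list(paste0("g", 1:4), paste0("s", 1:8))
  ds <- expression_dataset(x, rep(c(0L, 1L), each = 4))
  a <- signed_adjacency(ds, beta = 20)
  expect_equal(a$values["g1", "g2"], 1)            # cor = 1
  expect_equal(a$values["g1", "g3"], 0)            # cor = -1
  expect_equal(a$values["g1", "g4"], 0.5^20, tolerance = 1e-10)  # cor = 0
  expect_error(signed_adjacency(ds, beta = 0), "positive")
  x["g4", ] <- 7
  expect_error(signed_adjacency(expression_dataset(x, rep(c(0L, 1L), each = 4)), 6),
               "constant.*g4")
})

test_that("adjacency is monotone in correlation for a fixed power", {
  set.seed(31)
  ds <- make_tiny_ds(20, 15, seed = 31)
  cc <- cor(t(ds$values))
  a <- signed_adjacency(ds, beta = 7)$values
  ut <- upper.tri(cc)
  ord <- order(cc[ut])
  expect_true(all(diff(a[ut][ord]) >= 0))
})

test_that("connectivity sums off-diagonal adjacency", {
  a <- make_adjacency(matrix(1, 3, 3))
  expect_equal(unname(connectivity(a)), c(2, 2, 2))
  z <- make_adjacency(matrix(0, 3, 3))
  expect_equal(unname(connectivity(z)), c(0, 0, 0))
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.2; m[1, 3] <- m[3, 1] <- 0.3
  expect_equal(unname(connectivity(make_adjacency(m)))[1], 0.5)
})

test_that("an exact power-law connectivity profile gives near-perfect scale-free fit", {
  # frequencies proportional to k^(-1.5) at integer connectivities 1..10,
  # one distinct value per equal-width bin: the log-log regression is exact
  k <- rep(1:10, times = round(2000 * (1:10)^-1.5))
  r2 <- coexpharm:::.scale_free_r2(k, n_bins = 10)
  expect_gte(r2, 0.99)
  # uniform connectivities: no power-law signal
  set.seed(17)
  r2u <- coexpharm:::.scale_free_r2(runif(1000, 10, 20), n_bins = 10)
  expect_lt(r2u, 0.5)
})

test_that("power selection follows the smallest-passing rule and flags failures", {
  sim <- simulate_multitissue(n_tissues = 1, n_genes = 100,
                              n_samples_per_class = 10,
                              module_sizes = c(30), seed = 41)
  ds <- sim$datasets[[1]]
  fit <- pick_beta(ds, candidates = 20, r2_min = 0)
  expect_identical(fit$beta, 20)
  expect_true(fit$reached_threshold)
  fit2 <- pick_beta(ds, candidates = c(2, 6, 12), r2_min = 0.999)
  if (!fit2$reached_threshold)
    expect_identical(fit2$beta,
                     fit2$table$beta[which.max(fit2$table$r_squared)])
  full <- pick_beta(ds)
  hit <- full$table$beta[full$table$r_squared >= 0.8]
  if (length(hit)) expect_identical(full$beta, hit[1])
})

test_that("topological overlap matches hand-evaluated closed forms", {
  # two nodes joined with weight 1 and nothing else
  two <- make_adjacency(matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(unname(tom(two)$values[1, 2]), 1)
  # no edges at all
  none <- make_adjacency(matrix(0, 4, 4))
  expect_true(all(tom(none)$values[upper.tri(diag(4))] == 0))
  # complete triangle of unit weights
  tri <- make_adjacency(matrix(1, 3, 3))
  expect_equal(unname(tom(tri)$values[1, 2]), 1)
})

test_that("topological overlap equals the brute-force triple loop on random adjacencies", {
  for (seed in c(51, 52)) {
    adj <- random_adjacency(50, seed)
    fast <- tom(adj)$values
    slow <- tom_brute_force(adj$values)
    diag(slow) <- 1
    expect_lt(max(abs(fast - slow)), 1e-10)
    expect_true(all(fast >= 0 & fast <= 1))
  }
})

test_that("TOM dissimilarity is the unit complement with zero diagonal", {
  adj <- random_adjacency(10, 61)
  tm <- tom(adj)
  d <- tom_dissimilarity(tm)
  off <- upper.tri(d$values)
  expect_equal(d$values[off], (1 - tm$values)[off], tolerance = 1e-12)
  expect_true(all(diag(d$values) == 0))
  expect_equal(d$values[2, 5], 1 - tm$values[2, 5])
})

test_that("consensus operators behave elementwise", {
  m1 <- random_adjacency(6, 71); m2 <- random_adjacency(6, 72)
  m3 <- random_adjacency(6, 73)
  cmin <- consensus_matrix(list(m1, m2, m3), "min")
  expect_true(all(cmin$values <= m1$values + 1e-15))
  expect_true(all(cmin$values <= m2$values + 1e-15))
  expect_true(all(cmin$values <= m3$values + 1e-15))
  expect_equal(cmin$values[1, 2],
               min(m1$values[1, 2], m2$values[1, 2], m3$values[1, 2]))
  cmed <- consensus_matrix(list(m1, m2, m3), "median")
  expect_equal(cmed$values[3, 4],
               median(c(m1$values[3, 4], m2$values[3, 4], m3$values[3, 4])))
  # idempotence and permutation equivariance in the list of inputs
  same <- consensus_matrix(list(m1, m1), "min")
  expect_equal(same$values, m1$values)
  perm <- consensus_matrix(list(m3, m1, m2), "min")
  expect_equal(perm$values, cmin$values)
  bad <- m2; bad$genes <- rev(bad$genes)
  expect_error(consensus_matrix(list(m1, bad)), "gene lists")
})

test_that("planted dissimilarity blocks are cut into exact modules", {
  set.seed(81)
  n <- 100
  d <- matrix(0.9, n, n)
  d[1:50, 1:50] <- 0.2
  d[51:100, 51:100] <- 0.2
  d <- d + matrix(rnorm(n * n, sd = 0.01), n, n); d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0; d[d > 1] <- 1
  rownames(d) <- colnames(d) <- sprintf("g%03d", 1:n)
  part <- cluster_modules(gene_matrix(d, "dissimilarity"), min_module_size = 30)
  expect_identical(length(module_sizes(part)), 2L)
  expect_equal(best_jaccard(sprintf("g%03d", 1:50), part), 1)
  expect_equal(best_jaccard(sprintf("g%03d", 51:100), part), 1)
})

test_that("structureless dissimilarity leaves every gene unassigned", {
  n <- 40
  d <- matrix(1, n, n); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:n)
  part <- cluster_modules(gene_matrix(d, "dissimilarity"), min_module_size = 10)
  expect_true(all(part$labels == 0L))
})

test_that("module detection is equivariant under gene permutation", {
  set.seed(91)
  n <- 60
  d <- matrix(0.95, n, n)
  d[1:20, 1:20] <- 0.1; d[21:40, 21:40] <- 0.1
  d <- d + matrix(runif(n * n, 0, 0.02), n, n); d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("g%02d", 1:n)
  part <- cluster_modules(gene_matrix(pmin(d, 1), "dissimilarity"),
                          min_module_size = 15)
  perm <- sample(n)
  dp <- d[perm, perm]
  part_p <- cluster_modules(gene_matrix(pmin(dp, 1), "dissimilarity"),
                            min_module_size = 15)
  # same partition up to relabelling: co-membership must agree
  co <- function(p) outer(p$labels, p$labels, `==`) &
    outer(p$labels != 0L, p$labels != 0L, `&`)
  expect_identical(unname(co(part)[part$genes, part$genes][rownames(dp), rownames(dp)]),
                   unname(co(part_p)))
})

test_that("the consensus pipeline recovers planted modules across tissues", {
  sim <- simulate_multitissue(n_tissues = 3, n_genes = 300,
                              n_samples_per_class = 15,
                              module_sizes = c(40, 40), within_cor = 0.6,
                              seed = 77)
  fit <- consensus_modules(sim$datasets)
  truth <- sim$truth$module_membership
  for (m in 1:2)
    expect_gte(best_jaccard(names(truth)[truth == m], fit$partition), 0.8)
  # literal consensus orientation is exposed and runs
  fit2 <- consensus_modules(sim$datasets, beta = fit$beta, consensus_on_dissimilarity = TRUE)
  expect_s3_class(fit2$partition, "module_partition")
})
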