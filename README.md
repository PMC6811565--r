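# coexpharm

Consensus co-expression modules across tissues, and network-proximity
drug repurposing against the disease signature they define.

## The problem

Complex joint diseases such as osteoarthritis affect several tissues of
the same organ at once. Expression studies of single tissues disagree
about which genes matter; what is more robust is the *wiring*: groups of
genes that are co-expressed in every tissue, some of which track the
disease state. `coexpharm` implements that whole chain as a reusable
pipeline:

1. **Consensus weighted co-expression networks.** Per tissue, a signed
   adjacency `A_ij = (0.5 + 0.5·cor(x_i, x_j))^β` is built, with the soft
   power β chosen so the network approximates scale-free topology
   (R² ≥ 0.8 of the log–log connectivity fit). Each adjacency is
   transformed into a topological overlap matrix
   `TOM_ij = (Σ_u a_iu a_ju + a_ij) / (min(k_i, k_j) − a_ij + 1)`, and the
   elementwise **minimum** of the per-tissue TOMs forms the consensus:
   a gene pair counts as consensus-co-expressed only if *every* tissue
   co-expresses it. Modules are cut from `1 − consensus` by average-linkage
   clustering with a hybrid (tree cut + PAM-style reassignment) rule;
   genes in no module stay in the grey bucket.
2. **Stability.** Modules are recomputed under repeated sample
   perturbation (10% removal, or resampling with replacement) and scored
   by the fraction of reference module genes recovered by the best-matching
   perturbed module.
3. **Eigengenes and meta-modules.** Each module is summarised by its
   eigengene (first principal component of its expression submatrix);
   eigengene networks at β = 1 are compared across tissues via the
   preservation network `Preserv = 1 − (max − min)`, its scaled
   connectivity `C_i` and density `D`, and modules are grouped into
   meta-modules by classical MDS plus k-means on the consensus eigengene
   dissimilarity.
4. **Trait association.** Gene significance `GS = |cor(trait, x)|` and
   intramodular connectivity GC (weighted within-module degree) are
   medianed across tissues; a *positive GS–GC correlation* inside a
   meta-module says its hubs are its most disease-correlated genes — the
   signature of a disease meta-module.
5. **Network pharmacology.** Genes in the joint 80% quantile of GS and GC
   of the disease meta-module form the disease signature, mapped onto a
   protein–protein interactome. Its agglomeration (largest connected
   component S, mean nearest-neighbour distance ⟨d_s⟩) and each drug's
   closest-distance proximity ⟨d_c⟩ to the signature are standardised by
   `z = (X − μ(X_rand)) / σ(X_rand)` against degree-preserving random
   node sets; drugs are ranked by z among the low-⟨d_c⟩ candidates and
   the ranked lists validated with exact Fisher tests.

A synthetic-data module generates multi-tissue expression with planted
modules (a one-factor model per module, trait effects routed through the
latent factor), scale-free interactomes with a planted connected disease
neighbourhood, and drug target sets at controlled distance from it — so
every stage of the pipeline has a ground-truth recovery test.

## Worked example

```r
library(coexpharm)

## three tissues, two planted modules of 40 genes, module 1 trait-shifted
sim <- simulate_multitissue(n_tissues = 3, n_genes = 300,
                            n_samples_per_class = 15,
                            module_sizes = c(40, 40), within_cor = 0.65,
                            trait_shift = 1.2, seed = 7)
fit <- consensus_modules(sim$datasets)
fit
#> <consensus_fit> beta = 13
#> <module_partition> 300 genes, 2 modules (sizes 41, 41), 218 unassigned (grey)
```

The pipeline picked β = 13 by the scale-free fit and recovered both
planted modules (41 of 300 genes each; the rest stay grey). The disease
module shows the hub–trait coupling:

```r
adjs <- lapply(sim$datasets, signed_adjacency, beta = fit$beta)
gs   <- lapply(sim$datasets, gene_significance)
gc   <- lapply(adjs, gene_connectivity, partition = fit$partition)
names(gs) <- names(gc) <- paste0("tissue", 1:3)
mods <- sort(unique(fit$partition$labels[fit$partition$labels != 0]))
tab  <- consensus_scores(gs, gc, fit$partition,
                         setNames(as.integer(mods), as.character(mods)))
gs_gc_correlation(tab, 1)
#> meta-module 1: GS-GC r = 0.60 (p = 3.7e-05, n = 41)
```

On the interactome side, the planted disease neighbourhood is strongly
agglomerated and proximal drugs separate cleanly from distal ones:

```r
si  <- simulate_interactome(n_nodes = 2000, edges_per_node = 3,
                            neighborhood_size = 20, seed = 8)
sig <- signature_from_genes(si$truth$disease_neighborhood, si$interactome,
                            "planted neighbourhood")
signature_agglomeration(si$interactome, sig, n_reps = 500, seed = 9)
#> <agglomeration> S = 20 (z = 13.99), <d_s> = 1.000 (z = -5.71)

dr  <- simulate_drugs(si$interactome, si$truth, n_proximal = 5,
                      n_distal = 5, targets_per_drug = 3, seed = 10)
res <- proximity_screen(si$interactome, dr$drugs, sig, n_reps = 500, seed = 11)
res[order(res$z), c("drug_id", "d_c", "z")]
#>  drug_id d_c         z
#>  PROX003   1 -3.643625
#>  PROX004   1 -3.612232
#>  PROX001   1 -3.269534
#>  PROX002   1 -2.876225
#>  PROX005   1 -2.471932
#>  DIST002   3  1.635541
#>  ...
```

All five proximal drugs rank above all five distal drugs, with negative
z-scores (closer to the disease signature than degree-matched chance).

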