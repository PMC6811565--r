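#' Perturb the samples of a dataset
#'
#' `drop10` removes `ceiling(0.1 * M)` samples uniformly without
#' replacement; `resample` draws M samples with replacement (duplicated
#' sample ids get a numeric suffix). Phenotype labels travel with their
#' samples.
#'
#' @param ds An [expression_dataset()] (>= 10 samples for `drop10`).
#' @param mode `"drop10"` or `"resample"`.
#' @param seed Integer seed.
#' @return A perturbed [expression_dataset()].
#' @export
perturb_samples <- function(ds, mode = c("drop10", "resample"), seed = 1L) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  m <- length(ds$samples)
  if (mode == "drop10") {
    if (m < 10L) stop("drop10 needs at least 10 samples")
    drop <- sample.int(m, ceiling(0.1 * m))
    keep <- setdiff(seq_len(m), drop)
    return(expression_dataset(ds$values[, keep, drop = FALSE],
                              ds$phenotype[keep], ds$tissue_name))
  }
  idx <- sample.int(m, m, replace = TRUE)
  vals <- ds$values[, idx, drop = FALSE]
  colnames(vals) <- make.unique(ds$samples[idx], sep = "_dup")
  expression_dataset(vals, ds$phenotype[idx], ds$tissue_name)
}

#' Fraction of reference module genes recovered by a perturbed partition
#'
#' For every reference module the perturbed module with the largest
#' overlap is found (the unassigned label is never eligible as a match),
#' and the preserved fraction is the total best-match overlap divided by
#' the total number of reference module genes. The statistic is invariant
#' under relabelling of either partition.
#'
#' @param reference,perturbed [module_partition()] objects over the same
#'   genes.
#' @return Preserved fraction in \[0, 1\].
#' @export
preserved_fraction <- function(reference, perturbed) {
  if (!identical(reference$genes, perturbed$genes))
    stop("partitions must cover the same genes in the same order")
  ref_mods <- setdiff(unique(reference$labels), 0L)
  if (!length(ref_mods)) stop("reference partition has no assigned genes")
  total <- 0L; preserved <- 0L
  for (m in ref_mods) {
    members <- reference$labels == m
    total <- total + sum(members)
    counterpart <- perturbed$labels[members]
    counterpart <- counterpart[counterpart != 0L]
    if (length(counterpart))
      preserved <- preserved + max(tabulate(counterpart))
  }
  preserved / total
}

#' Module stability under repeated sample perturbation
#'
#' Every repetition perturbs each tissue's samples, reruns the consensus
#' clustering with the reference soft power and parameters, and records
#' the fraction of reference module genes recovered. Run separately for
#' each requested mode.
#'
#' @param datasets List of [expression_dataset()] sharing a gene list.
#' @param reference A `consensus_fit` from [consensus_modules()] on the
#'   unperturbed data; NULL computes it here.
#' @param modes Perturbation modes to run (default both).
#' @param n_reps Repetitions per mode (default 50).
#' @param seed Integer seed.
#' @param ... Clustering parameters forwarded to [consensus_modules()]
#'   (`min_module_size`, `cut_height_fraction`, ...).
#' @return Named list (one per mode) of class `stability_report`:
#'   `mode`, `n_reps`, `preserved` (per-rep fractions),
#'   `median_preserved`.
#' @export
stability_analysis <- function(datasets, reference = NULL,
                               modes = c("drop10", "resample"),
                               n_reps = 50L, seed = 1L, ...) {
  n_reps <- as.integer(n_reps)
  if (is.null(reference)) reference <- consensus_modules(datasets, ...)
  ref_part <- reference$partition
  beta <- reference$beta
  out <- list()
  for (mode in modes) {
    fractions <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- as.integer(seed) + 7919L * r +
        1000003L * match(mode, c("drop10", "resample"))
      perturbed <- lapply(seq_along(datasets), function(i)
        perturb_samples(datasets[[i]], mode, seed = rep_seed + i))
      fit <- consensus_modules(perturbed, beta = beta, ...)
      fractions[r] <- preserved_fraction(ref_part, fit$partition)
    }
    out[[mode]] <- structure(list(mode = mode, n_reps = n_reps,
                                  preserved = fractions,
                                  median_preserved = stats::median(fractions)),
                             class = "stability_report")
  }
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> mode %s: %d reps, median preserved %.1f%%\n",
              x$mode, x$n_reps, 100 * x$median_preserved))
  invisible(x)
}
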