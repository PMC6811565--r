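#' Remove outlier samples by within-class mean correlation
#'
#' For every sample the mean Pearson correlation to all other samples of
#' the same phenotype class is computed and standardized within the class;
#' samples falling below `z_cut` standard deviations are removed. The rule
#' is applied once (a single pass), mirroring an outlier cut on a sample
#' clustering dendrogram.
#'
#' @param ds An [expression_dataset()] with at least 4 samples per class.
#' @param z_cut Standardized cut-off (default -2.5).
#' @return List with `dataset` (samples removed) and `removed` (sample
#'   ids).
#' @export
remove_outlier_samples <- function(ds, z_cut = -2.5) {
  cls <- split(ds$samples, ds$phenotype)
  if (any(lengths(cls) < 4L)) stop("need at least 4 samples per class")
  removed <- character(0)
  for (samples in cls) {
    cc <- stats::cor(ds$values[, samples, drop = FALSE])
    meanc <- (rowSums(cc) - 1) / (length(samples) - 1L)
    z <- as.numeric(scale(meanc))
    removed <- c(removed, samples[!is.na(z) & z < z_cut])
  }
  if (length(removed)) {
    keep <- setdiff(ds$samples, removed)
    kept_classes <- table(factor(ds$phenotype[keep], levels = c(0L, 1L)))
    if (any(kept_classes < 3L))
      stop("outlier removal would leave a phenotype class with < 3 samples")
    ds <- expression_dataset(ds$values[, keep, drop = FALSE],
                             ds$phenotype[keep], ds$tissue_name)
    message(sprintf("removed %d outlier sample(s): %s", length(removed),
                    paste(removed, collapse = ", ")))
  }
  list(dataset = ds, removed = removed)
}

#' Per-gene differential expression between phenotype classes
#'
#' Welch two-sample t-test per gene on the (log2-scale) values, with
#' Benjamini-Hochberg adjustment across genes. A gene is called
#' differentially expressed when both `|log2FC| >= fc_threshold` and
#' `adj_p <= alpha` hold, where the log2 fold change is the disease-class
#' mean minus the healthy-class mean.
#'
#' Genes with zero variance in both classes get `p = 1` when the class
#' means are equal; otherwise the variance is floored at 1e-12 and the
#' statistic computed (reported via a message).
#'
#' @param ds An [expression_dataset()] with at least 2 samples per class.
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `data.frame` with columns `gene`, `log2_fold_change`,
#'   `p_value`, `adj_p`, `is_deg`.
#' @export
differential_expression <- function(ds, fc_threshold = 1.5, alpha = 0.05) {
  x1 <- ds$values[, ds$phenotype == 1L, drop = FALSE]
  x0 <- ds$values[, ds$phenotype == 0L, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples per class")
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  lfc <- m1 - m0

  degenerate <- v1 == 0 & v0 == 0
  if (any(degenerate & lfc != 0)) {
    message(sprintf("%d gene(s) with zero within-class variance; variance floored",
                    sum(degenerate & lfc != 0)))
    v1[degenerate & lfc != 0] <- 1e-12
    v0[degenerate & lfc != 0] <- 1e-12
  }
  se2 <- v1 / n1 + v0 / n0
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v0^2 / (n0^2 * (n0 - 1L))),
               1)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate & lfc == 0] <- 1
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = ds$genes,
             log2_fold_change = unname(lfc),
             p_value = unname(p),
             adj_p = unname(adj),
             is_deg = unname(abs(lfc) >= fc_threshold & adj <= alpha),
             stringsAsFactors = FALSE)
}

#' Venn-style overlap counts of DEG sets across tissues
#'
#' For every non-empty subset of tissues, counts the genes that are
#' differentially expressed in exactly that subset of tissues.
#'
#' @param tables Named list (tissue -> DEG `data.frame` from
#'   [differential_expression()]), length >= 2.
#' @return Named integer vector; names are tissue subsets joined by `&`.
#' @export
deg_overlap <- function(tables) {
  if (length(tables) < 2L) stop("need at least two tissues")
  tissues <- names(tables)
  if (is.null(tissues) || any(!nzchar(tissues)))
    stop("`tables` must be a named list")
  deg_sets <- lapply(tables, function(tb) tb$gene[tb$is_deg])
  subsets <- lapply(seq_len(2L^length(tissues) - 1L), function(mask) {
    tissues[bitwAnd(mask, 2L^(seq_along(tissues) - 1L)) > 0L]
  })
  counts <- integer(length(subsets))
  names(counts) <- vapply(subsets, paste, character(1L), collapse = "&")
  all_genes <- unique(unlist(deg_sets))
  if (length(all_genes)) {
    for (gset in all_genes) {
      present <- tissues[vapply(deg_sets, function(s) gset %in% s, logical(1L))]
      key <- paste(present, collapse = "&")
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}
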