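#' Construct an expression dataset for one tissue
#'
#' The basic container of the pipeline: a genes x samples matrix of
#' log-scale normalized intensities for one tissue, together with a binary
#' phenotype per sample (0 = healthy, 1 = diseased).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must
#'   have unique rownames (gene symbols) and colnames (sample ids).
#' @param phenotype Integer vector of 0/1 labels, one per sample, named by
#'   sample id or in column order.
#' @param tissue_name Character scalar naming the tissue.
#' @return An object of class `expression_dataset` with fields
#'   `tissue_name`, `genes`, `samples`, `values`, `phenotype`.
#' @export
expression_dataset <- function(values, phenotype, tissue_name = "tissue") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in `values` rownames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values` colnames")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (nrow(values) < 2L) stop("need at least 2 genes")
  if (ncol(values) < 4L) stop("need at least 4 samples")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != ncol(values))
    stop("`phenotype` length must equal the number of samples")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("`phenotype` labels must be 0 (healthy) or 1 (disease)")
  names(phenotype) <- colnames(values)
  structure(list(tissue_name = as.character(tissue_name),
                 genes = rownames(values),
                 samples = colnames(values),
                 values = values,
                 phenotype = phenotype),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> tissue '%s': %d genes x %d samples (%d healthy / %d disease)\n",
              x$tissue_name, length(x$genes), length(x$samples),
              sum(x$phenotype == 0L), sum(x$phenotype == 1L)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

.matrix_roles <- c("adjacency", "tom", "dissimilarity", "consensus",
                   "eigengene_adjacency", "preservation")

#' Construct a role-tagged symmetric gene-gene matrix
#'
#' Symmetric N x N matrices carry a role tag so downstream operations can
#' check they receive the right kind of input: `adjacency`, `tom` and
#' `eigengene_adjacency` matrices have entries in \[0, 1\] and unit
#' diagonal; `dissimilarity` and `consensus` matrices have entries in
#' \[0, 1\] and zero diagonal (a consensus of similarities keeps the unit
#' diagonal); `preservation` matrices have entries in \[0, 1\].
#'
#' @param values Numeric symmetric matrix with identical row/col names.
#' @param role One of `r toString(.matrix_roles)`.
#' @param check_range Enforce the role's range invariants (default TRUE).
#' @return An object of class `gene_matrix` with fields `genes`, `values`,
#'   `role`.
#' @export
gene_matrix <- function(values, role, check_range = TRUE) {
  role <- match.arg(role, .matrix_roles)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix")
  if (is.null(rownames(values))) {
    rn <- paste0("g", seq_len(nrow(values)))
    dimnames(values) <- list(rn, rn)
  }
  if (!identical(rownames(values), colnames(values)))
    stop("row and column names must match")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-12)
    stop(sprintf("matrix not symmetric (max |A - t(A)| = %g)", asym))
  values <- (values + t(values)) / 2  # kill representation-level asymmetry
  if (check_range) {
    if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
      stop(sprintf("'%s' entries must lie in [0, 1]", role))
    d <- diag(values)
    if (role %in% c("adjacency", "tom", "eigengene_adjacency") &&
        max(abs(d - 1)) > 1e-8)
      stop(sprintf("'%s' matrices must have unit diagonal", role))
    if (role == "dissimilarity" && max(abs(d)) > 1e-8)
      stop("'dissimilarity' matrices must have zero diagonal")
  }
  structure(list(genes = rownames(values), values = values, role = role),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> role '%s', %d x %d\n",
              x$role, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a module partition
#'
#' Maps every gene to exactly one module. Modules are labelled with
#' positive integers; label 0 is the reserved "grey" bucket of unassigned
#' genes.
#'
#' @param genes Character vector of gene symbols.
#' @param labels Integer vector of the same length; 0 marks unassigned.
#' @return An object of class `module_partition`.
#' @export
module_partition <- function(genes, labels) {
  if (length(genes) != length(labels))
    stop("`genes` and `labels` must have the same length")
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers (0 = unassigned)")
  names(labels) <- genes
  structure(list(genes = genes, labels = labels, unassigned_label = 0L),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  cat(sprintf("<module_partition> %d genes, %d modules (sizes %s), %d unassigned (grey)\n",
              length(x$genes), length(sizes),
              if (length(sizes)) paste(sizes, collapse = ", ") else "-",
              sum(x$labels == 0L)))
  invisible(x)
}

#' Sizes of assigned modules in a partition
#'
#' @param partition A `module_partition`.
#' @return Named integer vector of module sizes, unassigned excluded.
#' @export
module_sizes <- function(partition) {
  lab <- partition$labels[partition$labels != 0L]
  if (!length(lab)) return(integer(0))
  tab <- table(lab)
  structure(as.integer(tab), names = names(tab))
}

#' Genes belonging to one module
#'
#' @param partition A `module_partition`.
#' @param module Module label (integer; 0 for the unassigned set).
#' @return Character vector of gene symbols.
#' @export
module_genes <- function(partition, module) {
  partition$genes[partition$labels == as.integer(module)]
}

#' Construct a drug record
#'
#' @param drug_id Unique drug identifier.
#' @param name Human-readable drug name.
#' @param targets Character vector of target gene symbols (non-empty).
#' @return An object of class `drug_record`.
#' @export
drug_record <- function(drug_id, name, targets) {
  targets <- unique(as.character(targets))
  targets <- targets[nzchar(targets)]
  if (!length(targets)) stop(sprintf("drug '%s' has no targets", drug_id))
  structure(list(drug_id = as.character(drug_id), name = as.character(name),
                 targets = targets, mapped_targets = NULL),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s (%s): %d targets%s\n", x$drug_id, x$name,
              length(x$targets),
              if (is.null(x$mapped_targets)) ""
              else sprintf(", %d mapped", length(x$mapped_targets))))
  invisible(x)
}
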