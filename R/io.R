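#' Read a tissue expression matrix and its phenotype file
#'
#' Expression files are TSV with a header row of sample ids and gene
#' symbols in the first column; phenotype files are two-column TSV mapping
#' sample id to a 0/1 label. Rows sharing a gene symbol are collapsed by
#' keeping the row with the highest mean intensity (a message reports how
#' many rows were dropped).
#'
#' @param path Path to the expression TSV.
#' @param phenotype_path Path to the phenotype TSV (columns: sample id,
#'   label in 0/1; header optional but recommended).
#' @param tissue_name Name recorded on the returned dataset.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, phenotype_path, tissue_name = "tissue") {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("missing values in '%s': %s", path,
                 paste(sprintf("gene '%s' sample '%s'", genes[idx[, 1L]],
                               colnames(mat)[idx[, 2L]]), collapse = "; ")))
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(mat)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(i) i[which.max(means[i])]),
                   use.names = FALSE)
    keep <- sort(keep)
    message(sprintf("collapsed %d duplicate gene rows in '%s' (kept highest mean)",
                    length(genes) - length(keep), path))
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(mat) <- genes

  ph <- utils::read.delim(phenotype_path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(ph) < 2L) stop("phenotype file needs sample id and label columns")
  pheno <- ph[[2L]]
  names(pheno) <- as.character(ph[[1L]])
  missing <- setdiff(colnames(mat), names(pheno))
  if (length(missing))
    stop(sprintf("phenotype file lacks samples: %s",
                 paste(missing, collapse = ", ")))
  expression_dataset(mat, pheno[colnames(mat)], tissue_name)
}

#' Write an expression dataset and its phenotype as TSV
#'
#' Inverse of [read_expression()]; a write/read round trip reproduces the
#' dataset exactly (up to numeric printing at 15 significant digits).
#'
#' @param ds An [expression_dataset()].
#' @param path Destination expression TSV.
#' @param phenotype_path Destination phenotype TSV.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, path, phenotype_path) {
  df <- data.frame(gene = ds$genes,
                   format(ds$values, digits = 15, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("gene", ds$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = ds$samples, phenotype = ds$phenotype),
                     phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Read an undirected interactome from an edge list
#'
#' Accepts TSV/SIF-style files whose first two columns are gene symbols;
#' extra columns are ignored. Self-loops and duplicate (unordered) edges
#' are removed, with the removal counts reported.
#'
#' @param path Edge-list file.
#' @param restrict_lcc Keep only the largest connected component (default
#'   TRUE, so shortest-path distances are always defined).
#' @return An object of class `interactome`: a list with the `igraph`
#'   `graph` and the `restricted_to_lcc` flag.
#' @export
read_interactome <- function(path, restrict_lcc = TRUE) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (nrow(df) == 0L) stop(sprintf("empty interactome file '%s'", path))
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  interactome_from_edges(as.character(df[[1L]]), as.character(df[[2L]]),
                         restrict_lcc = restrict_lcc)
}

#' Build an interactome from two vectors of edge endpoints
#'
#' @param from,to Character vectors of gene symbols (equal length).
#' @param restrict_lcc Keep only the largest connected component.
#' @return An `interactome` object.
#' @export
interactome_from_edges <- function(from, to, restrict_lcc = TRUE) {
  stopifnot(length(from) == length(to), length(from) > 0L)
  self <- from == to
  a <- pmin(from[!self], to[!self])
  b <- pmax(from[!self], to[!self])
  dup <- duplicated(paste(a, b, sep = "\r"))
  n_removed <- sum(self) + sum(dup)
  if (n_removed > 0L)
    message(sprintf("removed %d self-loop(s) and %d duplicate edge(s)",
                    sum(self), sum(dup)))
  if (!length(a[!dup])) stop("no edges left after cleaning")
  g <- igraph::graph_from_edgelist(cbind(a[!dup], b[!dup]), directed = FALSE)
  if (restrict_lcc) {
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      keep <- which(comp$membership == which.max(comp$csize))
      g <- igraph::induced_subgraph(g, keep)
    }
  }
  structure(list(graph = g, restricted_to_lcc = restrict_lcc),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d proteins, %d interactions%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$restricted_to_lcc) " (largest connected component)" else ""))
  invisible(x)
}

#' Node symbols of an interactome
#' @param g An `interactome`.
#' @return Character vector of gene symbols.
#' @export
interactome_nodes <- function(g) igraph::V(g$graph)$name

#' Read a drug-target table
#'
#' TSV with columns `drug_id`, `name`, `targets`, the last holding
#' comma-separated gene symbols. Drugs with an empty target list are
#' dropped with a warning; duplicated drug ids are an error.
#'
#' @param path Drug-target TSV.
#' @return List of [drug_record()] objects.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("drug file needs drug_id, name, targets columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate drug ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    tg <- strsplit(as.character(df[[3L]][i]), ",")[[1L]]
    tg <- trimws(tg)
    tg <- tg[nzchar(tg)]
    if (!length(tg)) {
      warning(sprintf("drug '%s' has no targets; dropped", ids[i]))
      next
    }
    out[[i]] <- drug_record(ids[i], as.character(df[[2L]][i]), tg)
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Restrict several datasets to their common gene set
#'
#' Consensus network analysis requires the identical gene list in every
#' tissue, so the datasets are cut down to the (lexicographically sorted)
#' intersection of their gene sets.
#'
#' @param datasets List of at least two [expression_dataset()] objects.
#' @return List of datasets sharing the identical ordered gene list.
#' @export
intersect_gene_sets <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  common <- Reduce(intersect, lapply(datasets, `[[`, "genes"))
  if (!length(common)) stop("gene sets have an empty intersection")
  common <- sort(common)
  lapply(datasets, function(ds)
    expression_dataset(ds$values[common, , drop = FALSE], ds$phenotype,
                       ds$tissue_name))
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Empty sets are dropped with a
#' warning; duplicated set names are an error.
#'
#' @param path GMT file.
#' @return A list with `sets` (named list of character vectors) and
#'   `source_line_count`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names_))
    stop(sprintf("duplicate gene-set names: %s",
                 paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  sets <- lapply(parts, function(p) {
    g <- if (length(p) > 2L) p[-(1:2)] else character(0)
    unique(g[nzchar(g)])
  })
  names(sets) <- names_
  empty <- !lengths(sets)
  if (any(empty)) {
    warning(sprintf("dropped %d empty gene set(s): %s", sum(empty),
                    paste(names_[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  list(sets = sets, source_line_count = length(lines))
}
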