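#' Load a subtype centroid table
#'
#' Tab-separated file: first column `gene_symbol`, one column per subtype.
#' @param path file path.
#' @return gene-by-subtype numeric matrix.
#' @export
load_centroids <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (ncol(tab) < 3L) stop("centroid TSV needs gene_symbol plus >=2 subtypes")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Nearest-centroid intrinsic subtype assignment
#'
#' Each sample is correlated (Spearman) with every subtype centroid over the
#' genes shared between the sample matrix and the centroid panel; the label
#' is the centroid with the highest correlation. Rank-based correlation makes
#' the call invariant to any strictly monotone transform of a sample's
#' expression. Ties are broken by centroid column order with a warning.
#'
#' @param gene_matrix gene-by-sample matrix (gene symbols as rownames).
#' @param centroids gene-by-subtype matrix, e.g. from [load_centroids()].
#' @param min_coverage minimum fraction of panel genes that must be present.
#' @return list with `assignments` (data.frame `sample_id`, `subtype`,
#'   `best_cor`) and `correlations` (sample-by-subtype matrix).
#' @export
classify_subtype <- function(gene_matrix, centroids, min_coverage = 0.5) {
  if (!is.matrix(gene_matrix) || is.null(rownames(gene_matrix))) {
    stop("gene_matrix must have gene rownames")
  }
  if (!is.matrix(centroids) || ncol(centroids) < 2L) {
    stop("centroids must be a gene-by-subtype matrix with >=2 subtypes")
  }
  shared <- intersect(rownames(centroids), rownames(gene_matrix))
  if (length(shared) < min_coverage * nrow(centroids)) {
    stop(sprintf("only %d/%d centroid panel genes present (< %g%%)",
                 length(shared), nrow(centroids), 100 * min_coverage))
  }
  cors <- stats::cor(gene_matrix[shared, , drop = FALSE],
                     centroids[shared, , drop = FALSE],
                     method = "spearman")
  best <- apply(cors, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1L) {
      warning("centroid correlation tie; first subtype in order taken")
    }
    top[1]
  })
  list(assignments = data.frame(sample_id = colnames(gene_matrix),
                                subtype = colnames(centroids)[best],
                                best_cor = cors[cbind(seq_along(best), best)]),
       correlations = cors)
}

#' Collapse a full probe matrix to gene level with a probe map
#'
#' General rowsum/average collapse used before subtype classification (the
#' metagene path uses [collapse_probes()] which restricts to a signature).
#'
#' @param x probe-by-sample matrix.
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`.
#' @return gene-by-sample matrix (mean over each gene's probes).
#' @export
collapse_to_genes <- function(x, probe_map) {
  assert_matrix(x)
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    stop("probe_map needs columns probe_id, gene_symbol")
  }
  pm <- probe_map[probe_map$probe_id %in% rownames(x), , drop = FALSE]
  if (nrow(pm) == 0L) stop("no probe_map probes present in matrix")
  sub <- x[pm$probe_id, , drop = FALSE]
  g <- rowsum(sub, group = pm$gene_symbol, reorder = TRUE)
  g / as.vector(table(pm$gene_symbol)[rownames(g)])
}
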