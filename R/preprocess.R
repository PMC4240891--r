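#' Read a probe-by-sample expression matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample, values log2
#' intensities.
#' @param path file path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs probe_id plus >=1 sample")
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  storage.mode(x) <- "double"
  assert_matrix(x)
  x
}

#' Write an expression matrix as TSV
#' @param x probe-by-sample matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  assert_matrix(x)
  tab <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove redundant expression profiles
#'
#' Pooled public cohorts often contain the same hybridization more than once;
#' duplicates are detected by near-perfect pairwise Pearson correlation and
#' the later-ordered member of each pair is dropped (first-in-order kept).
#'
#' @param x probe-by-sample matrix.
#' @param threshold correlation above which two samples are duplicates.
#' @return list with `matrix` (deduplicated) and `report` data.frame
#'   (`removed`, `kept`, `correlation`).
#' @export
dedup_profiles <- function(x, threshold = 0.99) {
  assert_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  cc <- stats::cor(x)
  n <- ncol(x)
  keep <- rep(TRUE, n)
  removed <- kept_partner <- character(0)
  rs <- numeric(0)
  for (j in seq_len(n)[-1]) {
    earlier <- which(keep[seq_len(j - 1L)])
    if (!length(earlier)) next
    hits <- earlier[cc[earlier, j] > threshold]
    if (length(hits)) {
      keep[j] <- FALSE
      removed <- c(removed, colnames(x)[j])
      kept_partner <- c(kept_partner, colnames(x)[hits[1]])
      rs <- c(rs, cc[hits[1], j])
    }
  }
  list(matrix = x[, keep, drop = FALSE],
       report = data.frame(removed = removed, kept = kept_partner,
                           correlation = rs))
}

#' Exclude low-signal outlier arrays
#'
#' Flags samples whose median log2 intensity lies more than `k` robust
#' deviations (MAD of the per-sample medians) below the cohort median of
#' medians — a surrogate for visual inspection of intensity distributions.
#'
#' @param x probe-by-sample matrix.
#' @param k number of MADs below the center that defines an outlier.
#' @return list with `matrix` and `report` (`removed`, `median`).
#' @export
filter_outliers <- function(x, k = 3) {
  assert_matrix(x)
  if (ncol(x) < 4L) stop("need at least 4 samples to screen outliers")
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  center <- stats::median(med)
  scale <- stats::mad(med)
  low <- med < center - k * scale
  list(matrix = x[, !low, drop = FALSE],
       report = data.frame(removed = colnames(x)[low],
                           median = unname(med[low])))
}

#' Restrict matrices to their common probe panel
#'
#' Mixed-platform cohorts are reduced to the probe sets shared by every
#' matrix (e.g. the U133A panel shared with U133 PLUS 2.0).
#'
#' @param matrices list of probe-by-sample matrices.
#' @return list of matrices, all with the same (intersection) probe rows.
#' @export
restrict_common_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("need a non-empty list of matrices")
  }
  lapply(matrices, assert_matrix)
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0L) stop("no probes shared across matrices")
  lapply(matrices, function(m) m[shared, , drop = FALSE])
}

#' Quantile-normalize a matrix across samples
#'
#' Each sample's sorted value vector is replaced by the across-sample mean of
#' sorted vectors, preserving within-sample ranks.
#'
#' @param x probe-by-sample matrix, no missing values.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  assert_matrix(x)
  if (anyNA(x)) stop("quantile normalization requires a complete matrix")
  if (ncol(x) == 1L) return(x)
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction with parametric priors (the COMBAT
#' method): per-probe standardization, batch-effect estimation with
#' shrinkage toward batch-level priors, and back-transformation.
#'
#' @param x probe-by-sample matrix.
#' @param batch batch label per sample, in column order or named by sample.
#' @return adjusted matrix; identity when only one batch is present.
#' @export
combat_adjust <- function(x, batch) {
  assert_matrix(x)
  if (!is.null(names(batch))) {
    if (!all(colnames(x) %in% names(batch))) {
      stop("batch vector is missing some samples")
    }
    batch <- batch[colnames(x)]
  }
  if (length(batch) != ncol(x)) stop("one batch label per sample required")
  batch <- factor(as.character(batch))
  if (nlevels(batch) < 2L) return(x)
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  out <- suppressMessages(sva::ComBat(dat = x, batch = batch,
                                      par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(x)
  out
}
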