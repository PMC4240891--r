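#' Probe sets excluded from the immune metagenes
#'
#' Three probe sets shared between the T/NK and M/D gene lists are removed
#' from both metagenes so the two scores measure distinct infiltrates.
#' @export
DEFAULT_EXCLUSION_PROBES <- c("200904_at", "204834_at", "211742_s_at")

#' Construct a validated signature set
#'
#' A signature set maps array probe sets to gene symbols and to one of the
#' four metagenes: B/P (B cells / plasma cells), T/NK (T cells / natural
#' killer cells), M/D (monocytes / dendritic cells) and P (proliferation).
#' Probes on the exclusion list are dropped from every metagene before
#' validation, so that after construction no probe belongs to more than one
#' metagene.
#'
#' @param entries data.frame with columns `probe_id`, `gene_symbol`,
#'   `metagene`; `metagene` must be one of `"B/P"`, `"T/NK"`, `"M/D"`, `"P"`.
#' @param exclusion_list character vector of probe ids to drop.
#' @return An object of class `signature_set`: list with `entries` (kept
#'   rows), `excluded` (dropped rows), and `exclusion_list`.
#' @export
signature_set <- function(entries, exclusion_list = DEFAULT_EXCLUSION_PROBES) {
  required <- c("probe_id", "gene_symbol", "metagene")
  if (!is.data.frame(entries) || !all(required %in% names(entries))) {
    stop("signature entries need columns probe_id, gene_symbol, metagene")
  }
  if (nrow(entries) == 0L) stop("signature table is empty")
  entries <- entries[required]
  entries[] <- lapply(entries, as.character)
  bad <- setdiff(unique(entries$metagene), unname(METAGENE_LABELS))
  if (length(bad)) {
    stop("unknown metagene name(s) in signature table: ",
         paste(bad, collapse = ", "))
  }
  drop <- entries$probe_id %in% exclusion_list
  excluded <- entries[drop, , drop = FALSE]
  kept <- entries[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no signature entries remain after exclusion")
  if (nrow(excluded)) {
    message(nrow(excluded), " signature row(s) dropped by the exclusion list")
  }
  multi <- tapply(kept$metagene, kept$probe_id,
                  function(m) length(unique(m)))
  if (any(multi > 1L)) {
    stop("probe(s) mapped to more than one metagene after exclusion: ",
         paste(names(multi)[multi > 1L], collapse = ", "))
  }
  structure(list(entries = kept, excluded = excluded,
                 exclusion_list = exclusion_list),
            class = "signature_set")
}

#' Load metagene signature definitions from a TSV file
#'
#' Expects a tab-separated file with header
#' `probe_id<TAB>gene_symbol<TAB>metagene`. The file may carry extra
#' annotation columns (for example an MHC-class-II membership flag); they are
#' preserved in an `annotation` element.
#'
#' @param path path to the signature TSV.
#' @param exclusion_list probe ids to drop (defaults to the three probes
#'   shared between T/NK and M/D).
#' @return A `signature_set`.
#' @export
load_signatures <- function(path, exclusion_list = DEFAULT_EXCLUSION_PROBES) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stop("signature file is empty: ", path)
  sig <- signature_set(tab, exclusion_list = exclusion_list)
  extra <- setdiff(names(tab), c("probe_id", "gene_symbol", "metagene"))
  if (length(extra)) {
    keep <- !(tab$probe_id %in% exclusion_list)
    sig$annotation <- tab[keep, c("probe_id", "gene_symbol", extra),
                          drop = FALSE]
  }
  sig
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", nrow(x$entries), "probe sets after exclusion",
      sprintf("(%d excluded)\n", nrow(x$excluded)))
  for (lab in unname(METAGENE_LABELS)) {
    pre <- sum(x$entries$metagene == lab) + sum(x$excluded$metagene == lab)
    post <- sum(x$entries$metagene == lab)
    genes <- length(unique(x$entries$gene_symbol[x$entries$metagene == lab]))
    if (pre > 0) {
      cat(sprintf("  %-4s %d probe sets (%d before exclusion), %d genes\n",
                  lab, post, pre, genes))
    }
  }
  invisible(x)
}

#' Collapse signature probes to gene-level values
#'
#' When several probe sets interrogate the same gene, they are averaged
#' first; cross-gene averaging happens later in [score_metagene()].
#'
#' @param x probe-by-sample numeric matrix (log2 intensities) with probe
#'   rownames.
#' @param sig a `signature_set`.
#' @param metagene metagene to collapse (`"B/P"`/`"BP"`, ...).
#' @param min_coverage minimum fraction of the metagene's probes that must be
#'   present in `x`; below this a coverage error is raised.
#' @return gene-by-sample matrix; attribute `skipped_probes` lists signature
#'   probes absent from `x`.
#' @export
collapse_probes <- function(x, sig, metagene, min_coverage = 0.5) {
  assert_matrix(x)
  lab <- metagene_label(metagene)
  ent <- sig$entries[sig$entries$metagene == lab, , drop = FALSE]
  if (nrow(ent) == 0L) stop("signature has no probes for metagene ", lab)
  present <- ent$probe_id %in% rownames(x)
  if (!any(present)) {
    stop("coverage error: none of the ", nrow(ent), " ", lab,
         " probes are present in the matrix")
  }
  if (mean(present) < min_coverage) {
    stop(sprintf("coverage error: only %d/%d %s probes present (< %g%%)",
                 sum(present), nrow(ent), lab, 100 * min_coverage))
  }
  skipped <- ent$probe_id[!present]
  if (length(skipped)) {
    message(length(skipped), " ", lab, " probe(s) absent from matrix, skipped")
  }
  ent <- ent[present, , drop = FALSE]
  sub <- x[ent$probe_id, , drop = FALSE]
  g <- rowsum(sub, group = ent$gene_symbol, reorder = TRUE)
  g <- g / as.vector(table(ent$gene_symbol)[rownames(g)])
  attr(g, "skipped_probes") <- skipped
  g
}

#' Score a metagene from gene-level values
#'
#' The metagene score of a tumor is the mean log2 intensity over the
#' metagene's member genes.
#'
#' @param gene_matrix gene-by-sample matrix, e.g. from [collapse_probes()].
#' @return named numeric vector of per-sample scores; samples with no
#'   measured gene are `NA`.
#' @export
score_metagene <- function(gene_matrix) {
  if (!is.matrix(gene_matrix) || nrow(gene_matrix) == 0L) {
    stop("gene_matrix must be a non-empty matrix")
  }
  s <- colMeans(gene_matrix, na.rm = TRUE)
  s[!is.finite(s)] <- NA_real_
  s
}

#' Score all four metagenes for a cohort
#'
#' @param x probe-by-sample matrix.
#' @param sig a `signature_set`.
#' @param min_coverage forwarded to [collapse_probes()].
#' @return sample-by-metagene matrix with columns `BP`, `TNK`, `MD`, `P`
#'   (only those metagenes present in `sig`).
#' @export
score_metagenes <- function(x, sig, min_coverage = 0.5) {
  labs <- intersect(unname(METAGENE_LABELS), unique(sig$entries$metagene))
  out <- sapply(labs, function(lab) {
    score_metagene(collapse_probes(x, sig, lab, min_coverage = min_coverage))
  })
  out <- matrix(out, ncol = length(labs),
                dimnames = list(colnames(x), metagene_code(labs)))
  out
}

#' Mean-center a score vector
#'
#' Used when comparing score distributions across cohorts; model fits use the
#' raw (uncentered) averages.
#'
#' @param scores numeric vector, may contain `NA`.
#' @return vector with mean zero over the non-missing entries.
#' @export
mean_center <- function(scores) {
  if (all(is.na(scores))) stop("all scores missing; cannot center")
  scores - mean(scores, na.rm = TRUE)
}

#' Assign tertile labels to metagene scores
#'
#' Thresholds are the empirical 33.33rd and 66.67th percentiles (linear
#' interpolation); a score at or below a threshold goes to the lower group.
#'
#' @param scores numeric vector (>= 3 finite values required).
#' @param labels the three group labels, low to high.
#' @return factor of the same length as `scores`; `NA` scores give `NA`.
#' @export
assign_tertiles <- function(scores,
                            labels = c("low", "intermediate", "high")) {
  ok <- is.finite(scores)
  if (sum(ok) < 3L) stop("need at least 3 finite scores for tertiles")
  qs <- stats::quantile(scores[ok], probs = c(1, 2) / 3, type = 7, names = FALSE)
  lab <- ifelse(scores <= qs[1], labels[1],
                ifelse(scores <= qs[2], labels[2], labels[3]))
  lab[!ok] <- NA
  out <- factor(lab, levels = labels)
  if (length(unique(out[ok])) == 1L) {
    warning("degenerate tertiles: all scored samples fall in one group")
  }
  out
}
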