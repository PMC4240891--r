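# Fixture builders shared across test files; everything is generated in code.

# Miniature signature: 2 probes x 4 genes for B/P and T/NK, 2 genes for M/D
# and P -- enough structure to exercise collapsing and exclusion.
mini_signature_entries <- function() {
  data.frame(
    probe_id = c("bp1_at", "bp2_at", "bp3_at", "bp4_at",
                 "tnk1_at", "tnk2_at", "tnk3_at", "tnk4_at",
                 "md1_at", "md2_at", "p1_at", "p2_at"),
    gene_symbol = c("BPA", "BPA", "BPB", "BPC",
                    "TNKA", "TNKA", "TNKB", "TNKC",
                    "MDA", "MDB", "PA", "PB"),
    metagene = c(rep("B/P", 4), rep("T/NK", 4), rep("M/D", 2), rep("P", 2)),
    stringsAsFactors = FALSE)
}

mini_signature <- function() signature_set(mini_signature_entries())

# Random probe-by-sample matrix covering the mini signature probes.
mini_matrix <- function(n_samples = 6, seed = 42, extra_probes = 3) {
  set.seed(seed)
  probes <- c(mini_signature_entries()$probe_id,
              if (extra_probes > 0) sprintf("noise%d_at", seq_len(extra_probes)))
  m <- matrix(rnorm(length(probes) * n_samples, mean = 8, sd = 1),
              length(probes), n_samples,
              dimnames = list(probes, sprintf("s%02d", seq_len(n_samples))))
  m
}

write_signature_tsv <- function(entries, path = tempfile(fileext = ".tsv")) {
  write.table(entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent probes->genes->score oracle: plain loops, no package code.
oracle_metagene_score <- function(x, entries, metagene_label) {
  ent <- entries[entries$metagene == metagene_label, , drop = FALSE]
  ent <- ent[ent$probe_id %in% rownames(x), , drop = FALSE]
  genes <- unique(ent$gene_symbol)
  sapply(colnames(x), function(s) {
    gvals <- sapply(genes, function(g) {
      mean(x[ent$probe_id[ent$gene_symbol == g], s])
    })
    mean(gvals)
  })
}

# Brute-force likelihood for a single-covariate logistic model, used as an
# IRLS-independent oracle: four zoom stages of a 101x101 grid.
grid_loglik_max <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- c(0, 0); width <- 8
  for (stage in 1:4) {
    b0s <- seq(c0[1] - width, c0[1] + width, length.out = 101)
    b1s <- seq(c0[2] - width, c0[2] + width, length.out = 101)
    vals <- outer(b0s, b1s, Vectorize(ll))
    idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c0 <- c(b0s[idx[1]], b1s[idx[2]])
    width <- width / 25
  }
  ll(c0[1], c0[2])
}

# One-way batch F statistic computed directly from group means/residuals,
# independent of any model-fitting code.
batch_f <- function(x, batch) {
  batch <- factor(batch)
  k <- nlevels(batch); n <- ncol(x)
  gm <- rowMeans(x)
  means <- sapply(levels(batch), function(b) rowMeans(x[, batch == b, drop = FALSE]))
  ssb <- rowSums(sweep(means, 1, gm)^2 *
                   matrix(table(batch), nrow(x), k, byrow = TRUE))
  ssw <- rowSums((x - means[, batch])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# 2x2 cohort as long-format data for logistic fits.
two_by_two_data <- function(a, b, c, d) {
  # exposed: a responders / b nonresponders; unexposed: c / d
  data.frame(exposure = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
             response = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}

# Small clinical table exercising every response-coding branch.
mini_clinical <- function() {
  data.frame(
    sample_id = sprintf("c%02d", 1:8),
    rcb = c(0, 1, 2, 3, NA, NA, NA, 0),
    pcr = c("yes", "no", "no", "no", "yes", "no", NA, "no"),
    er_status = c("positive", "negative", "positive", NA,
                  "negative", "positive", "negative", "positive"),
    her2_status = c("negative", "negative", "positive", "negative",
                    NA, "negative", "positive", "negative"),
    treatment = c("FAC", "FAC+paclitaxel", "paclitaxel", "FEC",
                  "docetaxel", "FAC", "unspecified", "FEC+paclitaxel"),
    subtype = c("Basal", "LumA", "LumB", "HER2-E",
                "Claudin-low", "Normal-like", "Basal", "LumA"),
    stringsAsFactors = FALSE)
}
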