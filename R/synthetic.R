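#' Default target Spearman correlation among the latent metagene factors
#'
#' The monocyte/dendritic and T/NK infiltrate factors are strongly coupled
#' (rho = 0.80); the remaining immune-immune entries default to 0.60 and the
#' immune-proliferation entries to 0 — stated modelling assumptions, since
#' only the M/D-T/NK value is an observed quantity.
#' @return 4x4 matrix over (BP, TNK, MD, P).
#' @export
default_latent_spearman <- function() {
  s <- diag(4)
  dimnames(s) <- list(c("BP", "TNK", "MD", "P"), c("BP", "TNK", "MD", "P"))
  s["BP", "TNK"] <- s["TNK", "BP"] <- 0.60
  s["BP", "MD"] <- s["MD", "BP"] <- 0.60
  s["TNK", "MD"] <- s["MD", "TNK"] <- 0.80
  s
}

#' Simulation configuration for a synthetic neoadjuvant cohort
#'
#' Defaults emulate a pooled breast-tumor cohort treated with neoadjuvant
#' chemotherapy: six intrinsic subtypes at their observed frequencies, four
#' correlated latent metagene factors (Gaussian copula; Spearman targets
#' converted to Pearson via 2*sin(pi*rho/6)), a logistic response model with
#' literature effect sizes, a ~27% marginal response rate, probe-set
#' multiplicity per gene, and additive per-probe dataset/batch shifts.
#'
#' @param n_samples cohort size (default 680, the response-annotated panel).
#' @param subtype_freqs named probabilities over the six subtypes (sum 1).
#' @param spearman_latent 4x4 target Spearman matrix over (BP,TNK,MD,P).
#' @param effect_log_ors per-unit log odds ratios of the latent factors.
#' @param subtype_log_ors subtype log odds ratios versus Normal-like.
#' @param target_response_rate marginal responder fraction to calibrate the
#'   model intercept against.
#' @param p_shift subtype-specific shift of the proliferation latent
#'   (proliferative subtypes elevated).
#' @param genes_per_metagene member-gene counts per metagene.
#' @param probes_per_gene probe sets per gene.
#' @param noise_sd_gene,noise_sd_probe gene- and probe-level noise SD (log2).
#' @param n_marker_genes subtype marker genes used for centroid classification.
#' @param marker_sd SD of marker centroid values across genes/subtypes.
#' @param n_batches number of datasets/batches.
#' @param batch_shift_sd SD of the per-probe additive batch shifts.
#' @param rcb_missing_rate fraction of samples whose RCB is withheld so the
#'   response must be recovered from the pCR flag.
#' @param seed integer seed threaded to all stochastic components.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 680,
                       subtype_freqs = c(Basal = 0.30, LumA = 0.31,
                                         LumB = 0.19, `HER2-E` = 0.11,
                                         `Claudin-low` = 0.07,
                                         `Normal-like` = 0.02),
                       spearman_latent = default_latent_spearman(),
                       effect_log_ors = c(BP = log(1.60), TNK = log(1.59),
                                          MD = log(1.69), P = log(2.54)),
                       subtype_log_ors = c(Basal = log(1.33),
                                           `Claudin-low` = log(1.12),
                                           `HER2-E` = log(1.08),
                                           LumA = log(0.18),
                                           LumB = log(0.55),
                                           `Normal-like` = 0),
                       target_response_rate = 0.27,
                       p_shift = c(Basal = 0.8, LumA = -0.5, LumB = 0.5,
                                   `HER2-E` = 0.6, `Claudin-low` = 0,
                                   `Normal-like` = -0.8),
                       genes_per_metagene = c(BP = 40, TNK = 46, MD = 19,
                                              P = 54),
                       probes_per_gene = 2,
                       noise_sd_gene = 0.5,
                       noise_sd_probe = 0.5,
                       n_marker_genes = 50,
                       marker_sd = 1,
                       n_batches = 5,
                       batch_shift_sd = 0.3,
                       rcb_missing_rate = 0.10,
                       seed = 20140101L) {
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_freqs = subtype_freqs,
              spearman_latent = spearman_latent,
              effect_log_ors = effect_log_ors,
              subtype_log_ors = subtype_log_ors,
              target_response_rate = target_response_rate,
              p_shift = p_shift,
              genes_per_metagene = genes_per_metagene,
              probes_per_gene = as.integer(probes_per_gene),
              noise_sd_gene = noise_sd_gene,
              noise_sd_probe = noise_sd_probe,
              n_marker_genes = as.integer(n_marker_genes),
              marker_sd = marker_sd,
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              rcb_missing_rate = rcb_missing_rate,
              seed = as.integer(seed))
  if (abs(sum(cfg$subtype_freqs) - 1) > 1e-9) {
    stop("subtype_freqs must sum to 1")
  }
  if (any(cfg$subtype_freqs < 0) || any(cfg$subtype_freqs > 1)) {
    stop("subtype_freqs must lie in [0, 1]")
  }
  stopifnot(setequal(names(cfg$subtype_freqs), SUBTYPE_LEVELS),
            setequal(names(cfg$subtype_log_ors), SUBTYPE_LEVELS),
            setequal(names(cfg$p_shift), SUBTYPE_LEVELS),
            identical(dim(cfg$spearman_latent), c(4L, 4L)))
  if (max(abs(cfg$spearman_latent - t(cfg$spearman_latent))) > 1e-12) {
    stop("spearman_latent must be symmetric")
  }
  if (min(eigen(.spearman_to_pearson(cfg$spearman_latent),
                symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("latent correlation target is not positive semi-definite")
  }
  structure(cfg, class = "sim_config")
}

# Gaussian-copula conversion: the Pearson correlation of a bivariate normal
# whose population Spearman correlation equals rho.
.spearman_to_pearson <- function(s) {
  p <- 2 * sin(pi * s / 6)
  diag(p) <- 1
  p
}

# Draw latent factors and subtype labels; shared by the simulator and the
# intercept calibration so both sample from the same population.
.draw_latents <- function(config, n) {
  subtype <- sample(names(config$subtype_freqs), n, replace = TRUE,
                    prob = config$subtype_freqs)
  sigma <- .spearman_to_pearson(config$spearman_latent)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(sigma)
  colnames(z) <- colnames(config$spearman_latent)
  z[, "P"] <- z[, "P"] + config$p_shift[subtype]
  list(latent = z, subtype = subtype)
}

.linear_predictor <- function(config, latent, subtype, intercept) {
  beta <- config$effect_log_ors[colnames(latent)]
  intercept + as.vector(latent %*% beta) + config$subtype_log_ors[subtype]
}

#' Calibrate the response-model intercept to a target prevalence
#'
#' Root-finds the intercept so that the marginal responder probability,
#' averaged over a large Monte-Carlo draw from the latent/subtype
#' population, equals the configured target.
#'
#' @param config a `sim_config`.
#' @param n_draws Monte-Carlo sample size.
#' @return scalar intercept (log odds).
#' @export
calibrate_intercept <- function(config, n_draws = 1e5) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed((config$seed %% 1000000007L) + 77003L)
  pop <- .draw_latents(config, n_draws)
  eta0 <- .linear_predictor(config, pop$latent, pop$subtype, 0)
  f <- function(b0) mean(stats::plogis(b0 + eta0)) - config$target_response_rate
  if (f(-30) > 0 || f(30) < 0) {
    stop("target response rate unreachable under the configured effects")
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a synthetic neoadjuvant cohort
#'
#' Generates, in one seeded pass: latent metagene factors from a Gaussian
#' copula, subtype labels with subtype-shifted proliferation, a Bernoulli
#' response from a calibrated logistic model, RCB/pCR outcome fields coded so
#' that [code_response()] recovers the drawn response, ER/HER2 status
#' (ER negatively associated with Basal), treatment categories, and a
#' probe-level log2 expression matrix (signature genes driven by the latent
#' factors, subtype marker genes driven by generative centroids, per-gene
#' baselines, per-probe affinities, gene/probe noise, additive per-probe
#' batch shifts).
#'
#' @param config a `sim_config`.
#' @return object of class `synthetic_cohort`: list with `expr`
#'   (probe-by-sample matrix), `batch` (named vector), `clinical`
#'   (data.frame), `truth` (latents, true subtype, response probability),
#'   `signatures` (a `signature_set` for the synthetic panel), `probe_map`,
#'   `centroids` (generative marker-gene means, gene-by-subtype),
#'   `intercept`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  b0 <- calibrate_intercept(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  pop <- .draw_latents(config, n)
  latent <- pop$latent
  subtype <- pop$subtype
  eta <- .linear_predictor(config, latent, subtype, b0)
  prob <- stats::plogis(eta)
  response <- stats::rbinom(n, 1, prob)

  # clinical outcome fields: RCB 0/1 for responders, 2/3 otherwise; a
  # fraction of samples lose their RCB and keep only the pCR flag
  rcb <- ifelse(response == 1, sample(0:1, n, replace = TRUE),
                sample(2:3, n, replace = TRUE))
  pcr <- ifelse(rcb == 0, "yes", "no")
  hide <- stats::runif(n) < config$rcb_missing_rate
  pcr[hide] <- ifelse(response[hide] == 1, "yes", "no")
  rcb[hide] <- NA

  er_pos_prob <- c(Basal = 0.10, LumA = 0.95, LumB = 0.90, `HER2-E` = 0.30,
                   `Claudin-low` = 0.20, `Normal-like` = 0.70)
  her2_pos_prob <- c(Basal = 0.04, LumA = 0.04, LumB = 0.04, `HER2-E` = 0.55,
                     `Claudin-low` = 0.04, `Normal-like` = 0.04)
  er <- ifelse(stats::runif(n) < er_pos_prob[subtype], "positive", "negative")
  her2 <- ifelse(stats::runif(n) < her2_pos_prob[subtype], "positive",
                 "negative")
  treat_freq <- c(FAC = 74, `FAC+paclitaxel` = 236, `FAC+docetaxel` = 61,
                  FEC = 33, `FEC+paclitaxel` = 73, paclitaxel = 65,
                  docetaxel = 39, unspecified = 120)
  treatment <- sample(names(treat_freq), n, replace = TRUE,
                      prob = treat_freq / sum(treat_freq))

  # --- expression layer ---
  codes <- names(config$genes_per_metagene)
  gene_tab <- data.frame(
    gene_symbol = unlist(lapply(codes, function(m)
      sprintf("%sG%02d", m, seq_len(config$genes_per_metagene[[m]])))),
    metagene = rep(codes, config$genes_per_metagene[codes]))
  n_sig_genes <- nrow(gene_tab)
  baseline <- stats::rnorm(n_sig_genes, mean = 8, sd = 1)
  gene_vals <- baseline +
    t(latent[, gene_tab$metagene, drop = FALSE]) +
    matrix(stats::rnorm(n_sig_genes * n, sd = config$noise_sd_gene),
           n_sig_genes, n)
  rownames(gene_vals) <- gene_tab$gene_symbol

  marker_genes <- sprintf("MKG%03d", seq_len(config$n_marker_genes))
  centroids <- matrix(stats::rnorm(config$n_marker_genes * length(SUBTYPE_LEVELS),
                                   mean = 8, sd = config$marker_sd),
                      config$n_marker_genes, length(SUBTYPE_LEVELS),
                      dimnames = list(marker_genes, SUBTYPE_LEVELS))
  marker_vals <- centroids[, subtype, drop = FALSE] +
    matrix(stats::rnorm(config$n_marker_genes * n, sd = config$noise_sd_gene),
           config$n_marker_genes, n)
  rownames(marker_vals) <- marker_genes

  all_gene_vals <- rbind(gene_vals, marker_vals)
  gene_meta <- c(gene_tab$metagene, rep(NA_character_, length(marker_genes)))
  all_genes <- rownames(all_gene_vals)

  ppg <- config$probes_per_gene
  probe_map <- data.frame(
    probe_id = sprintf("%s_p%d_at", rep(all_genes, each = ppg),
                       rep(seq_len(ppg), length(all_genes))),
    gene_symbol = rep(all_genes, each = ppg),
    metagene = rep(gene_meta, each = ppg))
  affinity <- stats::rnorm(nrow(probe_map), sd = 0.3)
  expr <- all_gene_vals[probe_map$gene_symbol, , drop = FALSE] + affinity +
    matrix(stats::rnorm(nrow(probe_map) * n, sd = config$noise_sd_probe),
           nrow(probe_map), n)
  rownames(expr) <- probe_map$probe_id
  colnames(expr) <- sample_ids

  batch <- sample(sprintf("batch%d", seq_len(config$n_batches)), n,
                  replace = TRUE)
  names(batch) <- sample_ids
  if (config$n_batches > 1 && config$batch_shift_sd > 0) {
    delta <- matrix(stats::rnorm(nrow(expr) * config$n_batches,
                                 sd = config$batch_shift_sd),
                    nrow(expr), config$n_batches,
                    dimnames = list(NULL, sprintf("batch%d",
                                                  seq_len(config$n_batches))))
    expr <- expr + delta[, batch]
  }

  sig_entries <- data.frame(
    probe_id = probe_map$probe_id[!is.na(probe_map$metagene)],
    gene_symbol = probe_map$gene_symbol[!is.na(probe_map$metagene)],
    metagene = metagene_label(probe_map$metagene[!is.na(probe_map$metagene)]))
  signatures <- signature_set(sig_entries)

  clinical <- data.frame(sample_id = sample_ids, rcb = rcb, pcr = pcr,
                         er_status = er, her2_status = her2,
                         treatment = treatment, subtype = subtype,
                         stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, latent, subtype = subtype,
                      response_prob = prob, response = response)

  structure(list(expr = expr, batch = batch, clinical = clinical,
                 truth = truth, signatures = signatures,
                 probe_map = probe_map, centroids = centroids,
                 intercept = b0, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d probes, %d batches, seed %d\n",
              ncol(x$expr), nrow(x$expr), length(unique(x$batch)),
              x$config$seed))
  cat(sprintf("  responders: %d (%.1f%%), intercept %.4f\n",
              sum(x$truth$response), 100 * mean(x$truth$response),
              x$intercept))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv` (probe-by-sample matrix), `clinical.csv`,
#' `truth.csv`, `sample_batches.csv` and `signatures.tsv` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = names(cohort$batch),
                              batch = unname(cohort$batch)),
                   file.path(dir, "sample_batches.csv"), row.names = FALSE)
  utils::write.table(cohort$signatures$entries,
                     file.path(dir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
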