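#' Merge metagene scores and clinical covariates for modelling
#'
#' Builds the analysis data.frame: score columns joined to the clinical
#' table, the subtype as a factor with Normal-like as reference, an
#' `er_neg` indicator (negative versus positive), and one binary indicator
#' column per subtype (`st_Basal`, `st_LumA`, ...) for models that enter the
#' subtypes individually.
#'
#' @param scores sample-by-metagene matrix from [score_metagenes()].
#' @param clinical clinical data.frame (after [code_response()]).
#' @return data.frame, one row per scored sample present in both inputs.
#' @export
prepare_model_data <- function(scores, clinical) {
  sc <- data.frame(sample_id = rownames(scores), scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  d <- merge(sc, clinical, by = "sample_id", sort = TRUE)
  if (!is.null(d$subtype)) {
    d$subtype <- factor(d$subtype,
                        levels = c("Normal-like",
                                   setdiff(SUBTYPE_LEVELS, "Normal-like")))
    for (s in SUBTYPE_LEVELS) {
      d[[paste0("st_", gsub("[^A-Za-z0-9]", "", s))]] <-
        ifelse(is.na(d$subtype), NA_integer_,
               as.integer(d$subtype == s))
    }
  }
  if (!is.null(d$er_status)) {
    d$er_neg <- ifelse(is.na(d$er_status), NA_integer_,
                       as.integer(d$er_status == "negative"))
  }
  d
}

#' Collapse treatment categories to regimen classes
#'
#' Maps the detailed regimen labels onto four classes for the
#' treatment-by-response contingency test: anthracycline only (FAC, FEC),
#' anthracycline plus paclitaxel, anthracycline plus docetaxel, and taxane
#' only; unspecified treatment becomes `NA`.
#'
#' @param treatment character vector of regimen labels.
#' @return factor with four levels.
#' @export
treatment_class <- function(treatment) {
  map <- c(FAC = "anthracycline",
           FEC = "anthracycline",
           `FAC+paclitaxel` = "anthracycline+paclitaxel",
           `FEC+paclitaxel` = "anthracycline+paclitaxel",
           `FAC+docetaxel` = "anthracycline+docetaxel",
           paclitaxel = "taxane only",
           docetaxel = "taxane only")
  factor(unname(map[as.character(treatment)]),
         levels = c("anthracycline", "anthracycline+paclitaxel",
                    "anthracycline+docetaxel", "taxane only"))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> duplicate removal -> outlier filter -> quantile
#' normalization -> batch adjustment -> metagene scoring -> subtype
#' classification -> response coding -> regression tables, and writes the
#' report CSVs plus a JSON run manifest.
#'
#' @param out_dir output directory for report files (created if absent);
#'   `NULL` to skip writing.
#' @param config a `sim_config` describing the cohort to simulate.
#' @param dedup_threshold,outlier_k,min_stratum_n tuning knobs forwarded to
#'   the respective stages.
#' @return list with all result tables, the manifest, and the intermediate
#'   objects (`scores`, `model_data`, `subtype_calls`).
#' @export
run_analysis <- function(out_dir = NULL, config = sim_config(),
                         dedup_threshold = 0.99, outlier_k = 3,
                         min_stratum_n = 10) {
  manifest <- list(seed = config$seed,
                   tool_version = as.character(utils::packageVersion("immunemeta")),
                   counts = list())
  cohort <- simulate_cohort(config)
  x <- cohort$expr
  manifest$counts$input <- ncol(x)

  dd <- dedup_profiles(x, threshold = dedup_threshold)
  x <- dd$matrix
  manifest$counts$unique <- ncol(x)

  fo <- filter_outliers(x, k = outlier_k)
  x <- fo$matrix
  manifest$counts$post_outlier <- ncol(x)

  x <- quantile_normalize(x)
  x <- combat_adjust(x, cohort$batch)

  scores <- score_metagenes(x, cohort$signatures)
  gene_matrix <- collapse_to_genes(x, cohort$probe_map)
  subtype_calls <- classify_subtype(gene_matrix, cohort$centroids)

  clinical <- code_response(cohort$clinical)
  clinical <- clinical[clinical$sample_id %in% colnames(x), , drop = FALSE]
  d <- prepare_model_data(scores, clinical)
  manifest$counts$scored <- nrow(d)
  manifest$counts$annotated <- sum(!is.na(d$response))

  table1 <- summarize_cohort(clinical)
  table2_univariate <- univariate_response_table(d)
  table2_adjusted <- adjusted_response_table(d)

  tertiles <- assign_tertiles(d$P)
  table3 <- stratified_analysis(d, tertiles, min_n = min_stratum_n)
  table4 <- stratified_analysis(d, d$subtype, min_n = min_stratum_n)

  sw_vars6 <- c("er_neg", "P", "BP", "TNK", "MD", "subtype")
  sw_vars11 <- c("er_neg", "P", "BP", "TNK", "MD",
                 paste0("st_", gsub("[^A-Za-z0-9]", "", SUBTYPE_LEVELS)))
  manifest$counts$complete_case_6var <-
    sum(stats::complete.cases(d[c("response", sw_vars6)]))
  table5 <- stepwise_select(d, sw_vars6)
  table6 <- stepwise_select(d, sw_vars11)

  spearman <- spearman_matrix(d[, c("BP", "TNK", "MD", "P")])
  tc <- treatment_class(d$treatment)
  keep <- !is.na(tc) & !is.na(d$response)
  chisq <- chisq_independence(table(tc[keep], d$response[keep]))

  counts <- unlist(manifest$counts)
  if (any(diff(counts[c("input", "unique", "post_outlier", "scored",
                        "annotated")]) > 0)) {
    stop("manifest counts must be non-increasing along the filtering chain")
  }

  res <- list(table1 = table1, table2_univariate = table2_univariate,
              table2_adjusted = table2_adjusted, table3 = table3,
              table4 = table4, table5 = table5, table6 = table6,
              spearman = spearman, chisq = chisq, manifest = manifest,
              scores = scores, model_data = d,
              subtype_calls = subtype_calls,
              dedup_report = dd$report, outlier_report = fo$report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
    wr(table1, "table1_summary.csv")
    wr(table2_univariate, "table2_univariate.csv")
    wr(table2_adjusted, "table2_adjusted.csv")
    wr(table3, "table3_tertiles.csv")
    wr(table4, "table4_subtypes.csv")
    sw_csv <- function(sw) {
      tt <- sw$fit$terms
      data.frame(variable = tt$term, odds_ratio = tt$odds_ratio,
                 ci_low = tt$ci_low, ci_high = tt$ci_high,
                 p_value = tt$p_wald, n = sw$n_used,
                 converged = sw$fit$converged)
    }
    wr(sw_csv(table5), "table5_stepwise.csv")
    wr(sw_csv(table6), "table6_stepwise.csv")
    utils::write.csv(data.frame(metagene = rownames(spearman), spearman,
                                check.names = FALSE),
                     file.path(out_dir, "spearman.csv"), row.names = FALSE)
    manifest$chisq <- chisq[c("statistic", "df", "p")]
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
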