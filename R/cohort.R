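#' Read a per-sample clinical table
#'
#' CSV with columns `sample_id`, `rcb` (0-3 or empty), `pcr` (yes/no/empty),
#' `er_status`, `her2_status`, `treatment`, `subtype`. Empty strings and
#' "uncertain" entries become `NA` (complete-case analyses drop them).
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.csv(path, header = TRUE,
                         na.strings = c("", "NA", "uncertain", "unspecified"),
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "rcb", "pcr", "er_status", "her2_status",
            "treatment")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample_id in clinical table")
  if (any(!is.na(tab$rcb) & !tab$rcb %in% 0:3)) stop("rcb must be 0-3 or missing")
  tab
}

#' Derive the binary tumor-response outcome
#'
#' Residual cancer burden (RCB) class 0 or 1, or a pathologic complete
#' response (pCR) when no RCB score was assigned, is coded `1` (responder).
#' Any other non-missing outcome information codes `0`; samples with neither
#' RCB nor pCR stay missing. When RCB and the pCR flag contradict each other
#' RCB wins (it is the finer-grained measure) and a warning is emitted.
#'
#' @param table clinical data.frame with `rcb` and `pcr` columns.
#' @return the same data.frame with a `response` column (1/0/NA).
#' @export
code_response <- function(table) {
  rcb <- table$rcb
  pcr <- tolower(as.character(table$pcr))
  pcr[!pcr %in% c("yes", "no")] <- NA
  response <- rep(NA_integer_, nrow(table))
  response[!is.na(rcb) & rcb %in% c(0, 1)] <- 1L
  response[!is.na(rcb) & rcb %in% c(2, 3)] <- 0L
  response[is.na(rcb) & pcr == "yes"] <- 1L
  response[is.na(rcb) & pcr == "no"] <- 0L
  # RCB 0 is itself a pCR, and any residual disease (RCB 1-3) rules one out
  contra <- (!is.na(rcb) & !is.na(pcr)) &
    ((rcb == 0 & pcr == "no") | (rcb %in% c(1, 2, 3) & pcr == "yes"))
  if (any(contra)) {
    warning(sum(contra), " sample(s) with contradictory RCB/pCR; coded by RCB")
  }
  table$response <- response
  table
}

#' Cohort characteristics summary
#'
#' Category counts and integer percentages (of the total cohort, half-up
#' rounding) for each clinical characteristic, with missingness shown as its
#' own `unspecified` category so every characteristic sums to the cohort size.
#'
#' @param table clinical data.frame (after [code_response()] if response
#'   counts are wanted).
#' @param characteristics columns to summarize; defaults to those present.
#' @return data.frame with `characteristic`, `category`, `n`, `percent`.
#' @export
summarize_cohort <- function(table,
                             characteristics = intersect(
                               c("age_group", "treatment", "response",
                                 "er_status", "her2_status", "subtype"),
                               names(table))) {
  total <- nrow(table)
  rows <- lapply(characteristics, function(ch) {
    v <- as.character(table[[ch]])
    v[is.na(v)] <- "unspecified"
    tt <- table(v)
    if (length(tt) == 0L) return(NULL)
    data.frame(characteristic = ch, category = names(tt),
               n = as.integer(tt),
               percent = if (total > 0)
                 round_half_up(100 * as.integer(tt) / total) else 0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(characteristic = character(0), category = character(0),
                      n = integer(0), percent = numeric(0))
  }
  rownames(out) <- NULL
  out
}
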