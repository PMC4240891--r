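# Internal helpers shared across modules.

# Canonical metagene codes (syntactic, used for matrix/data.frame columns)
# and their display labels (used in signature files and report tables).
METAGENE_LABELS <- c(BP = "B/P", TNK = "T/NK", MD = "M/D", P = "P")

SUBTYPE_LEVELS <- c("Basal", "LumA", "LumB", "HER2-E", "Claudin-low", "Normal-like")

#' @keywords internal
metagene_code <- function(x) {
  codes <- names(METAGENE_LABELS)
  out <- ifelse(x %in% codes, x, codes[match(x, METAGENE_LABELS)])
  if (anyNA(out)) {
    stop("unknown metagene name(s): ", paste(x[is.na(out)], collapse = ", "))
  }
  out
}

#' @keywords internal
metagene_label <- function(x) {
  unname(METAGENE_LABELS[metagene_code(x)])
}

# round() uses banker's rounding; report tables use conventional half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop(what, ": duplicated probe ids")
  if (anyDuplicated(colnames(x))) stop(what, ": duplicated sample ids")
  invisible(x)
}
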