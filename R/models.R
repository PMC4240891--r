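#' Fit a binomial logistic regression with odds-ratio output
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) on the complete cases of the requested terms. Coefficients are
#' reported as odds ratios with 95% Wald confidence intervals; continuous
#' metagene terms are per unit of raw (uncentered) mean log2 intensity.
#'
#' @param data data.frame holding the outcome and covariates.
#' @param terms character vector of model terms (column names; factors are
#'   expanded against their declared reference level).
#' @param outcome name of the 0/1 outcome column.
#' @return object of class `logistic_fit`: list with `terms` (data.frame
#'   `term`, `estimate`, `se`, `odds_ratio`, `ci_low`, `ci_high`, `p_wald`),
#'   `loglik`, `n_used`, `n_dropped`, `converged`, `term_labels`, `model`.
#' @export
fit_logistic <- function(data, terms, outcome = "response") {
  stopifnot(is.data.frame(data), length(outcome) == 1L)
  vars <- unique(c(outcome, terms))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[vars])
  d <- droplevels(data[cc, vars, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) message(n_dropped, " incomplete case(s) dropped")
  form <- if (length(terms)) stats::reformulate(terms, response = outcome)
          else stats::as.formula(paste(outcome, "~ 1"))
  fit <- suppressWarnings(
    stats::glm(form, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (fit$rank < length(stats::coef(fit))) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear term(s): ", paste(alias, collapse = ", "))
  }
  if (nrow(d) <= length(stats::coef(fit))) {
    stop("fewer usable cases than model terms")
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  # perfect or quasi-separation: boundary fitted probabilities together with
  # degenerate Wald information (diverging coefficients or exploding SEs)
  separated <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8) &&
    (any(abs(est) > 10) || max(se) > 100)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    odds_ratio = exp(unname(est)),
                    ci_low = exp(unname(est - z * se)),
                    ci_high = exp(unname(est + z * se)),
                    p_wald = 2 * stats::pnorm(-abs(unname(est / se))))
  structure(list(terms = tab,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_used = nrow(d),
                 n_dropped = n_dropped,
                 converged = fit$converged && !separated,
                 term_labels = terms,
                 outcome = outcome,
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: n = %d (%d dropped), logLik = %.3f%s\n",
              x$n_used, x$n_dropped, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full `logistic_fit` for the larger model.
#' @param reduced `logistic_fit` for the nested model (same samples).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_pvalue <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (!all(reduced$term_labels %in% full$term_labels)) {
    stop("models are not nested: reduced terms must be a subset of full terms")
  }
  if (full$n_used != reduced$n_used) {
    stop("models were fit on different samples (n = ", full$n_used,
         " vs ", reduced$n_used, ")")
  }
  df <- nrow(full$terms) - nrow(reduced$terms)
  if (df < 0L) stop("full model has fewer parameters than reduced model")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p = if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

# Fit full and reduced models on the complete cases of the FULL variable set
# so the LRT compares like with like.
.fit_pair_lrt <- function(data, full_terms, reduced_terms, outcome) {
  vars <- unique(c(outcome, full_terms))
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, , drop = FALSE]
  full <- fit_logistic(d, full_terms, outcome)
  reduced <- fit_logistic(d, reduced_terms, outcome)
  list(full = full, reduced = reduced, lrt = lrt_pvalue(full, reduced))
}

.or_row <- function(variable, fit, term_match, p, n) {
  i <- grep(term_match, fit$terms$term)[1]
  data.frame(variable = variable,
             odds_ratio = fit$terms$odds_ratio[i],
             ci_low = fit$terms$ci_low[i],
             ci_high = fit$terms$ci_high[i],
             p_value = p, n = n, converged = fit$converged)
}

#' Univariate associations with tumor response
#'
#' One simple logistic model per metagene (continuous) and one model with
#' intrinsic subtype as a categorical covariate (reference Normal-like).
#' P-values are likelihood-ratio tests against the intercept-only model on
#' the same samples; subtype rows additionally carry per-level Wald tests
#' versus the reference.
#'
#' @param data data.frame with metagene score columns, a `subtype` factor and
#'   the outcome.
#' @param metagenes score columns to test.
#' @param subtype name of the subtype column (`NULL` to skip).
#' @param outcome outcome column name.
#' @return data.frame with columns `variable`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `converged`.
#' @export
univariate_response_table <- function(data,
                                      metagenes = c("BP", "TNK", "MD", "P"),
                                      subtype = "subtype",
                                      outcome = "response") {
  rows <- list()
  for (mg in metagenes) {
    pr <- .fit_pair_lrt(data, mg, character(0), outcome)
    rows[[mg]] <- .or_row(metagene_label(mg), pr$full, paste0("^", mg, "$"),
                          pr$lrt$p, pr$full$n_used)
  }
  if (!is.null(subtype) && subtype %in% names(data)) {
    pr <- .fit_pair_lrt(data, subtype, character(0), outcome)
    fit <- pr$full
    rows[["subtype"]] <- data.frame(
      variable = "subtype", odds_ratio = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = pr$lrt$p, n = fit$n_used,
      converged = fit$converged)
    lev <- fit$terms[grepl(paste0("^", subtype), fit$terms$term), ,
                     drop = FALSE]
    if (nrow(lev)) {
      rows[["subtype_levels"]] <- data.frame(
        variable = paste0("subtype:", sub(paste0("^", subtype), "",
                                          lev$term)),
        odds_ratio = lev$odds_ratio, ci_low = lev$ci_low,
        ci_high = lev$ci_high, p_value = lev$p_wald, n = fit$n_used,
        converged = fit$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immune metagene associations adjusted for proliferation and subtype
#'
#' For each immune metagene, fits `outcome ~ immune + P + subtype` and
#' reports the immune term's adjusted odds ratio with a likelihood-ratio
#' p-value against the model without the immune term.
#'
#' @inheritParams univariate_response_table
#' @param immune immune metagene columns.
#' @param proliferation proliferation score column.
#' @return data.frame in the same shape as [univariate_response_table()].
#' @export
adjusted_response_table <- function(data,
                                    immune = c("BP", "TNK", "MD"),
                                    proliferation = "P",
                                    subtype = "subtype",
                                    outcome = "response") {
  adj <- c(proliferation,
           if (!is.null(subtype) && subtype %in% names(data)) subtype)
  rows <- lapply(immune, function(mg) {
    pr <- .fit_pair_lrt(data, c(mg, adj), adj, outcome)
    .or_row(metagene_label(mg), pr$full, paste0("^", mg, "$"),
            pr$lrt$p, pr$full$n_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified univariate response analysis
#'
#' Within each stratum (proliferation tertile or intrinsic subtype), fits a
#' simple logistic model per immune metagene. Stratum headers report the
#' number of annotated cases, responders and nonresponders; strata with
#' fewer than `min_n` annotated cases are reported but their models skipped.
#'
#' @param data data.frame with score columns and the outcome.
#' @param strata factor of stratum labels aligned with `data` rows (labels
#'   computed on the full scored cohort; models use the annotated subset).
#' @param metagenes score columns to test within each stratum.
#' @param min_n minimum annotated cases for model fitting.
#' @param outcome outcome column name.
#' @return data.frame with `stratum`, `n`, `responders`, `nonresponders`,
#'   `variable`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `skipped`.
#' @export
stratified_analysis <- function(data, strata,
                                metagenes = c("BP", "TNK", "MD"),
                                min_n = 10, outcome = "response") {
  stopifnot(length(strata) == nrow(data))
  strata <- factor(strata)
  rows <- list()
  for (s in levels(strata)) {
    idx <- which(strata == s)
    sub <- data[idx, , drop = FALSE]
    ann <- sub[!is.na(sub[[outcome]]), , drop = FALSE]
    n <- nrow(ann)
    pr <- sum(ann[[outcome]] == 1)
    nr <- sum(ann[[outcome]] == 0)
    if (n < min_n) {
      message("stratum '", s, "' has ", n, " annotated cases (< ", min_n,
              "); models skipped")
      rows[[s]] <- data.frame(stratum = s, n = n, responders = pr,
                              nonresponders = nr, variable = metagene_label(metagenes),
                              odds_ratio = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p_value = NA_real_,
                              skipped = TRUE)
      next
    }
    rows[[s]] <- do.call(rbind, lapply(metagenes, function(mg) {
      fp <- .fit_pair_lrt(ann, mg, character(0), outcome)
      r <- .or_row(metagene_label(mg), fp$full, paste0("^", mg, "$"),
                   fp$lrt$p, fp$full$n_used)
      data.frame(stratum = s, n = n, responders = pr, nonresponders = nr,
                 variable = r$variable, odds_ratio = r$odds_ratio,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 p_value = r$p_value, skipped = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise logistic regression with likelihood-ratio criteria
#'
#' Forward selection with backward removal: at each step the candidate with
#' the smallest likelihood-ratio p-value below `alpha_enter` is added, then
#' any included term whose removal p-value exceeds `alpha_stay` is dropped
#' (worst first). Candidates are scanned in lexicographic order, which also
#' breaks exact ties. Factor candidates enter and leave as whole terms
#' (multi-degree-of-freedom tests). All fits use the complete cases of the
#' full candidate set so every comparison shares the same samples.
#'
#' @param data data.frame with candidates and outcome.
#' @param candidates character vector of candidate term names.
#' @param alpha_enter entry threshold on the LRT p-value.
#' @param alpha_stay stay threshold on the LRT p-value.
#' @param outcome outcome column name.
#' @return object of class `stepwise_result`: list with `selected` (ordered
#'   term names), `log` (data.frame `step`, `action`, `term`, `p`), `fit`
#'   (final `logistic_fit`), `n_used`.
#' @export
stepwise_select <- function(data, candidates, alpha_enter = 0.05,
                            alpha_stay = 0.05, outcome = "response") {
  stopifnot(length(candidates) >= 1L)
  candidates <- sort(unique(candidates))
  vars <- unique(c(outcome, candidates))
  cc <- stats::complete.cases(data[vars])
  d <- droplevels(data[cc, vars, drop = FALSE])
  selected <- character(0)
  log <- data.frame(step = integer(0), action = character(0),
                    term = character(0), p = numeric(0))
  step_i <- 0L
  seen <- character(0)
  repeat {
    changed <- FALSE
    # entry scan
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      base <- fit_logistic(d, selected, outcome)
      # candidates that are constant or collinear given the current model
      # cannot be evaluated and are passed over
      ps <- vapply(pool, function(tm) {
        tryCatch(lrt_pvalue(fit_logistic(d, c(selected, tm), outcome),
                            base)$p,
                 error = function(e) NA_real_)
      }, numeric(1))
      if (any(is.finite(ps)) && min(ps, na.rm = TRUE) < alpha_enter) {
        ps[!is.finite(ps)] <- Inf
        tm <- pool[which.min(ps)]
        selected <- c(selected, tm)
        step_i <- step_i + 1L
        log <- rbind(log, data.frame(step = step_i, action = "enter",
                                     term = tm, p = min(ps)))
        changed <- TRUE
      }
    }
    # removal scan
    repeat {
      if (length(selected) == 0L) break
      full <- fit_logistic(d, selected, outcome)
      ps <- vapply(selected, function(tm) {
        lrt_pvalue(full, fit_logistic(d, setdiff(selected, tm), outcome))$p
      }, numeric(1))
      if (max(ps) > alpha_stay) {
        tm <- selected[which.max(ps)]
        selected <- setdiff(selected, tm)
        step_i <- step_i + 1L
        log <- rbind(log, data.frame(step = step_i, action = "remove",
                                     term = tm, p = max(ps)))
        changed <- TRUE
      } else break
    }
    key <- paste(sort(selected), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  structure(list(selected = selected, log = log,
                 fit = fit_logistic(d, selected, outcome),
                 n_used = nrow(d)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise_result: selected",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(none)", sprintf("[n = %d]\n", x$n_used))
  if (nrow(x$log)) print(x$log)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' @param table contingency matrix of non-negative counts (e.g. treatment by
#'   response).
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("contingency table must hold non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal row/column in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Pairwise Spearman correlations among metagene scores
#'
#' @param scores sample-by-metagene matrix or data.frame (>= 3 complete
#'   rows). Constant columns yield `NA` rows/columns with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (sum(stats::complete.cases(m)) < 3L) {
    stop("need at least 3 samples with complete scores")
  }
  const <- apply(m, 2, function(v) {
    v <- v[is.finite(v)]
    length(v) > 0 && all(v == v[1])
  })
  if (any(const)) {
    warning("constant score column(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined")
  }
  out <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(out) <- ifelse(const, NA_real_, 1)
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out)[!const] <- 1
  out
}
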