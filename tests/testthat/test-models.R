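test_that("logistic fits reproduce closed-form 2x2 odds ratios and Wald CIs", {
  d <- two_by_two_data(20, 80, 10, 90)
  fit <- fit_logistic(d, "exposure")
  or <- (20 * 90) / (80 * 10)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  row <- fit$terms[fit$terms$term == "exposure", ]
  expect_equal(row$odds_ratio, or, tolerance = 1e-6)
  expect_equal(row$se, se, tolerance = 1e-6)
  expect_equal(row$ci_low, exp(log(or) - qnorm(0.975) * se), tolerance = 1e-6)
  expect_equal(row$ci_high, exp(log(or) + qnorm(0.975) * se), tolerance = 1e-6)
  expect_true(row$ci_low < row$odds_ratio && row$odds_ratio < row$ci_high)
  expect_lte(fit$loglik, 0)

  # no association: OR exactly 1
  d0 <- two_by_two_data(15, 85, 15, 85)
  fit0 <- fit_logistic(d0, "exposure")
  expect_equal(fit0$terms$odds_ratio[2], 1, tolerance = 1e-8)
})

test_that("maximized likelihood matches a grid-search oracle", {
  set.seed(41)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(-0.5 + 0.9 * x))
  d <- data.frame(response = y, x = x)
  fit <- fit_logistic(d, "x")
  expect_equal(fit$loglik, grid_loglik_max(x, y), tolerance = 1e-6)
})

test_that("logistic fits handle missing data, separation and singularity", {
  set.seed(42)
  d <- data.frame(response = rbinom(50, 1, 0.4), x = rnorm(50))
  d$x[1:5] <- NA
  expect_message(fit <- fit_logistic(d, "x"), "5 incomplete")
  expect_equal(fit$n_used, 45)
  expect_equal(fit$n_dropped, 5)

  # perfect separation flagged as non-converged
  ds <- data.frame(response = rep(c(0, 1), each = 20),
                   x = c(rnorm(20, -5), rnorm(20, 5)))
  fs <- fit_logistic(ds, "x")
  expect_false(fs$converged)

  # collinear design named in the error
  dc <- data.frame(response = rbinom(100, 1, 0.5), a = rnorm(100))
  dc$b <- 2 * dc$a
  expect_error(fit_logistic(dc, c("a", "b")), "collinear")
})

test_that("likelihood-ratio tests behave as chi-square comparisons of nested fits", {
  set.seed(43)
  d <- data.frame(response = rbinom(80, 1, 0.3), x = rnorm(80))
  full <- fit_logistic(d, "x")
  reduced <- fit_logistic(d, character(0))
  lrt <- lrt_pvalue(full, reduced)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_true(lrt$p >= 0 && lrt$p <= 1)

  # identical models: statistic 0, p = 1
  same <- lrt_pvalue(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # frozen chi-square reference point: statistic 3.84 on 1 df -> p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05004, tolerance = 1e-4)

  # non-nested / different-sample violations
  d2 <- d; d2$z <- rnorm(80)
  expect_error(lrt_pvalue(fit_logistic(d2, "z"), full), "not nested")
  expect_error(lrt_pvalue(fit_logistic(d[1:60, ], "x"), reduced),
               "different samples")
})

test_that("null-model LRT p-values are uniform", {
  set.seed(44)
  ps <- replicate(500, {
    d <- data.frame(response = rbinom(200, 1, 0.3), x = rnorm(200))
    lrt_pvalue(fit_logistic(d, "x"), fit_logistic(d, character(0)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("chi-square independence test matches the hand oracle", {
  # proportional rows: statistic 0
  prop <- rbind(c(10, 20), c(20, 40))
  r0 <- chisq_independence(prop)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  # hand-computed sum((O-E)^2/E): all expected 15, stat = 4 * 25/15
  r1 <- chisq_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(r1$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r1$df, 1)

  # 4x2 table has 3 degrees of freedom
  set.seed(45)
  t42 <- matrix(rpois(8, 30), 4, 2)
  expect_equal(chisq_independence(t42)$df, 3)

  expect_error(chisq_independence(rbind(c(0, 0), c(5, 5))), "marginal")
  expect_error(chisq_independence(rbind(c(-1, 2), c(5, 5))), "non-negative")
})

test_that("spearman matrix matches a rank-then-Pearson oracle", {
  set.seed(46)
  a <- rnorm(40); b <- a + rnorm(40); c <- rnorm(40)
  m <- cbind(BP = a, TNK = b, MD = c)
  S <- spearman_matrix(m)
  expect_equal(S["BP", "TNK"], cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(all(S >= -1 & S <= 1))

  # strictly monotone transform: correlation exactly 1
  expect_equal(spearman_matrix(cbind(a = a, b = exp(a)))["a", "b"], 1)

  # independent large-sample scores decorrelate
  set.seed(47)
  big <- cbind(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(spearman_matrix(big)["x", "y"]), 0.08)

  # constant column flagged undefined
  expect_warning(Sc <- spearman_matrix(cbind(u = a, v = rep(2, 40))),
                 "constant")
  expect_true(all(is.na(Sc["v", ])))
})

test_that("univariate and adjusted tables expose ORs, CIs and LRT p-values", {
  cfg <- sim_config(n_samples = 400, seed = 48)
  sc <- simulate_cohort(cfg)
  scores <- score_metagenes(sc$expr, sc$signatures)
  d <- prepare_model_data(scores, code_response(sc$clinical))

  uni <- univariate_response_table(d)
  expect_true(all(c("B/P", "T/NK", "M/D", "P", "subtype") %in% uni$variable))
  mg <- uni[uni$variable %in% c("B/P", "T/NK", "M/D", "P"), ]
  expect_true(all(mg$ci_low < mg$odds_ratio & mg$odds_ratio < mg$ci_high))
  expect_true(all(mg$p_value >= 0 & mg$p_value <= 1))
  # generative effects are positive: fitted ORs should sit above 1
  expect_true(all(mg$odds_ratio > 1))

  adj <- adjusted_response_table(d)
  expect_equal(adj$variable, c("B/P", "T/NK", "M/D"))
  expect_true(all(adj$ci_low < adj$odds_ratio & adj$odds_ratio < adj$ci_high))

  # orthogonal covariates: adjusted ~ unadjusted (no confounding channel)
  set.seed(49)
  n <- 4000
  dd <- data.frame(BP = rnorm(n), P = rnorm(n),
                   subtype = sample(c("Normal-like", "Basal"), n, TRUE))
  dd$response <- rbinom(n, 1, plogis(-1 + 0.5 * dd$BP))
  dd$subtype <- factor(dd$subtype, levels = c("Normal-like", "Basal"))
  u <- univariate_response_table(dd, metagenes = "BP", subtype = NULL)
  a <- adjusted_response_table(dd, immune = "BP")
  expect_lt(abs(log(u$odds_ratio[1]) - log(a$odds_ratio[1])), 0.1)
})

test_that("adjustment removes confounding carried by proliferation", {
  # immune score independent of outcome given P; marginally confounded
  set.seed(50)
  covered_adj <- covered_unadj <- logical(60)
  for (r in 1:60) {
    n <- 800
    P <- rnorm(n)
    BP <- 0.8 * P + rnorm(n, sd = 0.6)
    y <- rbinom(n, 1, plogis(-1 + 0.9 * P))
    dd <- data.frame(response = y, BP = BP, P = P)
    u <- fit_logistic(dd, "BP")
    a <- fit_logistic(dd, c("BP", "P"))
    ru <- u$terms[u$terms$term == "BP", ]
    ra <- a$terms[a$terms$term == "BP", ]
    covered_unadj[r] <- ru$ci_low <= 1 && 1 <= ru$ci_high
    covered_adj[r] <- ra$ci_low <= 1 && 1 <= ra$ci_high
  }
  expect_gte(mean(covered_adj), 0.93)
  expect_lt(mean(covered_unadj), 0.2)
})

test_that("stratified analysis reports per-stratum counts and skips tiny strata", {
  cfg <- sim_config(n_samples = 450, seed = 51)
  sc <- simulate_cohort(cfg)
  scores <- score_metagenes(sc$expr, sc$signatures)
  d <- prepare_model_data(scores, code_response(sc$clinical))
  tert <- assign_tertiles(d$P)

  tab <- stratified_analysis(d, tert)
  expect_equal(sort(unique(tab$stratum)), c("high", "intermediate", "low"))
  # per-stratum n sums to the annotated total
  hdr <- unique(tab[c("stratum", "n")])
  expect_equal(sum(hdr$n), sum(!is.na(d$response)))
  expect_equal(unique(tab$responders + tab$nonresponders), unique(tab$n))

  # identical strata (same samples in both) give identical per-stratum results
  d2 <- rbind(d, d)
  s2 <- factor(rep(c("g1", "g2"), each = nrow(d)))
  t2 <- suppressMessages(stratified_analysis(d2, s2))
  g1 <- t2[t2$stratum == "g1", -1]; g2 <- t2[t2$stratum == "g2", -1]
  expect_equal(g1, g2, ignore_attr = TRUE)

  # a stratum below the case threshold is reported but skipped
  small <- factor(c(rep("tiny", 5), rep("rest", nrow(d) - 5)))
  expect_message(t3 <- stratified_analysis(d, small), "skipped")
  expect_true(all(t3$skipped[t3$stratum == "tiny"]))
  expect_true(all(is.na(t3$odds_ratio[t3$stratum == "tiny"])))
})

test_that("an effect present only in the high stratum is localized there", {
  set.seed(52)
  hits_high <- hits_low <- logical(40)
  for (r in 1:40) {
    n <- 600
    strat <- factor(rep(c("low", "high"), each = n / 2), c("low", "high"))
    x <- rnorm(n)
    eta <- ifelse(strat == "high", -1 + 0.9 * x, -1)
    y <- rbinom(n, 1, plogis(eta))
    dd <- data.frame(response = y, BP = x)
    tab <- stratified_analysis(dd, strat, metagenes = "BP")
    hi <- tab[tab$stratum == "high", ]; lo <- tab[tab$stratum == "low", ]
    hits_high[r] <- hi$ci_low > 1
    hits_low[r] <- lo$ci_low <= 1 && 1 <= lo$ci_high
  }
  expect_gte(mean(hits_high), 0.80)   # power at the designed n and effect
  expect_gte(mean(hits_low), 0.90)    # nominal coverage of the null stratum
})

test_that("stepwise selection enters true predictors and controls noise entry", {
  set.seed(53)
  nrep <- 100
  true_in <- matrix(FALSE, nrep, 1)
  noise_in <- matrix(FALSE, nrep, 5)
  for (r in 1:nrep) {
    n <- 400
    d <- data.frame(replicate(5, rnorm(n)))
    names(d) <- paste0("noise", 1:5)
    d$signal <- rnorm(n)
    d$response <- rbinom(n, 1, plogis(-1 + 0.8 * d$signal))
    sw <- stepwise_select(d, c("signal", paste0("noise", 1:5)))
    true_in[r, 1] <- "signal" %in% sw$selected
    noise_in[r, ] <- paste0("noise", 1:5) %in% sw$selected
  }
  expect_gte(mean(true_in), 0.95)
  # per-candidate false-entry rate ~ alpha, allow Monte-Carlo slack
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / nrep)
  expect_true(all(colMeans(noise_in) <= bound))
})

test_that("stepwise selection on pure noise is usually empty and always valid", {
  set.seed(54)
  # single null candidate: empty in ~95% of replicates
  empty1 <- replicate(100, {
    d <- data.frame(response = rbinom(300, 1, 0.3), x = rnorm(300))
    length(stepwise_select(d, "x")$selected) == 0
  })
  expect_gte(mean(empty1), 0.85)

  # five null candidates: empty whenever no per-candidate test clears 0.05,
  # i.e. with probability ~0.95^5 ~ 0.77
  empty5 <- replicate(60, {
    d <- data.frame(response = rbinom(300, 1, 0.3))
    for (j in 1:5) d[[paste0("x", j)]] <- rnorm(300)
    length(stepwise_select(d, paste0("x", 1:5))$selected) == 0
  })
  expect_gt(mean(empty5), 0.6)
  expect_lt(mean(empty5), 0.93)

  # empty selection is a valid result with a complete log
  d <- data.frame(response = rbinom(200, 1, 0.3), x = rnorm(200))
  sw <- stepwise_select(d, "x")
  expect_s3_class(sw, "stepwise_result")
  expect_type(sw$selected, "character")
})

test_that("stepwise selection is deterministic and honours the stay criterion", {
  cfg <- sim_config(n_samples = 500, seed = 55)
  sc <- simulate_cohort(cfg)
  scores <- score_metagenes(sc$expr, sc$signatures)
  d <- prepare_model_data(scores, code_response(sc$clinical))
  cand <- c("er_neg", "P", "BP", "TNK", "MD", "subtype")
  sw1 <- stepwise_select(d, cand)
  sw2 <- stepwise_select(d, cand)
  expect_identical(sw1$selected, sw2$selected)
  expect_identical(sw1$log, sw2$log)
  # every retained term satisfies the stay criterion in the final model
  for (tm in sw1$selected) {
    dd <- d[complete.cases(d[c("response", cand)]), ]
    p <- lrt_pvalue(fit_logistic(dd, sw1$selected),
                    fit_logistic(dd, setdiff(sw1$selected, tm)))$p
    expect_lt(p, 0.05)
  }
})
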