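test_that("Fisher's exact test agrees with full enumeration", {
  tab <- matrix(c(2, 0, 0, 2), 2)
  expect_equal(fisher_exact(tab)$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact(tab)$p_value, oracle_fisher_rx2(tab),
               tolerance = 1e-10)

  prop <- matrix(c(4, 8, 2, 4), 2)  # proportional rows
  expect_equal(fisher_exact(prop)$p_value, 1, tolerance = 1e-9)

  smoking <- load_printed_tables()$egfr$smoking
  p <- fisher_exact(smoking)$p_value
  expect_lt(p, 1e-3)
  expect_equal(p, oracle_fisher_rx2(smoking), tolerance = 1e-8)

  expect_error(fisher_exact(matrix(1e5, 2, 2)), "budget")
  expect_error(fisher_exact(matrix(1, 1, 2)), "2x2")
})

test_that("chi-square statistic matches the hand formula", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 100 / 15, tolerance = 1e-12)

  exact <- matrix(c(15, 15, 15, 15), 2)
  res0 <- chi_square_test(exact)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  perm <- tab[2:1, 2:1]
  expect_equal(chi_square_test(perm)$statistic, res$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "expected")
})

test_that("Wilcoxon rank-sum is exact by enumeration at small n", {
  expect_equal(wilcoxon_rank_sum(c(3, 1, 4), c(3, 1, 4))$p_value, 1)
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- wilcoxon_rank_sum(x, y)$p_value
    expect_equal(pe, oracle_wilcoxon(x, y), tolerance = 1e-12)
    pa <- wilcoxon_rank_sum(x, y, exact_limit = 0)$p_value
    expect_lt(abs(pa - pe), 0.02)
    # reference implementation agrees on tie-free data
    expect_equal(pe, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("logistic slope on a binary covariate equals the table log-OR", {
  x <- rep(c(0, 1), times = c(30, 30))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  fit <- fit_logistic(data.frame(x = x), y)
  tab_or <- (10 / 20) / (20 / 10)  # odds(x=0) / odds(x=1) = 0.25
  expect_equal(unname(fit$coefficients["x"]), -log(tab_or), tolerance = 1e-8)
  expect_false(fit$separation)

  expect_error(fit_logistic(data.frame(x = x), rep(1, 60)), "constant")
  expect_error(fit_logistic(data.frame(x = rep(2, 60)), y), "constant")

  sep <- fit_logistic(data.frame(x = c(rep(0, 20), rep(1, 20))),
                      c(rep(0, 20), rep(1, 20)))
  expect_true(sep$separation)
})

test_that("stepwise selection obeys its limiting alphas", {
  set.seed(21)
  n <- 300
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y_null <- rbinom(n, 1, 0.3)
  sw0 <- stepwise_select(d, y_null, entry_p = 0, stay_p = 0)
  expect_length(attr(sw0, "selected"), 0)

  y_sig <- rbinom(n, 1, plogis(-1 + 1.5 * d$a))
  sw_all <- stepwise_select(d, y_sig, entry_p = 1, stay_p = 1)
  expect_setequal(attr(sw_all, "selected"), c("a", "b", "c"))

  # duplicate covariate enters once
  d2 <- data.frame(a = d$a, a_copy = d$a)
  sw_dup <- stepwise_select(d2, y_sig, entry_p = 0.05, stay_p = 0.05)
  expect_length(attr(sw_dup, "selected"), 1)
})

test_that("odds-ratio rescaling is a pure exponent identity", {
  expect_equal(rescale_odds_ratio(0, 10), 1)
  expect_equal(rescale_odds_ratio(0.05, -10), exp(-0.5))
  b <- 0.123
  expect_equal(rescale_odds_ratio(b, -10) * rescale_odds_ratio(b, 10), 1)
})

test_that("ROC AUC equals exhaustive pair concordance", {
  r1 <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(rep(5, 8), c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(r2$auc, 0.5)

  scores <- c(0.9, 0.4, 0.6, 0.2)
  labels <- c(1, 1, 0, 0)
  r3 <- roc_curve(scores, labels)
  expect_equal(r3$auc, 0.75)
  expect_equal(r3$auc, oracle_auc_pairs(scores, labels))

  set.seed(31)
  for (i in 1:10) {
    s <- sample(round(rnorm(40), 1))  # induce ties
    l <- rbinom(40, 1, 0.4)
    if (length(unique(l)) < 2) next
    rr <- roc_curve(s, l)
    expect_equal(rr$auc, oracle_auc_pairs(s, l), tolerance = 1e-12)
    rl <- roc_curve(s, l, direction = "lower")
    expect_equal(rl$auc, oracle_auc_pairs(s, l, "lower"), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  r <- roc_curve(s, l)
  ref <- suppressMessages(pROC::roc(l, s, direction = "<"))
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("sensitivity-targeted cutoff maximizes specificity", {
  r1 <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  op <- threshold_at_sensitivity(r1, 0.8)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  scores <- c(3, 2, 1, 0.5, 0.4, 2.5, 1.5, 0.6, 0.3)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  r2 <- roc_curve(scores, labels)
  op2 <- threshold_at_sensitivity(r2, 0.8)
  expect_gte(op2$sensitivity, 0.8)
  # brute-force scan over all cutpoints
  cand <- sort(unique(scores))
  best <- -1
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens >= 0.8 && spec > best) best <- spec
  }
  expect_equal(op2$specificity, best)

  # target 0 is vacuous: the max-specificity threshold is returned
  op0 <- threshold_at_sensitivity(r2, 0)
  expect_equal(op0$specificity, 1)
})

test_that("Pearson correlation handles affine and degenerate cases", {
  x <- rnorm(20)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, rep(3, 20)), "constant")

  # partition identity: constant BCG forces corr(VIRO, YP) = -1
  set.seed(41)
  viro <- runif(30, 20, 60)
  yp <- 100 - 30 - viro  # BCG fixed at 30
  expect_equal(pearson_correlation(viro, yp), -1)
})

test_that("the single CART split equals the exhaustive search", {
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  feats <- data.frame(good = c(1, 2, 3, 4, 10, 11, 12, 13),
                      flat = rep(1, 8),
                      noise = c(5, 1, 4, 2, 3, 6, 2, 5))
  sp <- recursive_partition_split(feats, y)
  expect_identical(sp$feature, "good")
  expect_equal(sp$impurity, 0)

  set.seed(51)
  f10 <- data.frame(a = rnorm(10), b = rnorm(10), c = sample(1:3, 10, TRUE))
  y10 <- rbinom(10, 1, 0.5)
  if (length(unique(y10)) > 1) {
    got <- recursive_partition_split(f10, y10)
    want <- oracle_best_split(f10, y10)
    expect_identical(got$feature, want$feature)
    expect_equal(got$split, want$split)
    expect_equal(got$impurity, want$impurity)
  }
  expect_error(recursive_partition_split(feats, rep(1, 8)), "both classes")
})

test_that("Kaplan-Meier matches the hand product-limit", {
  km0 <- km_estimator(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  km <- km_estimator(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km_survival_at(km, c(0.5, 1.5, 2.5, 3.5)), c(1, 1, 0.5, 0))

  set.seed(61)
  t <- rexp(40); e <- rbinom(40, 1, 0.7)
  kmr <- km_estimator(t, e)
  expect_true(all(diff(kmr$surv) <= 1e-12))
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")
})

test_that("Cox estimate maximizes the hand-written partial likelihood", {
  t4 <- c(1, 2, 3, 4); e4 <- c(1, 1, 1, 1); x4 <- c(0, 1, 0, 1)
  res <- cox_lrt(t4, e4, x4)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), times = t4, events = e4,
               x = x4)
  expect_lt(abs(unname(res$beta) - grid[which.max(ll)]), 1e-3)
  expect_equal(unname(res$lrt_statistic),
               2 * (max(ll) - oracle_cox_loglik(0, t4, e4, x4)),
               tolerance = 1e-6)

  # direction: uniformly later events mean hazard ratio < 1
  tt <- c(1, 2, 3, 10, 11, 12); ee <- rep(1, 6); grp <- c(0, 0, 0, 1, 1, 1)
  # groups are perfectly separated in time, so the MLE diverges towards 0;
  # the direction of the estimate is still the property under test
  expect_lt(suppressWarnings(cox_lrt(tt, ee, grp)$hazard_ratio), 1)
  expect_error(cox_lrt(tt, rep(0, 6), grp), "event")
  expect_error(cox_lrt(tt, ee, rep(1, 6)), "constant")
})

test_that("Cox LRT p-values are calibrated under the null", {
  set.seed(71)
  rejections <- 0
  for (i in 1:100) {
    t <- rexp(200); e <- rep(1, 200); x <- rnorm(200)
    if (cox_lrt(t, e, x)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 10)
})

test_that("table percentages reproduce the printed worked examples", {
  tabs <- load_printed_tables()
  pct_e <- table_percentages(tabs$egfr$smoking, digits = 1)
  expect_equal(unname(pct_e["Never", "EGFR_positive"]), 53.3)
  expect_equal(unname(pct_e["Never", "Wild_type"]), 5.8)
  pct_k <- table_percentages(tabs$kras$smoking, digits = 1)
  expect_equal(unname(pct_k["Never", "KRAS_positive"]), 2.1)
  expect_equal(unname(pct_k["Never", "Wild_type"]), 18.3)
  expect_equal(unname(colSums(table_percentages(tabs$egfr$prognosis))),
               c(100, 100))
  expect_error(table_percentages(matrix(c(0, 0, 1, 2), 2)), "zero column")
})
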