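# Cohort-level statistics: contingency tests, rank tests, logistic
# modelling with stepwise selection, ROC cutoffs, correlation, a single
# CART-style split, and survival. Standard fits are delegated to stats/
# survival; the surfaces here add the contracts (validation, exact
# small-sample behavior, selection rules) the analysis depends on.

check_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integer counts")
  tab
}

#' Fisher's exact test for an r x c table
#'
#' Two-sided exact p-value by probability ordering: the sum of
#' probabilities, under fixed margins, of all tables no more probable than
#' the one observed.
#'
#' @param table Contingency matrix (>= 2x2, non-negative integers).
#' @param max_total Enumeration budget; larger tables are refused with a
#'   pointer to [chi_square_test()].
#' @return List with `p_value` and `method`.
#' @export
fisher_exact <- function(table, max_total = 10000) {
  tab <- check_contingency(table)
  if (sum(tab) > max_total)
    stop("table total ", sum(tab), " exceeds the exact-test budget (",
         max_total, "); use chi_square_test()")
  res <- stats::fisher.test(tab)
  list(p_value = unname(res$p.value), method = "fisher_exact")
}

#' Pearson chi-square test for an r x c table
#'
#' @param table Contingency matrix; all expected counts must be positive.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  tab <- check_contingency(table)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("zero expected cell count")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = expected)
}

#' Wilcoxon rank-sum test with midranks
#'
#' Exact two-sided p by full enumeration of rank assignments (with
#' midranks under ties) when the combined sample size is at most
#' `exact_limit`; otherwise the normal approximation with tie-corrected
#' variance and a continuity correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_limit Combined-size bound for exact enumeration
#'   (default 12).
#' @return List with `statistic` (rank sum of `x`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, nx)
    Wdist <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(Wdist - EW) >= abs(W - EW) - 1e-9)
    return(list(statistic = W, p_value = p, exact = TRUE))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  V <- nx * ny / 12 * ((n + 1) - tie_term)
  z <- (W - EW - sign(W - EW) * 0.5) / sqrt(V)
  list(statistic = W, p_value = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS fit with Wald standard errors from the observed information;
#' complete or quasi-complete separation is detected and flagged rather
#' than silently reported with meaningless standard errors.
#'
#' @param design Covariate matrix or data.frame (no intercept column), or
#'   `NULL` for an intercept-only model.
#' @param y Binary 0/1 outcome.
#' @return An object of class `logistic_fit`: `variables`,
#'   `coefficients`, `se`, `p_value` (Wald), `loglik`, `converged`,
#'   `separation`, and the underlying `glm`.
#' @export
fit_logistic <- function(design, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("outcome is constant; no information to fit")
  if (is.null(design) || NCOL(design) == 0) {
    df <- data.frame(.y = y)
  } else {
    design <- as.data.frame(design)
    if (nrow(design) != length(y)) stop("design and y lengths differ")
    num <- vapply(design, is.numeric, logical(1))
    if (any(vapply(design[num], function(v) stats::var(v) == 0, logical(1))))
      stop("design contains constant columns")
    if (length(y) <= ncol(design) + 1)
      stop("need more observations than parameters")
    df <- data.frame(.y = y, design, check.names = TRUE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  aliased <- is.na(stats::coef(fit))
  separation <- sep_warn || any(abs(stats::coef(fit)[!aliased]) > 15)
  structure(list(
    variables = setdiff(rownames(cf), "(Intercept)"),
    coefficients = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    p_value = cf[, "Pr(>|z|)"],
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    separation = separation,
    glm = fit), class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> logLik ", format(x$loglik, digits = 6),
      if (x$separation) "  [separation flagged]", "\n", sep = "")
  print(cbind(coef = round(x$coefficients, 4), se = round(x$se, 4),
              p = signif(x$p_value, 3)))
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stats::predict(object$glm, type = type)
  else stats::predict(object$glm, newdata = as.data.frame(newdata),
                      type = type)
}

#' Stepwise logistic variable selection
#'
#' Classical p-value stepwise selection: at each step the candidate with
#' the smallest score-test (Rao) p-value below `entry_p` enters, then any
#' included variable whose Wald p-value exceeds `stay_p` is dropped
#' (worst first). A visited-set guard prevents add/drop cycles. An empty
#' selection returns the intercept-only fit.
#'
#' @param candidates Data frame of candidate covariates.
#' @param y Binary outcome.
#' @param entry_p,stay_p Entry and stay significance levels (default 0.05
#'   each).
#' @return A `logistic_fit` on the selected variables, with the selection
#'   history in `attr(, "trace")` and the names in `attr(, "selected")`.
#' @export
stepwise_select <- function(candidates, y, entry_p = 0.05, stay_p = 0.05) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("need at least one candidate")
  df <- data.frame(.y = as.numeric(y), candidates, check.names = TRUE)
  cand_names <- setdiff(names(df), ".y")
  included <- character(0)
  trace <- list()
  seen <- character(0)
  refit <- function(vars) {
    fml <- if (length(vars) == 0) .y ~ 1
    else stats::reformulate(vars, response = ".y")
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  }
  fit <- refit(included)
  repeat {
    changed <- FALSE
    # entry: smallest score-test p among excluded candidates
    pool <- setdiff(cand_names, included)
    if (length(pool) > 0) {
      scope <- stats::reformulate(c(included, pool), response = ".y")
      a1 <- suppressWarnings(stats::add1(fit, scope = scope, test = "Rao"))
      pv <- a1[pool, "Pr(>Chi)"]
      names(pv) <- pool
      pv <- pv[is.finite(pv)]
      if (length(pv) > 0 && min(pv) < entry_p) {
        best <- names(pv)[which.min(pv)]
        key <- paste(sort(c(included, best)), collapse = "+")
        if (!key %in% seen) {
          seen <- c(seen, key)
          included <- c(included, best)
          fit <- refit(included)
          trace[[length(trace) + 1]] <- list(action = "add", variable = best,
                                             p = unname(min(pv)))
          changed <- TRUE
        }
      }
    }
    # removal: worst Wald p above stay_p
    while (length(included) > 0) {
      cf <- summary(fit)$coefficients
      wp <- cf[setdiff(rownames(cf), "(Intercept)"), "Pr(>|z|)", drop = TRUE]
      wp <- wp[!is.na(wp)]
      if (length(wp) == 0 || max(wp) <= stay_p) break
      worst <- names(wp)[which.max(wp)]
      included <- setdiff(included, worst)
      fit <- refit(included)
      trace[[length(trace) + 1]] <- list(action = "drop", variable = worst,
                                         p = unname(max(wp)))
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- fit_logistic(if (length(included) > 0)
    df[, included, drop = FALSE] else NULL, df$.y)
  attr(out, "selected") <- included
  attr(out, "trace") <- trace
  out
}

#' Rescale a log-odds coefficient to an odds ratio per delta units
#'
#' `exp(beta_per_unit * delta_units)`; pass a negative delta for
#' "per 10-point decrease" phrasings.
#'
#' @param beta_per_unit Log-odds per unit of the covariate.
#' @param delta_units Change in covariate units.
#' @return Odds ratio.
#' @examples
#' rescale_odds_ratio(-0.0207, -10)  # OR per 10-point decrease
#' @export
rescale_odds_ratio <- function(beta_per_unit, delta_units) {
  if (!is.finite(beta_per_unit)) stop("beta must be finite")
  exp(beta_per_unit * delta_units)
}

#' ROC curve with trapezoidal AUC
#'
#' Thresholds at every distinct score (plus sentinels); AUC by the
#' trapezoidal rule, which with midrank tie handling equals the pairwise
#' concordance probability.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary 0/1 truth (1 = positive).
#' @param direction `"higher"` if larger scores indicate the positive
#'   class (default), `"lower"` otherwise.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `direction`.
#' @export
roc_curve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- sort(unique(s), decreasing = TRUE)
  thr <- c(Inf, thr)
  sens <- vapply(thr, function(t) sum(s >= t & labels == 1) / np, numeric(1))
  spec <- vapply(thr, function(t) sum(s < t & labels == 0) / nn, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  out_thr <- if (direction == "lower") -thr else thr
  structure(list(thresholds = out_thr, sensitivity = sens,
                 specificity = spec, auc = auc, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4), " (",
      length(x$thresholds), " thresholds, direction: ", x$direction,
      "-is-positive)\n", sep = "")
  invisible(x)
}

#' Operating point at a target sensitivity
#'
#' Among all thresholds achieving at least the target sensitivity, returns
#' the one maximizing specificity; residual ties resolve to the threshold
#' admitting the most positives.
#'
#' @param roc A [roc_curve()] result.
#' @param target Target sensitivity (default 0.80, the published screening
#'   operating point).
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_at_sensitivity <- function(roc, target = 0.80) {
  stopifnot(inherits(roc, "roc_result"))
  ok <- which(roc$sensitivity >= target)
  spec_ok <- roc$specificity[ok]
  best_spec <- max(spec_ok)
  cand <- ok[spec_ok == best_spec]
  pick <- cand[which.max(roc$sensitivity[cand])]
  list(threshold = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors, length >= 2, non-constant.
#' @return Pearson r.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has undefined correlation")
  stats::cor(x, y)
}

#' Best single CART-style split
#'
#' Exhaustive search over every feature and every midpoint of its sorted
#' distinct values for the split minimizing weighted Gini impurity.
#'
#' @param features Data frame of numeric candidate features.
#' @param y Binary 0/1 outcome with both classes present.
#' @return List with `feature`, `split` (cut point; left branch is
#'   `< split`), `impurity` (weighted Gini), and `n_left`/`n_right`.
#' @export
recursive_partition_split <- function(features, y) {
  features <- as.data.frame(features)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (length(y) < 2) stop("need at least 2 observations")
  gini <- function(lab) {
    p <- mean(lab); 2 * p * (1 - p)
  }
  best <- list(feature = NA_character_, split = NA_real_, impurity = Inf,
               n_left = NA_integer_, n_right = NA_integer_)
  n <- length(y)
  for (nm in names(features)) {
    v <- features[[nm]]
    u <- sort(unique(v))
    if (length(u) < 2) next
    cuts <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
    for (cp in cuts) {
      left <- v < cp
      imp <- mean(left) * gini(y[left]) + mean(!left) * gini(y[!left])
      if (imp < best$impurity - 1e-12) {
        best <- list(feature = nm, split = cp, impurity = imp,
                     n_left = sum(left), n_right = sum(!left))
      }
    }
  }
  if (!is.finite(best$impurity)) stop("no splittable feature found")
  best
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return List of class `km_curve`: event-time grid `time`, `n_risk`,
#'   `n_event`, and the survival estimate `surv` (right-continuous step
#'   function values after each time).
#' @export
km_estimator <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv), class = "km_curve")
}

#' Survival probability from a Kaplan-Meier curve
#' @param km A [km_estimator()] result.
#' @param t Time point(s).
#' @return S(t), the step-function value at each `t`.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Cox proportional-hazards fit with likelihood-ratio test
#'
#' Partial-likelihood maximization with Breslow tie handling; significance
#' by the likelihood-ratio statistic against the null model.
#'
#' @param times,events Survival outcome (>= 1 event required).
#' @param covariate Numeric vector, factor, or data.frame of covariates;
#'   must be non-constant.
#' @return List with `hazard_ratio` (per covariate), `beta`,
#'   `lrt_statistic`, `df`, `p_value`, and the `coxph` fit.
#' @export
cox_lrt <- function(times, events, covariate) {
  if (sum(events) < 1) stop("need at least one event")
  cov_df <- as.data.frame(covariate)
  if (any(vapply(cov_df, function(v) length(unique(v)) < 2, logical(1))))
    stop("constant covariate")
  df <- data.frame(.t = times, .e = events, cov_df)
  fml <- stats::reformulate(names(df)[-(1:2)],
                            response = "survival::Surv(.t, .e)")
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  k <- sum(!is.na(stats::coef(fit)))
  list(hazard_ratio = exp(stats::coef(fit)), beta = stats::coef(fit),
       lrt_statistic = lrt, df = k,
       p_value = stats::pchisq(lrt, df = k, lower.tail = FALSE),
       fit = fit)
}

#' Column-wise percentages of a contingency table
#'
#' @param table Count matrix with positive column totals.
#' @param digits Optional rounding to the printed precision.
#' @return Matrix of percentages (each column sums to 100 up to rounding).
#' @examples
#' table_percentages(load_printed_tables()$egfr$smoking, digits = 1)
#' @export
table_percentages <- function(table, digits = NULL) {
  tab <- as.matrix(table)
  ct <- colSums(tab)
  if (any(ct <= 0)) stop("zero column total")
  pct <- sweep(tab, 2, ct, "/") * 100
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}
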