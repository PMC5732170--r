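# Independent brute-force oracles used to validate the package's
# implementations. Everything here is deliberately naive: enumeration,
# exhaustive scans and closed forms, never the code path under test.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force 3x3 in-plane median with reflection padding
oracle_median3x3 <- function(a) {
  d <- dim(a)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- a
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    vals <- numeric(9); t <- 1
    for (dy in -1:1) for (dx in -1:1) {
      vals[t] <- a[refl(x + dx, d[1]), refl(y + dy, d[2]), z]
      t <- t + 1
    }
    out[x, y, z] <- median(vals)
  }
  out
}

# exhaustive min-distance (mm) from each query voxel to any mask voxel
oracle_min_dist <- function(query_idx, mask_idx, spacing) {
  qs <- sweep(query_idx, 2, spacing, "*")
  ms <- sweep(mask_idx, 2, spacing, "*")
  apply(qs, 1, function(q)
    sqrt(min(colSums((t(ms) - q)^2))))
}

# Fisher exact two-sided p for an r x 2 table by full enumeration of
# margin-consistent tables (probability ordering)
oracle_fisher_rx2 <- function(tab) {
  rt <- rowSums(tab); c1 <- sum(tab[, 1]); N <- sum(tab)
  logp <- function(k) sum(lchoose(rt, k)) - lchoose(N, c1)
  grid <- do.call(expand.grid, lapply(rt, function(m) 0:m))
  grid <- grid[rowSums(grid) == c1, , drop = FALSE]
  lps <- apply(grid, 1, logp)
  obs <- logp(tab[, 1])
  sum(exp(lps[lps <= obs + 1e-7]))
}

# exact Wilcoxon rank-sum two-sided p by enumeration (midranks)
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  Wdist <- colSums(matrix(r[utils::combn(n, nx)], nrow = nx))
  mean(abs(Wdist - EW) >= abs(W - EW) - 1e-9)
}

# AUC by exhaustive pair concordance (ties half credit)
oracle_auc_pairs <- function(scores, labels, direction = "higher") {
  s <- if (direction == "lower") -scores else scores
  pos <- s[labels == 1]; neg <- s[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# exhaustive 1-medoid: the point maximizing summed similarity
oracle_1medoid <- function(S) which.max(rowSums(S))

# exhaustive k-medoid clustering cost for a given medoid triple
oracle_best_3medoids <- function(D) {
  n <- nrow(D)
  best <- NULL; best_cost <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cost <- sum(pmin(D[, i], D[, j], D[, k]))
    if (cost < best_cost) { best_cost <- cost; best <- c(i, j, k) }
  }
  assign <- apply(D[, best, drop = FALSE], 1, which.min)
  list(medoids = best, assignment = assign, cost = best_cost)
}

# exhaustive best Gini split over all features and midpoints
oracle_best_split <- function(features, y) {
  gini <- function(lab) { p <- mean(lab); 2 * p * (1 - p) }
  best <- list(feature = NA, split = NA, impurity = Inf)
  for (nm in names(features)) {
    v <- features[[nm]]; u <- sort(unique(v))
    if (length(u) < 2) next
    for (cp in (head(u, -1) + tail(u, -1)) / 2) {
      l <- v < cp
      imp <- mean(l) * gini(y[l]) + mean(!l) * gini(y[!l])
      if (imp < best$impurity - 1e-12)
        best <- list(feature = nm, split = cp, impurity = imp)
    }
  }
  best
}

# Breslow partial log-likelihood for a single covariate
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force nearest-exemplar labels: per-voxel 9x9 reflect-padded patch
# compared against every exemplar with roi_similarity
oracle_classify <- function(volume, mask, model) {
  d <- dim(volume$data)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  idx <- which(mask$data, arr.ind = TRUE)
  colors <- rownames(model$features)
  out <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    patch <- matrix(0, 9, 9)
    for (dy in -4:4) for (dx in -4:4)
      patch[dx + 5, dy + 5] <- volume$data[refl(i[1] + dx, d[1]),
                                           refl(i[2] + dy, d[2]), i[3]]
    sims <- vapply(colors, function(cc)
      roi_similarity(as.numeric(patch), model$patches[[cc]]$values,
                     clip = model$clip), numeric(1))
    out[r] <- which.max(sims)  # first max = canonical color precedence
  }
  out
}

# constant-HU ROI patch helper
make_patch <- function(hu, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- ct_volume(array(hu + rnorm(81 * 4, 0, noise_sd), c(18, 18, 1)))
  m <- voxel_mask(array(FALSE, c(18, 18, 1)))
  m$data[9, 9, 1] <- TRUE
  extract_rois(v, m)[[1]]
}

# ROIs drawn around well-separated HU levels
make_level_rois <- function(levels, per_level = 6, noise_sd = 8, seed = 1) {
  set.seed(seed)
  rois <- list()
  for (l in levels) for (r in seq_len(per_level))
    rois <- c(rois, list(make_patch(l, noise_sd)))
  rois
}
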