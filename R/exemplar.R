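# Nine color-coded texture exemplars; canonical display/tie-break order.
EXEMPLAR_COLORS <- c("V", "I", "B", "G", "Y", "O", "R", "C", "P")
# Color assignment by ascending mean patch HU: ground-glass-like codes take
# the lowest densities, solid-like the highest.
COLOR_ORDER_BY_HU <- c("B", "C", "G", "Y", "P", "V", "I", "R", "O")
COLOR_GROUPS <- list(VIRO = c("V", "I", "R", "O"),
                     BCG = c("B", "C", "G"),
                     YP = c("Y", "P"))

#' Extract 9x9 in-plane ROI patches from a masked region
#'
#' Samples axial 9x9 HU patches centered on mask voxels at the given
#' stride; centers whose window would overlap the grid edge are skipped.
#'
#' @param volume A [ct_volume()].
#' @param mask A [voxel_mask()] on the same grid.
#' @param stride Sampling stride (voxels) applied on all axes.
#' @return A list of `roi_patch` objects (9x9 HU matrix plus its center).
#' @export
extract_rois <- function(volume, mask, stride = 1) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "voxel_mask"))
  check_same_geometry(volume, mask)
  if (!any(mask$data)) stop("empty mask")
  if (stride < 1) stop("stride must be >= 1")
  d <- dim(volume$data)
  idx <- which(mask$data, arr.ind = TRUE)
  ok <- idx[, 1] >= 5 & idx[, 1] <= d[1] - 4 &
        idx[, 2] >= 5 & idx[, 2] <= d[2] - 4
  idx <- idx[ok, , drop = FALSE]
  if (stride > 1 && nrow(idx) > 0) {
    keep <- (idx[, 1] - min(idx[, 1])) %% stride == 0 &
            (idx[, 2] - min(idx[, 2])) %% stride == 0 &
            (idx[, 3] - min(idx[, 3])) %% stride == 0
    idx <- idx[keep, , drop = FALSE]
  }
  lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, ]
    structure(list(values = volume$data[(i[1] - 4):(i[1] + 4),
                                        (i[2] - 4):(i[2] + 4), i[3]],
                   center = unname(i)),
              class = "roi_patch")
  })
}

# Patch feature map: raw HU clipped to [-1024, 200], scaled to [0, 1].
roi_features <- function(x, clip = c(-1024, 200)) {
  v <- if (inherits(x, "roi_patch")) x$values else x
  v <- as.numeric(v)
  if (length(v) != 81L) stop("an ROI patch must hold exactly 81 HU values")
  if (!all(is.finite(v))) stop("ROI patch contains non-finite values")
  (pmin(pmax(v, clip[1]), clip[2]) - clip[1]) / (clip[2] - clip[1])
}

#' Pairwise ROI similarity
#'
#' Negative squared Euclidean distance between patch feature vectors (HU
#' values clipped to \[-1024, 200\] and scaled to \[0, 1\]). Zero is the
#' maximum, attained only for feature-identical patches; higher values mean
#' more similar texture.
#'
#' @param a,b `roi_patch` objects or numeric vectors of 81 HU values.
#' @param clip HU clipping range of the feature map.
#' @return A single non-positive similarity value.
#' @export
roi_similarity <- function(a, b, clip = c(-1024, 200)) {
  -sum((roi_features(a, clip) - roi_features(b, clip))^2)
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing on a similarity
#' matrix with damping. The diagonal of `S` is replaced by `preference`
#' (default: the median off-diagonal similarity). Convergence is declared
#' when the exemplar set is stable for `conv_window` consecutive
#' iterations; non-convergence within `max_iter` is reported via the
#' `converged` flag, with the last exemplar set returned.
#'
#' @param S Square similarity matrix (higher = more similar), symmetric off
#'   the diagonal.
#' @param preference Self-similarity assigned to every point; scalar or
#'   length-n vector.
#' @param damping Message damping factor in (0, 1).
#' @param max_iter,conv_window Iteration budget and stability window.
#' @return List with `exemplars` (indices of self-exemplar points),
#'   `labels` (assigned exemplar index per point), `converged`, and
#'   `iterations`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 1000, conv_window = 50) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  if (n == 1L)
    return(list(exemplars = 1L, labels = 1L, converged = TRUE,
                iterations = 0L))
  if (is.null(preference)) preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  S0 <- S
  # tiny deterministic jitter removes degenerate oscillation on exact ties;
  # final assignment uses the unjittered S0 so duplicates label identically
  jit <- outer(seq_len(n), seq_len(n),
               function(i, k) ((i * 37 + k * 17) %% 101) / 101)
  S <- S + (max(abs(S)) + 1) * 1e-12 * jit
  R <- A <- matrix(0, n, n)
  ex_prev <- NULL; stable <- 0L; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS; AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    cs <- colSums(Rp)
    Anew <- matrix(rep(diag(R) + cs, each = n), n, n) - Rp -
      matrix(rep(diag(Rp), each = n), n, n)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, ex_prev) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= conv_window) { converged <- TRUE; break }
    } else stable <- 0L
    ex_prev <- ex
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  labels <- ex[max.col(S0[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  list(exemplars = as.integer(ex), labels = as.integer(labels),
       converged = converged, iterations = it)
}

#' Learn the nine texture exemplars from ROI patches
#'
#' Clusters ROI patches by affinity propagation on the pairwise similarity,
#' tuning the preference by bisection until exactly `k_target` exemplars
#' emerge. Color codes are then attached by ranking exemplar mean HU from
#' lowest to highest onto the fixed order B, C, G, Y, P, V, I, R, O
#' (ground-glass-like codes to the lowest densities, solid-like to the
#' highest), and grouped into the fixed partition VIRO / BCG / YP.
#'
#' @param rois List of `roi_patch` objects, length >= `k_target`.
#' @param k_target Number of exemplars (default 9).
#' @param seed Recorded in the provenance (the fit itself is
#'   deterministic).
#' @param damping,max_iter,conv_window Passed to
#'   [affinity_propagation()].
#' @param max_attempts Bisection budget on the preference.
#' @param clip HU clipping range of the feature map.
#' @return An object of class `exemplar_model`.
#' @export
fit_exemplar_model <- function(rois, k_target = 9, seed = 1L, damping = 0.9,
                               max_iter = 1000, conv_window = 50,
                               max_attempts = 40, clip = c(-1024, 200)) {
  if (length(rois) < k_target)
    stop("need at least ", k_target, " ROI patches, got ", length(rois))
  Fm <- t(vapply(rois, roi_features, numeric(81), clip = clip))
  sq <- rowSums(Fm^2)
  S <- -(outer(sq, sq, `+`) - 2 * tcrossprod(Fm))   # -squared distances
  S <- (S + t(S)) / 2
  off <- S[row(S) != col(S)]
  run <- function(pref) {
    ap <- affinity_propagation(S, preference = pref, damping = damping,
                               max_iter = max_iter,
                               conv_window = conv_window)
    ap$k <- length(ap$exemplars)
    ap
  }
  # more negative preference -> fewer exemplars
  lo <- min(off) * length(rois)    # few clusters
  hi <- 0                          # every point tends to self-exemplar
  pref <- stats::median(off)
  ap <- run(pref)
  attempt <- 1L
  while (ap$k != k_target && attempt < max_attempts) {
    attempt <- attempt + 1L
    if (ap$k > k_target) hi <- pref else lo <- pref
    pref <- (lo + hi) / 2
    ap <- run(pref)
  }
  if (ap$k != k_target)
    stop("could not reach ", k_target, " exemplars within ", max_attempts,
         " preference bisection attempts (last k = ", ap$k, ")")
  ex_idx <- ap$exemplars
  mean_hu <- vapply(ex_idx, function(i) mean(rois[[i]]$values), numeric(1))
  colors_by_rank <- COLOR_ORDER_BY_HU[seq_len(k_target)]
  color_of <- character(k_target)
  color_of[order(mean_hu)] <- colors_by_rank
  # store in canonical color order so argmax tie-breaks follow it
  canon <- intersect(EXEMPLAR_COLORS, color_of)
  ord <- match(canon, color_of)
  features <- Fm[ex_idx[ord], , drop = FALSE]
  rownames(features) <- canon
  group_of <- function(cc) names(COLOR_GROUPS)[vapply(COLOR_GROUPS,
                                                      function(g) cc %in% g,
                                                      logical(1))]
  structure(list(
    colors = canon,
    features = features,
    patches = stats::setNames(lapply(ex_idx[ord], function(i) rois[[i]]),
                              canon),
    groups = stats::setNames(vapply(canon, group_of, character(1)), canon),
    clip = clip,
    provenance = list(seed = seed, preference = pref,
                      iterations = ap$iterations, converged = ap$converged,
                      n_rois = length(rois), attempts = attempt)),
    class = "exemplar_model")
}

#' @export
print.exemplar_model <- function(x, ...) {
  mh <- round(apply(x$features, 1, function(f)
    mean(f * (x$clip[2] - x$clip[1]) + x$clip[1])))
  cat("<exemplar_model> ", nrow(x$features), " exemplars from ",
      x$provenance$n_rois, " ROIs\n  mean HU by color: ",
      paste(sprintf("%s=%d", rownames(x$features), mh), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Label every mask voxel with its nearest exemplar
#'
#' For each mask voxel, the 9x9 in-plane neighborhood (reflect-padded at
#' the grid edge) is compared to all exemplars under the patch similarity;
#' the voxel takes the color of the most similar exemplar. Exact ties break
#' to the earliest color in the canonical order V, I, B, G, Y, O, R, C, P.
#'
#' @param volume A [ct_volume()].
#' @param mask A [voxel_mask()] on the same grid.
#' @param model An [fit_exemplar_model()] result.
#' @return An integer array of the grid shape: 0 outside the mask,
#'   otherwise the index into `attr(, "colors")`.
#' @export
classify_voxels <- function(volume, mask, model) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "voxel_mask"),
            inherits(model, "exemplar_model"))
  check_same_geometry(volume, mask)
  if (!any(mask$data)) stop("empty mask")
  d <- dim(volume$data)
  # reflect-pad by 4 in-plane
  rx <- c(5:2, seq_len(d[1]), (d[1] - 1):(d[1] - 4))
  ry <- c(5:2, seq_len(d[2]), (d[2] - 1):(d[2] - 4))
  if (d[1] < 5 || d[2] < 5) stop("in-plane grid too small for 9x9 patches")
  ap <- volume$data[rx, ry, , drop = FALSE]
  dp <- dim(ap)
  idx <- which(mask$data, arr.ind = TRUE)
  n <- nrow(idx)
  P <- matrix(0, n, 81)
  col <- 1L
  base <- (idx[, 1] + 4) + (idx[, 2] + 3) * dp[1] +
    (idx[, 3] - 1) * dp[1] * dp[2]
  for (dy in -4:4) for (dx in -4:4) {
    P[, col] <- ap[base + dx + dy * dp[1]]
    col <- col + 1L
  }
  cl <- model$clip
  P <- (pmin(pmax(P, cl[1]), cl[2]) - cl[1]) / (cl[2] - cl[1])
  E <- model$features
  d2 <- outer(rowSums(P^2), rowSums(E^2), `+`) - 2 * tcrossprod(P, E)
  lab <- max.col(-d2, ties.method = "first")
  out <- array(0L, d)
  out[mask$data] <- lab
  attr(out, "colors") <- rownames(E)
  out
}

#' Glyph: exemplar proportions of a nodule
#'
#' @param labels Label array from [classify_voxels()].
#' @param mask The nodule [voxel_mask()] the labels cover.
#' @return A `glyph`: named numeric of 9 percentages summing to 100.
#' @export
compute_glyph <- function(labels, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$data)) stop("empty mask")
  colors <- attr(labels, "colors")
  if (is.null(colors)) colors <- EXEMPLAR_COLORS
  lab <- labels[mask$data]
  if (any(lab == 0L)) stop("every mask voxel must be labeled")
  counts <- tabulate(lab, nbins = length(colors))
  g <- stats::setNames(100 * counts / sum(counts), colors)
  # report in canonical color order
  g <- g[order(match(names(g), EXEMPLAR_COLORS))]
  structure(g, class = "glyph")
}

#' @export
print.glyph <- function(x, ...) {
  cat("<glyph> ", paste(sprintf("%s=%.1f%%", names(x), unclass(x)),
                        collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Composite exemplar features of a glyph
#'
#' Sums the glyph into the three exemplar groups plus the individual Y and
#' G percentages used for mutation prediction: VIRO (invasive component),
#' YP, BCG (lepidic component), Y, G and Y+G. VIRO + YP + BCG = 100 by
#' construction.
#'
#' @param glyph A [compute_glyph()] result (or named 9-vector of
#'   percentages).
#' @return A named numeric of class `composite_features` with entries
#'   `VIRO`, `YP`, `BCG`, `Y`, `G`, `YplusG`.
#' @export
composite_features <- function(glyph) {
  g <- unclass(glyph)
  if (is.null(names(g)) || !all(EXEMPLAR_COLORS %in% names(g)))
    stop("glyph must be named with the 9 exemplar colors")
  if (any(g < 0) || abs(sum(g) - 100) > 1e-6)
    stop("glyph percentages must be non-negative and sum to 100")
  out <- c(VIRO = sum(g[COLOR_GROUPS$VIRO]),
           YP = sum(g[COLOR_GROUPS$YP]),
           BCG = sum(g[COLOR_GROUPS$BCG]),
           Y = unname(g["Y"]), G = unname(g["G"]),
           YplusG = unname(g["Y"] + g["G"]))
  structure(out, class = "composite_features")
}

# registered mutation-screening cutoffs (percent of tumor volume)
DEFAULT_CUTOFFS <- list(VIRO = list(threshold = 71, direction = "le"),
                        YP = list(threshold = 23.5, direction = "ge"))

#' Apply a screening cutoff to a composite feature
#'
#' Boundary-inclusive thresholding of a composite feature. The registered
#' defaults are the published screening rules VIRO <= 71% and YP >= 23.5%
#' of tumor volume (each chosen for 80% sensitivity to EGFR mutation).
#'
#' @param features A [composite_features()] result.
#' @param feature Feature name (e.g. `"VIRO"`, `"YP"`).
#' @param threshold,direction Override the registered cutoff; `direction`
#'   is `"le"` (flag when value <= threshold) or `"ge"`.
#' @return Logical flag.
#' @examples
#' f <- structure(c(VIRO = 70, YP = 20, BCG = 10, Y = 10, G = 5,
#'                  YplusG = 15), class = "composite_features")
#' apply_cutoff(f, "VIRO")
#' @export
apply_cutoff <- function(features, feature, threshold = NULL,
                         direction = NULL) {
  vals <- unclass(features)
  if (!feature %in% names(vals)) stop("unknown feature: ", feature)
  if (is.null(threshold) || is.null(direction)) {
    reg <- DEFAULT_CUTOFFS[[feature]]
    if (is.null(reg))
      stop("no registered cutoff for ", feature,
           "; supply threshold and direction")
    if (is.null(threshold)) threshold <- reg$threshold
    if (is.null(direction)) direction <- reg$direction
  }
  direction <- match.arg(direction, c("le", "ge"))
  v <- vals[[feature]]
  if (direction == "le") v <= threshold else v >= threshold
}

#' Assign G/I/P risk groups from cohort glyphs
#'
#' Clusters the 9-dimensional glyph vectors into three groups by k-medoids
#' (Euclidean metric, deterministic) and labels the groups G, I, P in order
#' of ascending mean VIRO, reflecting the association of the invasive
#' component with worse prognosis. If all glyphs are identical the
#' clustering is degenerate: every nodule is assigned I with a warning.
#'
#' @param glyphs A list of [compute_glyph()] results or a numeric matrix
#'   (one row per nodule, 9 color columns).
#' @return Character vector of `"G"`, `"I"`, `"P"` labels.
#' @export
assign_risk_groups <- function(glyphs) {
  if (is.list(glyphs)) {
    G <- t(vapply(glyphs, function(g) unclass(g)[EXEMPLAR_COLORS],
                  numeric(9)))
    colnames(G) <- EXEMPLAR_COLORS
  } else {
    G <- as.matrix(glyphs)[, EXEMPLAR_COLORS, drop = FALSE]
  }
  n <- nrow(G)
  if (n < 3) stop("need at least 3 nodules to form risk groups")
  if (all(apply(G, 2, function(col) max(col) - min(col)) < 1e-9)) {
    warning("all glyphs identical; degenerate clustering, assigning ",
            "all nodules to the intermediate group")
    return(rep("I", n))
  }
  viro <- rowSums(G[, COLOR_GROUPS$VIRO, drop = FALSE])
  cl <- tryCatch(cluster::pam(G, k = 3, cluster.only = TRUE),
                 error = function(e) NULL)
  if (is.null(cl)) {
    # too few distinct glyphs for 3 medoids: fall back to VIRO tertiles
    cl <- as.integer(cut(rank(viro, ties.method = "first"),
                         breaks = 3, labels = FALSE))
  }
  mean_viro <- tapply(viro, cl, mean)
  lab_of <- stats::setNames(c("G", "I", "P")[rank(mean_viro,
                                                  ties.method = "first")],
                            names(mean_viro))
  unname(lab_of[as.character(cl)])
}

#' @export
plot.glyph <- function(x, ...) {
  cols <- c(V = "#8F00FF", I = "#4B0082", B = "#0047AB", G = "#00A550",
            Y = "#FFD500", O = "#FF7F00", R = "#E32636", C = "#00B7EB",
            P = "#FFA6C9")
  graphics::barplot(unclass(x), col = cols[names(x)], border = NA,
                    ylab = "% of nodule volume", xlab = "exemplar", ...)
  invisible(x)
}
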