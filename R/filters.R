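# Array utilities shared by the imaging operations. Everything here is
# vectorized over whole volumes; no per-voxel R loops except the 1-D
# distance-transform envelope scan.

# Shift a 3-D array by (dx,dy,dz); vacated voxels take `fill`.
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) == 0 || length(sy) == 0 || length(sz) == 0) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

neighbor_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2, "26" = nrm >= 1)
  off[keep, , drop = FALSE]
}

# One binary dilation step restricted to the given neighborhood.
dilate3d <- function(mask, offsets) {
  out <- mask
  for (r in seq_len(nrow(offsets)))
    out <- out | shift3d(mask, offsets[r, 1], offsets[r, 2], offsets[r, 3])
  out
}

# Flood fill: grow `seed` within `candidate` until stable.
flood_fill3d <- function(candidate, seed, connectivity = 26) {
  off <- neighbor_offsets(connectivity)
  cur <- seed & candidate
  repeat {
    nxt <- dilate3d(cur, off) & candidate
    if (sum(nxt) == sum(cur)) return(nxt)
    cur <- nxt
  }
}

# Label connected components of a logical array. Returns an integer array
# (0 = background) plus component sizes, largest first relabeled 1, 2, ...
label_components <- function(mask, connectivity = 26) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood_fill3d(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  sizes <- if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer(0)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k); relab[ord] <- seq_len(k)
  lab[lab > 0] <- relab[lab[lab > 0]]
  list(labels = lab, sizes = sizes[ord])
}

# Fill in-plane (axial, x-y) holes of a mask: background not reachable from
# the slice border under 4-connectivity is folded into the mask. All slices
# are processed simultaneously by restricting the flood to in-plane shifts.
fill_holes_inplane <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  seed <- array(FALSE, d)
  seed[c(1, d[1]), , ] <- TRUE
  seed[, c(1, d[2]), ] <- TRUE
  seed <- seed & bg
  off <- cbind(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1), dz = 0)
  cur <- seed
  repeat {
    nxt <- dilate3d(cur, off) & bg
    if (sum(nxt) == sum(cur)) break
    cur <- nxt
  }
  mask | (bg & !cur)
}

# Exact anisotropic squared Euclidean distance transform (lower-envelope
# algorithm, one separable pass per axis). Returns squared distance in mm^2
# from every voxel to the nearest TRUE voxel of `mask`.
edt_squared <- function(mask, spacing) {
  d <- dim(mask)
  f <- array(ifelse(mask, 0, Inf), d)
  f <- edt_pass(f, axis = 1, w = spacing[1])
  f <- edt_pass(f, axis = 2, w = spacing[2])
  f <- edt_pass(f, axis = 3, w = spacing[3])
  f
}

edt_pass <- function(f, axis, w) {
  d <- dim(f)
  n <- d[axis]
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  g <- aperm(f, perm)                       # lines along first dim
  m <- matrix(g, nrow = n)
  for (j in seq_len(ncol(m))) m[, j] <- edt_1d(m[, j], w)
  g <- array(m, dim = dim(g))
  aperm(g, order(perm))
}

edt_1d <- function(f, w) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0) return(f)
  x <- fin * w
  fv <- f[fin]
  m <- length(fin)
  v <- integer(m); z <- numeric(m + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  if (m > 1) for (q in 2:m) {
    repeat {
      p <- v[k]
      s <- ((fv[q] + x[q]^2) - (fv[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    xq <- q * w
    while (z[k + 1] < xq) k <- k + 1L
    out[q] <- (xq - x[v[k]])^2 + fv[v[k]]
  }
  out
}

# Vectorized median of 9 via a sorting network (Paeth), applied column-wise
# to a list of 9 equal-length vectors.
median9 <- function(p) {
  srt <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  srt(2, 3); srt(5, 6); srt(8, 9)
  srt(1, 2); srt(4, 5); srt(7, 8)
  srt(2, 3); srt(5, 6); srt(8, 9)
  srt(1, 4); srt(6, 9); srt(5, 8)
  srt(4, 7); srt(2, 5); srt(3, 6)
  srt(5, 8); srt(5, 3); srt(7, 5)
  srt(5, 3)
  p[[5]]
}

#' In-plane 3x3 median smoothing
#'
#' Replaces every voxel by the median of its 3x3 axial (in-plane)
#' neighborhood, the standard remedy for edge-enhancing reconstruction
#' kernel artifact before texture analysis. Slice edges are handled by
#' reflection, so constant slices are exactly preserved.
#'
#' @param volume A [ct_volume()].
#' @return A smoothed [ct_volume()] on the same grid.
#' @export
median_filter_inplane <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  a <- volume$data
  d <- dim(a)
  # reflect-pad by 1 in x and y
  px <- c(2L, seq_len(d[1]), d[1] - 1L)
  if (d[1] == 1L) px <- c(1L, 1L, 1L)
  py <- c(2L, seq_len(d[2]), d[2] - 1L)
  if (d[2] == 1L) py <- c(1L, 1L, 1L)
  ap <- a[px, py, , drop = FALSE]
  idx <- 1L
  p <- vector("list", 9)
  for (dy in 0:2) for (dx in 0:2) {
    p[[idx]] <- as.vector(ap[dx + seq_len(d[1]), dy + seq_len(d[2]), ,
                             drop = FALSE])
    idx <- idx + 1L
  }
  ct_volume(array(median9(p), d), spacing = volume$spacing,
            origin = volume$origin)
}
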