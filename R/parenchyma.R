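#' Thresholds of the rule-based parenchymal classifier
#'
#' The five-class parenchymal typing (normal N, low attenuation LA,
#' ground glass GG, reticular R, honeycomb HC) is implemented as a
#' transparent decision table on per-VOI statistics rather than a
#' re-derivation of a trained clustering: LA when the fraction of voxels
#' below -950 HU exceeds `la_frac`; HC when the cyst-wall score (fraction
#' of voxels below `hc_cyst_hu` 6-adjacent to voxels above `hc_wall_hu`)
#' exceeds `hc_score`; otherwise the mean-HU bands decide N vs GG, with R
#' whenever the texture SD exceeds the band's SD limit.
#'
#' @param la_frac LA rule: fraction of voxels < -950 HU (default 0.5).
#' @param normal_band,normal_sd N band: mean HU range and SD limit.
#' @param gg_band,gg_sd GG band: mean HU range and SD limit.
#' @param hc_cyst_hu,hc_wall_hu,hc_score Honeycomb cyst/wall HU limits and
#'   score threshold.
#' @return A list of class `parenchyma_thresholds`.
#' @export
parenchyma_thresholds <- function(la_frac = 0.5,
                                  normal_band = c(-950, -700), normal_sd = 80,
                                  gg_band = c(-700, -300), gg_sd = 120,
                                  hc_cyst_hu = -910, hc_wall_hu = -300,
                                  hc_score = 0.03) {
  structure(list(la_frac = la_frac, normal_band = normal_band,
                 normal_sd = normal_sd, gg_band = gg_band, gg_sd = gg_sd,
                 hc_cyst_hu = hc_cyst_hu, hc_wall_hu = hc_wall_hu,
                 hc_score = hc_score),
            class = "parenchyma_thresholds")
}

#' Tile a shell mask into 15x15x15 VOIs
#'
#' Partitions the shell's bounding box into non-overlapping cubic blocks of
#' `voi_size` voxels; a block is retained when at least `min_occupancy` of
#' its voxels lie in the shell. Each retained VOI records its in-shell
#' voxel indices so class fractions can be voxel-weighted.
#'
#' @param volume A [ct_volume()].
#' @param shell A [voxel_mask()] (typically from [peritumoral_shell()]).
#' @param voi_size Block edge length in voxels (default 15).
#' @param min_occupancy Minimum in-shell fraction to retain a block
#'   (default 0.3, accommodating thin shells).
#' @return List of `voi` objects: `values` (HU array of the block),
#'   `origin` (block corner index), `in_shell` (logical array),
#'   `n_shell` voxel count.
#' @export
tile_vois <- function(volume, shell, voi_size = 15, min_occupancy = 0.3) {
  stopifnot(inherits(volume, "ct_volume"), inherits(shell, "voxel_mask"))
  check_same_geometry(volume, shell)
  if (!any(shell$data)) stop("empty shell mask")
  idx <- which(shell$data, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  d <- dim(volume$data)
  out <- list()
  for (z0 in seq(lo[3], hi[3], by = voi_size))
    for (y0 in seq(lo[2], hi[2], by = voi_size))
      for (x0 in seq(lo[1], hi[1], by = voi_size)) {
        x1 <- min(x0 + voi_size - 1L, d[1])
        y1 <- min(y0 + voi_size - 1L, d[2])
        z1 <- min(z0 + voi_size - 1L, d[3])
        sub_shell <- shell$data[x0:x1, y0:y1, z0:z1, drop = FALSE]
        occ <- mean(sub_shell)
        if (occ >= min_occupancy && any(sub_shell)) {
          out[[length(out) + 1L]] <- structure(list(
            values = volume$data[x0:x1, y0:y1, z0:z1, drop = FALSE],
            origin = c(x0, y0, z0),
            in_shell = sub_shell,
            n_shell = sum(sub_shell)), class = "voi")
        }
      }
  out
}

# cyst-wall score: fraction of block voxels that are cystic (below
# hc_cyst_hu) and 6-adjacent to a wall voxel (above hc_wall_hu)
cyst_wall_score <- function(values, thresholds) {
  cyst <- values < thresholds$hc_cyst_hu
  wall <- values > thresholds$hc_wall_hu
  if (!any(cyst) || !any(wall)) return(0)
  near_wall <- dilate3d(wall, neighbor_offsets(6))
  mean(cyst & near_wall)
}

#' Classify one VOI into a parenchymal class
#'
#' For VOIs from [tile_vois()], the scalar statistics (mean, SD, fraction
#' below -950 HU) are computed over the in-shell voxels only, so partially
#' occupied blocks at the shell boundary are not contaminated by tumor or
#' chest-wall voxels; the cyst-wall adjacency score uses the full block,
#' which carries the 3-D structure.
#'
#' @param voi A `voi` from [tile_vois()], or a plain numeric array/vector
#'   of HU values.
#' @param thresholds A [parenchyma_thresholds()].
#' @return One of `"N"`, `"LA"`, `"GG"`, `"R"`, `"HC"`.
#' @export
classify_voi <- function(voi, thresholds = parenchyma_thresholds()) {
  values <- if (inherits(voi, "voi")) voi$values else voi
  v <- if (inherits(voi, "voi")) as.numeric(values[voi$in_shell])
       else as.numeric(values)
  if (!all(is.finite(v))) stop("VOI contains non-finite HU values")
  if (mean(v < -950) > thresholds$la_frac) return("LA")
  if (is.array(values) && length(dim(values)) == 3L &&
      cyst_wall_score(values, thresholds) > thresholds$hc_score)
    return("HC")
  mu <- mean(v); sdv <- stats::sd(v)
  if (mu <= thresholds$normal_band[2]) {
    if (sdv < thresholds$normal_sd) "N" else "R"
  } else if (mu <= thresholds$gg_band[2]) {
    if (sdv < thresholds$gg_sd) "GG" else "R"
  } else "R"
}

#' Summarize the parenchymal composition of a shell
#'
#' Classifies every retained VOI of the shell and accumulates class
#' fractions weighted by in-shell voxel counts. When no VOI meets the
#' occupancy rule (very thin shells), falls back to classifying the shell
#' voxel-wise in a single pooled block per connected 15^3 tile with
#' occupancy 0. Fibrosis is the summed GG + R + HC fraction; low
#' attenuation is the LA fraction.
#'
#' @param volume A [ct_volume()].
#' @param shell A [voxel_mask()].
#' @param thresholds A [parenchyma_thresholds()].
#' @param voi_size,min_occupancy Passed to [tile_vois()].
#' @return A list of class `parenchyma_summary`: the five fractions
#'   (`fraction_normal`, `fraction_LA`, `fraction_GG`,
#'   `fraction_reticular`, `fraction_HC`, summing to 1), `fibrosis`,
#'   `low_attenuation`, and `n_vois`.
#' @export
summarize_parenchyma <- function(volume, shell,
                                 thresholds = parenchyma_thresholds(),
                                 voi_size = 15, min_occupancy = 0.3) {
  vois <- tile_vois(volume, shell, voi_size, min_occupancy)
  if (length(vois) == 0) {
    vois <- tile_vois(volume, shell, voi_size, min_occupancy = 0)
    if (length(vois) == 0) stop("no classifiable region in shell")
  }
  classes <- vapply(vois, classify_voi, character(1),
                    thresholds = thresholds)
  w <- vapply(vois, function(v) v$n_shell, numeric(1))
  tot <- sum(w)
  frac <- vapply(c(N = "N", LA = "LA", GG = "GG", R = "R", HC = "HC"),
                 function(cl) sum(w[classes == cl]) / tot, numeric(1))
  structure(list(
    fraction_normal = unname(frac["N"]),
    fraction_LA = unname(frac["LA"]),
    fraction_GG = unname(frac["GG"]),
    fraction_reticular = unname(frac["R"]),
    fraction_HC = unname(frac["HC"]),
    fibrosis = unname(frac["GG"] + frac["R"] + frac["HC"]),
    low_attenuation = unname(frac["LA"]),
    n_vois = length(vois)), class = "parenchyma_summary")
}

#' @export
print.parenchyma_summary <- function(x, ...) {
  cat(sprintf(paste0("<parenchyma_summary> N=%.2f LA=%.2f GG=%.2f R=%.2f ",
                     "HC=%.2f | fibrosis=%.2f low_attenuation=%.2f ",
                     "(%d VOIs)\n"),
              x$fraction_normal, x$fraction_LA, x$fraction_GG,
              x$fraction_reticular, x$fraction_HC, x$fibrosis,
              x$low_attenuation, x$n_vois))
  invisible(x)
}
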