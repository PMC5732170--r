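#' Segment the lung parenchyma of a CT volume
#'
#' Threshold-and-component lung masking: voxels below `air_threshold` HU are
#' candidate air/parenchyma; the component touching the volume border
#' (outside air) is discarded; the largest remaining components (both lungs)
#' are kept and in-plane holes (vessels, nodules) are filled.
#'
#' @param volume A [ct_volume()] in HU.
#' @param air_threshold HU below which a voxel counts as air/parenchyma.
#'   Default -300 separates lung (about -850) and soft tissue (>= 0).
#' @param keep_ratio Components at least this fraction of the largest
#'   component's size are retained (so two lungs survive).
#' @return A [voxel_mask()] of the lung.
#' @export
segment_lung <- function(volume, air_threshold = -300, keep_ratio = 0.25) {
  stopifnot(inherits(volume, "ct_volume"))
  cand <- volume$data < air_threshold
  if (!any(cand)) stop("no lung-like component found (no voxels below ",
                       air_threshold, " HU)")
  d <- dim(cand)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood_fill3d(cand, border & cand, connectivity = 6)
  interior <- cand & !outside
  if (!any(interior)) stop("no lung-like component found after removing ",
                           "border-connected air")
  cc <- label_components(interior, connectivity = 26)
  keep <- which(cc$sizes >= keep_ratio * cc$sizes[1])
  lung <- array(cc$labels %in% keep, d)
  lung <- fill_holes_inplane(lung)
  voxel_mask(lung, spacing = volume$spacing, origin = volume$origin)
}

#' Seeded region growing of a nodule
#'
#' Grows from a user-placed seed through all connected voxels whose HU lies
#' in `[hu_low, hu_high]` (ground-glass through solid attenuation by
#' default), then fills in-plane holes. The default bounds span ground-glass
#' to solid tumor density; they are configuration, not a claim about any
#' particular clinical tool's internal thresholds.
#'
#' @param volume A [ct_volume()].
#' @param seed Integer voxel index triple (1-based, x/y/z).
#' @param hu_low,hu_high Inclusive HU bounds for region membership.
#' @param connectivity 6, 18 or 26 (default) neighborhood.
#' @return A [voxel_mask()] of the grown nodule.
#' @export
grow_nodule <- function(volume, seed, hu_low = -750, hu_high = 200,
                        connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"))
  if (hu_low >= hu_high) stop("hu_low must be below hu_high")
  seed <- check_in_bounds(seed, dim(volume$data), "seed")
  hu_seed <- volume$data[seed[1], seed[2], seed[3]]
  if (hu_seed < hu_low || hu_seed > hu_high)
    stop("seed voxel HU (", round(hu_seed), ") outside growth bounds [",
         hu_low, ", ", hu_high, "]; seed appears misplaced")
  cand <- volume$data >= hu_low & volume$data <= hu_high
  sd_arr <- array(FALSE, dim(volume$data))
  sd_arr[seed[1], seed[2], seed[3]] <- TRUE
  grown <- flood_fill3d(cand, sd_arr, connectivity)
  grown <- fill_holes_inplane(grown)
  voxel_mask(grown, spacing = volume$spacing, origin = volume$origin)
}

#' Manually edit a mask
#'
#' Applies user additions and removals to a segmentation, mirroring the
#' review step in which a reader ensures the whole nodule volume is
#' captured. Removals win when a voxel appears in both sets. The edit is
#' recorded in the `edit_log` attribute.
#'
#' @param mask A [voxel_mask()].
#' @param additions,removals Integer matrices with 3 columns (x, y, z voxel
#'   indices, 1-based), or `NULL`.
#' @return The edited [voxel_mask()] with an `edit_log` attribute.
#' @export
edit_mask <- function(mask, additions = NULL, removals = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- dim(mask$data)
  as_idx <- function(m, what) {
    if (is.null(m) || NROW(m) == 0) return(NULL)
    m <- matrix(as.integer(m), ncol = 3)
    if (anyNA(m) || any(m < 1L) || any(m > matrix(d, nrow(m), 3, byrow = TRUE)))
      stop(what, " contain out-of-bounds voxel indices")
    m
  }
  add <- as_idx(additions, "additions")
  rem <- as_idx(removals, "removals")
  out <- mask$data
  if (!is.null(add)) out[add] <- TRUE
  if (!is.null(rem)) out[rem] <- FALSE
  res <- voxel_mask(out, spacing = mask$spacing, origin = mask$origin)
  log_prev <- attr(mask, "edit_log")
  attr(res, "edit_log") <- c(log_prev, list(list(
    n_added = if (is.null(add)) 0L else nrow(add),
    n_removed = if (is.null(rem)) 0L else nrow(rem),
    timestamp = NA_character_)))
  res
}

#' Peritumoral shell of tumor-free lung
#'
#' The rind of lung within `distance_mm` (Euclidean, anisotropic spacing) of
#' the nodule surface, excluding the nodule itself: the region whose
#' parenchymal texture is scored for fibrosis and low attenuation.
#'
#' @param nodule,lung [voxel_mask()]s on the same grid.
#' @param distance_mm Shell thickness in mm, measured from the nodule
#'   boundary (default 10).
#' @return A [voxel_mask()]; always a subset of `lung`, disjoint from
#'   `nodule`.
#' @export
peritumoral_shell <- function(nodule, lung, distance_mm = 10) {
  stopifnot(inherits(nodule, "voxel_mask"), inherits(lung, "voxel_mask"))
  check_same_geometry(nodule, lung)
  if (distance_mm <= 0) stop("distance_mm must be positive")
  if (!any(nodule$data)) stop("empty nodule mask")
  d2 <- edt_squared(nodule$data, nodule$spacing)
  shell <- d2 <= distance_mm^2 & lung$data & !nodule$data
  voxel_mask(shell, spacing = nodule$spacing, origin = nodule$origin)
}
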