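#' CT volume in Hounsfield units
#'
#' Constructs a 3-D CT volume: an array of Hounsfield unit (HU) values plus
#' the grid geometry (voxel spacing in mm per axis and a world origin).
#' Axes are ordered x, y, z; voxel indices are 1-based in R convention.
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing Numeric length-3, mm per voxel along x, y, z. Must be > 0.
#' @param origin Numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(-850, c(8, 8, 4)), spacing = c(0.7, 0.7, 2.5))
#' dim(v)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array of HU values")
  if (any(dim(data) == 0L)) stop("volume grid is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (!all(is.finite(data))) stop("HU values must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Binary voxel mask aligned to a CT volume
#'
#' A mask lives on exactly the grid of its parent volume: same shape, same
#' spacing. Masks are never resampled.
#'
#' @param data 3-D logical (or 0/1) array.
#' @param spacing,origin Grid geometry, as in [ct_volume()].
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
dim.voxel_mask <- function(x) dim(x$data)

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n  HU range [", round(min(x$data)), ", ", round(max(x$data)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", paste(dim(x$data), collapse = " x "),
      " grid, ", sum(x$data), " voxels in mask (",
      format(mask_volume_cc(x), digits = 4), " cc)\n", sep = "")
  invisible(x)
}

# shared-geometry check used by every two-mask operation
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid shape mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("voxel spacing mismatch")
  invisible(TRUE)
}

#' Physical volume of a mask in cubic centimetres
#'
#' Voxel count times the voxel volume implied by the anisotropic spacing,
#' converted from mm^3 to cc.
#'
#' @param mask A [voxel_mask()].
#' @return Volume in cc.
#' @examples
#' m <- voxel_mask(array(TRUE, c(10, 10, 10)))  # 1 mm isotropic
#' mask_volume_cc(m)  # 1 cc
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

# Validate a voxel index triple (1-based) against a grid
check_in_bounds <- function(idx, dims, what = "voxel index") {
  idx <- as.integer(idx)
  if (length(idx) != 3L || anyNA(idx))
    stop(what, " must be an integer triple")
  if (any(idx < 1L) || any(idx > dims))
    stop(what, " ", paste(idx, collapse = ","), " outside grid bounds ",
         paste(dims, collapse = "x"))
  idx
}
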