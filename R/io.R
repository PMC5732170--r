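#' Read a CT volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and raw-encoded NRRD
#' (`.nrrd`). DICOM series directories are not supported by this build and
#' raise an informative error.
#'
#' @param path File path (or directory for DICOM, which errors).
#' @param format One of `"auto"`, `"nifti"`, `"nrrd"`, `"dicom"`. `"auto"`
#'   infers from the file extension.
#' @return A [ct_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else stop("cannot infer format from path: ", path)
  }
  if (format == "dicom")
    stop("DICOM series reading is not supported; convert to NIfTI or NRRD")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    if (length(dim(arr)) != 3L) stop("expected a 3-D volume, got ",
                                     length(dim(arr)), " dims")
    sp <- RNifti::pixdim(img)[1:3]
    return(ct_volume(arr, spacing = sp))
  }
  read_nrrd(path)
}

#' Write a CT volume to disk
#'
#' @param volume A [ct_volume()].
#' @param path Output path; extension selects the format under `"auto"`.
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (format == "nifti") {
    arr <- volume$data
    attr(arr, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(arr, datatype = "double")
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(volume, path)
  }
  invisible(path)
}

#' Write a voxel mask as unsigned 8-bit NIfTI
#'
#' @param mask A [voxel_mask()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  attr(arr, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path NIfTI path.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_mask(array(as.numeric(img) != 0, dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3])
}

# --- minimal NRRD (raw encoding, little-endian, 3-D double) ---------------
# Detached headers, compressed encodings and non-double types are out of
# scope; enough for lossless phantom interchange.

write_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(dim(volume$data), collapse = " ")),
           paste("spacings:", paste(format(volume$spacing, digits = 17),
                                    collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated NRRD header")
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  if (!identical(fields$encoding, "raw"))
    stop("only raw NRRD encoding supported, got: ", fields$encoding)
  if (!identical(fields$type, "double"))
    stop("only double NRRD type supported, got: ", fields$type)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("expected 3-D NRRD")
  spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  vals <- readBin(con, "double", n = prod(sizes), size = 8, endian = "little")
  if (length(vals) != prod(sizes)) stop("truncated NRRD data")
  ct_volume(array(vals, dim = sizes), spacing = spacing)
}
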