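#' Write an image/mask case pair as NIfTI files
#'
#' Cases follow the `<case>_img.nii.gz` / `<case>_seg.nii.gz` naming
#' convention. Images are stored as float64 so voxel data round-trips
#' bitwise; masks are stored as int16. Array index order is
#' (row, col\[, slice\]), matching the order of the spacing vector;
#' 2D cases are written as 2-dimensional NIfTI volumes.
#'
#' @param case a list with elements `image` (numeric array), `mask`
#'   (integer array of equal shape) and `spacing` (mm per voxel, one entry
#'   per axis). Extra elements are ignored.
#' @param dir output directory (created if missing).
#' @param name case identifier used as file stem.
#' @return invisibly, the two file paths.
#' @export
write_case <- function(case, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- case$image
  msk <- case$mask
  if (!identical(dim(img), dim(msk))) stopf("inconsistent case: image/mask shape mismatch")
  if (length(case$spacing) != length(dim(img))) stopf("invalid metadata: spacing length")
  fi <- file.path(dir, paste0(name, "_img.nii.gz"))
  fm <- file.path(dir, paste0(name, "_seg.nii.gz"))
  ni <- RNifti::asNifti(img)
  RNifti::pixdim(ni) <- case$spacing
  RNifti::writeNifti(ni, fi, datatype = "double")
  nm <- RNifti::asNifti(array(as.integer(msk), dim(msk)))
  RNifti::pixdim(nm) <- case$spacing
  RNifti::writeNifti(nm, fm, datatype = "int16")
  invisible(c(fi, fm))
}

#' Read an image/mask case pair
#'
#' @param dir directory containing the pair.
#' @param name case identifier (file stem without `_img`/`_seg`).
#' @return a list with `image`, `mask`, `spacing`, `name`.
#' @export
read_case <- function(dir, name) {
  fi <- file.path(dir, paste0(name, "_img.nii.gz"))
  fm <- file.path(dir, paste0(name, "_seg.nii.gz"))
  if (!file.exists(fi) || !file.exists(fm)) {
    stopf("inconsistent case: missing pair member for '%s'", name)
  }
  img <- RNifti::readNifti(fi)
  msk <- RNifti::readNifti(fm)
  sp <- as.numeric(RNifti::pixdim(img))
  ia <- array(as.numeric(img), dim(img))
  ma <- array(as.integer(msk), dim(msk))
  if (!identical(dim(ia), dim(ma))) stopf("inconsistent case: image/mask shape mismatch for '%s'", name)
  if (any(sp <= 0) || length(sp) != length(dim(ia))) stopf("invalid metadata: nonpositive or missing spacing for '%s'", name)
  list(image = ia, mask = ma, spacing = sp, name = name)
}

#' List case identifiers in a dataset directory
#'
#' @param dir dataset directory of `*_img.nii.gz` / `*_seg.nii.gz` pairs.
#' @return sorted character vector of case stems.
#' @export
list_cases <- function(dir) {
  f <- list.files(dir, pattern = "_img\\.nii(\\.gz)?$")
  sort(sub("_img\\.nii(\\.gz)?$", "", f))
}

#' Read all cases in a directory
#'
#' @param dir dataset directory.
#' @return list of cases as returned by [read_case()].
#' @export
read_dataset <- function(dir) {
  ids <- list_cases(dir)
  if (!length(ids)) stopf("no cases in '%s'", dir)
  lapply(ids, function(id) read_case(dir, id))
}
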