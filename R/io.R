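#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti. Volumes are written as NIfTI-1 with the
#' affine stored in the qform (code 2) and `double` data so that a written
#' volume re-reads to an identical array. 4D data (tensor components, radial
#' field, DWI) use the last dimension for volumes.
#'
#' @param x Numeric or integer array (3D or 4D).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a list with `data` (array) and `affine`.
#' @export
write_volume <- function(x, affine, path) {
  x[is.na(x)] <- NaN
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = as.array(img), affine = unclass(matrix(aff, 4, 4)))
}

write_metrics_csv <- function(df, path) {
  write.csv(format(df, digits = 6, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
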