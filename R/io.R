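#' NIfTI-1 input/output for pipeline arrays
#'
#' Thin wrappers around RNifti that attach the voxel-to-mm affine as the
#' sform/qform. `write_dwi()` writes the 4D signal plus FSL-style bval/bvec
#' sidecars; `read_dwi()` reads them back into the structure [fit_tensor()]
#' accepts. Uncompressed `.nii` is used by default so that repeated runs are
#' byte-identical (gzip streams embed metadata).
#'
#' @param x 3D/4D numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti_array <- function(x, affine, path) {
  img <- RNifti::asNifti(x)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_array
#' @export
read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(array = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' @rdname write_nifti_array
#' @param dwi A `dwi_phantom` or compatible list.
#' @param prefix Path prefix; writes `<prefix>.nii`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti_array(dwi$signal, dwi$affine, paste0(prefix, ".nii"))
  write_bval_bvec(dwi$gtab, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_nifti_array
#' @export
read_dwi <- function(prefix) {
  nii <- if (file.exists(paste0(prefix, ".nii"))) paste0(prefix, ".nii")
  else paste0(prefix, ".nii.gz")
  img <- read_nifti_array(nii)
  list(signal = img$array, affine = img$affine,
       gtab = read_bval_bvec(paste0(prefix, ".bval"),
                             paste0(prefix, ".bvec")))
}

#' Write tensor-field component maps as NIfTI
#'
#' Writes `dxx`, `dyy`, `dzz`, `dxy`, `dxz`, `dyz` and, via [scalar_maps()],
#' `fa` and `md`, one file each.
#'
#' @param tf A `tensor_field`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_tensor_maps <- function(tf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  sm <- scalar_maps(tf)
  arrays <- c(lapply(comps, function(k) tf[[k]]),
              list(sm$fa, sm$md))
  names(arrays) <- c(comps, "fa", "md")
  paths <- vapply(names(arrays), function(nm) {
    a <- arrays[[nm]]
    a[is.na(a)] <- 0
    write_nifti_array(a, tf$affine, file.path(dir, paste0(nm, ".nii")))
  }, "")
  invisible(paths)
}
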