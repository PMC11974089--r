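#' Label masks for volumetry
#'
#' Wraps an integer 3D segmentation array with its voxel-to-mm affine and a
#' label dictionary. Every nonzero value present in the array must be named
#' in the dictionary. If tumor and edema labels were drawn independently
#' (for example, on different sequences) use [combine_tumor_edema()] first:
#' peritumoral edema is defined as the edema region excluding the tumor.
#'
#' @param array Integer 3D array of labels (0 = background).
#' @param affine 4x4 voxel-to-mm affine (RAS+).
#' @param labels Named integer vector mapping label names to values, e.g.
#'   `c(GM = 1, WM = 2, CSF = 3, tumor = 4, PTBE = 5)`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(array, affine = diag(4), labels = phantom_labels()) {
  if (length(dim(array)) != 3L) stop("label array must be 3D")
  vals <- array
  storage.mode(vals) <- "integer"
  if (any(vals < 0L)) stop("labels must be nonnegative")
  present <- setdiff(unique(as.vector(vals)), 0L)
  missing <- setdiff(present, labels)
  if (length(missing))
    stop("labels present in the array but absent from the dictionary: ",
         paste(missing, collapse = ", "))
  structure(list(array = vals, affine = affine, labels = labels),
            class = "label_mask")
}

#' Merge independently drawn tumor and edema masks
#'
#' Voxels marked in both masks are assigned to the tumor; a warning reports
#' the overlap count, and the returned PTBE region excludes it.
#'
#' @param tumor,edema Logical 3D arrays.
#' @param base Optional `label_mask` to write into; otherwise a fresh mask.
#' @param affine Affine for a fresh mask.
#' @return A `label_mask` with `tumor` and `PTBE` labels set.
#' @export
combine_tumor_edema <- function(tumor, edema, base = NULL, affine = diag(4)) {
  overlap <- sum(tumor & edema)
  if (overlap > 0)
    warning(overlap, " voxels labeled both tumor and edema; assigned to ",
            "tumor (PTBE excludes the tumor region)")
  L <- phantom_labels()
  if (is.null(base)) {
    arr <- array(0L, dim(tumor))
  } else arr <- base$array
  arr[edema & !tumor] <- L[["PTBE"]]
  arr[tumor] <- L[["tumor"]]
  label_mask(arr, if (is.null(base)) affine else base$affine)
}

#' Volume of one label in cm^3
#'
#' Counts voxels carrying the label and multiplies by the voxel volume,
#' `|det(A[1:3, 1:3])|` mm^3 for affine `A` (correct for rotated and sheared
#' grids alike; a sheared affine additionally triggers a warning).
#'
#' @param mask A `label_mask`.
#' @param label Label name (in the dictionary) or integer value.
#' @return Volume in cm^3.
#' @examples
#' m <- label_mask(array(rep(c(4L, 0L), c(1000, 24)), c(32, 32, 1)),
#'                 diag(4))
#' mask_volume(m, "CSF")  # 1 cm^3 at 1 mm isotropic voxels
#' @export
mask_volume <- function(mask, label) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.character(label)) {
    if (!label %in% names(mask$labels))
      stop("label '", label, "' not in the dictionary (",
           paste(names(mask$labels), collapse = ", "), ")")
    label <- mask$labels[[label]]
  } else if (!label %in% mask$labels)
    stop("label value ", label, " not in the dictionary")
  A <- mask$affine[1:3, 1:3]
  G <- crossprod(A)                      # non-orthogonal columns mean shear
  if (max(abs(G[upper.tri(G)])) > 1e-8)
    warning("affine has shear; voxel volume still taken as |det|")
  sum(mask$array == label) * abs(det(A)) / 1000
}

#' CSF, tumor, and PTBE volumes for one subject
#'
#' @param mask A `label_mask` whose dictionary names `CSF` and, for
#'   patients, `tumor` and `PTBE`.
#' @return Named list `csf`, `tumor`, `ptbe` (cm^3) and `control_like`
#'   (`TRUE` when no tumor or PTBE label exists in the dictionary or the
#'   array, in which case those volumes are 0).
#' @export
subject_volumes <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (!"CSF" %in% names(mask$labels))
    stop("label dictionary must name a CSF label")
  vol_or_zero <- function(nm) {
    if (nm %in% names(mask$labels)) mask_volume(mask, nm) else 0
  }
  tumor <- vol_or_zero("tumor")
  ptbe <- vol_or_zero("PTBE")
  list(csf = mask_volume(mask, "CSF"), tumor = tumor, ptbe = ptbe,
       control_like = tumor == 0 && ptbe == 0)
}
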