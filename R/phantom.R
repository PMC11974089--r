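#' Specify a ventricle-level diffusion phantom
#'
#' Builds the parameter set for a block-geometry digital phantom of the slab
#' of brain at the level of the lateral ventricles, the plane where the
#' DTI-ALPS method is applied. Each hemisphere contains, lateral to a
#' CSF-filled ventricle box, a band of projection fibers (principal
#' diffusivity along z, superior-inferior) and a band of association fibers
#' (principal diffusivity along y, anterior-posterior). In both bands the
#' x-axis diffusivity models water movement along the perivascular spaces of
#' the medullary veins, which run left-right at this level; the multiplier
#' `alpha` scales it, so `alpha < 1` emulates glymphatic impairment.
#' Optionally a spherical tumor with a surrounding shell of peritumoral edema
#' (PTBE) is carved into one hemisphere.
#'
#' Axis convention (enforced throughout the package): RAS+ affine with
#' x = left-right, y = anterior-posterior, z = superior-inferior.
#'
#' @param shape Integer grid dimensions (x, y, z). Default `c(64, 64, 16)`.
#' @param voxel_size Voxel edge lengths in mm. Default `c(2, 2, 4)` (4 mm
#'   slices, matching a typical 2D DTI protocol).
#' @param alpha Perivascular diffusivity multiplier applied to Dxx inside the
#'   fiber bands; scalar or named vector `c(left=, right=)`. Must be > 0.
#' @param s0 Baseline (b = 0) signal amplitude.
#' @param snr Signal-to-noise ratio defining the Rician noise level
#'   `sigma = s0 / snr`; `Inf` for a noiseless phantom.
#' @param seed Integer seed used when noise is drawn.
#' @param d_gm,d_csf,d_tumor,d_edema Isotropic diffusivities (mm^2/s) for
#'   grey-matter-like tissue, ventricular CSF, tumor, and PTBE.
#' @param d_pvs Unscaled perivascular (x-axis) diffusivity inside fiber
#'   bands, mm^2/s. With the defaults the noiseless ALPS index is
#'   `d_pvs / d_radial * alpha = 1.4 * alpha`.
#' @param d_radial,d_axial Radial and axial fiber diffusivities, mm^2/s.
#' @param tumor_radius Tumor sphere radius in mm; 0 for a control phantom.
#' @param tumor_center Voxel-index (1-based) center of the tumor, or `NULL`
#'   for a default position in `tumor_side`'s hemisphere.
#' @param ptbe_thickness Thickness in mm of the edema shell around the tumor.
#' @param tumor_side `"left"` or `"right"`; hemisphere holding the tumor.
#' @return An object of class `phantom_spec`.
#' @seealso [synthesize_dwi()]
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L), voxel_size = c(2, 2, 4),
                         alpha = c(left = 1, right = 1), s0 = 1000,
                         snr = Inf, seed = 1L,
                         d_gm = 0.8e-3, d_csf = 3.0e-3,
                         d_tumor = 1.0e-3, d_edema = 1.2e-3,
                         d_pvs = 0.63e-3, d_radial = 0.45e-3,
                         d_axial = 1.4e-3,
                         tumor_radius = 0, tumor_center = NULL,
                         ptbe_thickness = 0, tumor_side = "left") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("shape must be three integers >= 4")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (length(alpha) == 1L) alpha <- c(left = unname(alpha), right = unname(alpha))
  if (is.null(names(alpha))) names(alpha) <- c("left", "right")
  if (any(alpha <= 0)) stop("alpha must be > 0")
  d <- c(d_gm, d_csf, d_tumor, d_edema, d_pvs, d_radial, d_axial)
  if (any(d <= 0)) stop("all diffusivities must be > 0")
  if (snr <= 0) stop("snr must be > 0 (use Inf for noiseless)")
  tumor_side <- match.arg(tumor_side, c("left", "right"))
  structure(list(shape = shape, voxel_size = voxel_size, alpha = alpha,
                 s0 = s0, snr = snr, seed = as.integer(seed),
                 d_gm = d_gm, d_csf = d_csf, d_tumor = d_tumor,
                 d_edema = d_edema, d_pvs = d_pvs, d_radial = d_radial,
                 d_axial = d_axial, tumor_radius = tumor_radius,
                 tumor_center = tumor_center,
                 ptbe_thickness = ptbe_thickness, tumor_side = tumor_side),
            class = "phantom_spec")
}

#' Integer labels used in phantom label masks
#'
#' @return Named integer vector mapping region names to mask values.
#' @export
phantom_labels <- function() {
  c(background = 0L, GM = 1L, WM_projection = 2L, WM_association = 3L,
    CSF = 4L, tumor = 5L, PTBE = 6L)
}

# 1-based inclusive index range for a fractional interval of an axis
.frac_range <- function(lo, hi, n) {
  a <- max(1L, as.integer(ceiling(lo * n)))
  b <- min(n, as.integer(floor(hi * n)))
  if (b < a) integer(0) else a:b
}

# region label array + hemisphere array for a phantom spec
.phantom_geometry <- function(spec) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  lab <- array(phantom_labels()[["GM"]], dim = spec$shape)
  hemi <- array(2L, dim = spec$shape)  # 1 = left, 2 = right
  hemi[seq_len(nx %/% 2), , ] <- 1L
  yr <- .frac_range(0.30, 0.70, ny)
  zr <- .frac_range(0.30, 0.70, nz)
  place <- function(xlo, xhi, yy, zz, value) {
    xs <- .frac_range(xlo, xhi, nx)
    if (length(xs) && length(yy) && length(zz))
      lab[xs, yy, zz] <<- value
  }
  L <- phantom_labels()
  # ventricles hug the midline; fiber bands sit laterally, spanning all slices
  place(0.40, 0.47, yr, zr, L[["CSF"]])
  place(0.53, 0.60, yr, zr, L[["CSF"]])
  place(0.24, 0.34, yr, seq_len(nz), L[["WM_projection"]])
  place(0.66, 0.76, yr, seq_len(nz), L[["WM_projection"]])
  place(0.10, 0.20, yr, seq_len(nz), L[["WM_association"]])
  place(0.80, 0.90, yr, seq_len(nz), L[["WM_association"]])
  if (spec$tumor_radius > 0) {
    ctr <- spec$tumor_center
    if (is.null(ctr)) {
      cx <- if (spec$tumor_side == "left") 0.22 else 0.78
      ctr <- round(c(cx, 0.78, 0.5) * spec$shape)
    }
    mm <- sweep(which(array(TRUE, spec$shape), arr.ind = TRUE), 2, ctr, "-")
    mm <- sweep(mm, 2, spec$voxel_size, "*")
    dist <- sqrt(rowSums(mm^2))
    tum <- array(dist <= spec$tumor_radius, spec$shape)
    if (any(tum & lab == L[["CSF"]]))
      stop("tumor sphere overlaps the ventricle region; move tumor_center ",
           "or shrink tumor_radius")
    if (spec$ptbe_thickness > 0) {
      shell <- array(dist <= spec$tumor_radius + spec$ptbe_thickness,
                     spec$shape) & !tum & lab != L[["CSF"]]
      lab[shell] <- L[["PTBE"]]
    }
    lab[tum] <- L[["tumor"]]
  }
  list(labels = lab, hemisphere = hemi)
}

# diagonal generating tensor (mm^2/s) for a region label on one side
.region_diag <- function(spec, label, side) {
  L <- phantom_labels()
  a <- spec$alpha[[side]]
  if (label == L[["GM"]])             rep(spec$d_gm, 3)
  else if (label == L[["CSF"]])       rep(spec$d_csf, 3)
  else if (label == L[["tumor"]])     rep(spec$d_tumor, 3)
  else if (label == L[["PTBE"]])      rep(spec$d_edema, 3)
  else if (label == L[["WM_projection"]])
    c(a * spec$d_pvs, spec$d_radial, spec$d_axial)
  else if (label == L[["WM_association"]])
    c(a * spec$d_pvs, spec$d_axial, spec$d_radial)
  else rep(0, 3)
}

#' Ground-truth generating tensor of a phantom region
#'
#' @param phantom A `dwi_phantom` from [synthesize_dwi()].
#' @param label Region name (see [phantom_labels()]) or integer label.
#' @param side `"left"` or `"right"`.
#' @return Length-3 numeric: the diagonal (Dxx, Dyy, Dzz) of the generating
#'   tensor in mm^2/s (off-diagonals are zero by construction).
#' @export
phantom_region_tensor <- function(phantom, label, side = "left") {
  if (is.character(label)) label <- phantom_labels()[[label]]
  .region_diag(phantom$spec, label, match.arg(side, c("left", "right")))
}

#' Synthesize a diffusion-weighted volume from a phantom specification
#'
#' Evaluates the Stejskal-Tanner signal equation
#' `S = S0 * exp(-b * g' D g)` voxelwise, with `D` the diagonal generating
#' tensor of the voxel's region (projection bands have their largest diagonal
#' element on z, association bands on y, ventricles isotropic CSF), and adds
#' Rician noise as the magnitude of a complex Gaussian perturbation with
#' `sigma = s0 / snr` when `snr` is finite. Background voxels have zero
#' signal. Output is bit-identical for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param gtab A [gradient_table()].
#' @return An object of class `dwi_phantom`: list with `signal` (4D array,
#'   x-y-z-volume), `affine` (4x4 RAS+ voxel-to-mm), `gtab`, `labels`
#'   (integer 3D array, see [phantom_labels()]), `hemisphere` (3D array,
#'   1 = left, 2 = right), and `spec`.
#' @export
synthesize_dwi <- function(spec, gtab) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(gtab, "gradient_table"))
  geo <- .phantom_geometry(spec)
  nvol <- length(gtab$bvals)
  nvox <- prod(spec$shape)
  sig <- matrix(0, nvox, nvol)
  g2 <- gtab$bvecs^2                      # diagonal tensors: only g_i^2 terms
  key <- paste(geo$labels, geo$hemisphere)
  for (k in unique(key)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    label <- as.integer(parts[1])
    if (label == 0L) next
    side <- c("left", "right")[as.integer(parts[2])]
    dvec <- .region_diag(spec, label, side)
    atten <- exp(-gtab$bvals * as.vector(g2 %*% dvec))
    sig[key == k, ] <- rep(spec$s0 * atten, each = sum(key == k))
  }
  if (is.finite(spec$snr)) {
    set.seed(spec$seed)
    sigma <- spec$s0 / spec$snr
    sig <- sqrt((sig + sigma * stats::rnorm(length(sig)))^2 +
                  (sigma * stats::rnorm(length(sig)))^2)
  }
  affine <- diag(c(spec$voxel_size, 1))
  affine[1:3, 4] <- -spec$voxel_size * spec$shape / 2
  structure(list(signal = array(sig, c(spec$shape, nvol)), affine = affine,
                 gtab = gtab, labels = geo$labels,
                 hemisphere = geo$hemisphere, spec = spec),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat("DWI phantom: grid ", paste(x$spec$shape, collapse = "x"), " at ",
      paste(x$spec$voxel_size, collapse = "x"), " mm, ",
      length(x$gtab$bvals), " volumes, SNR = ", x$spec$snr, "\n", sep = "")
  tab <- table(factor(x$labels, levels = phantom_labels(),
                      labels = names(phantom_labels())))
  print(tab[tab > 0])
  invisible(x)
}
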