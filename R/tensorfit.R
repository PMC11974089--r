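#' Fit the diffusion tensor voxelwise by log-linear least squares
#'
#' Linearizes the Stejskal-Tanner equation,
#' `ln S_i = ln S0 - b_i * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz +
#' 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)`,
#' and solves the resulting 7-unknown linear system per voxel over all
#' volumes. `method = "ols"` is the plain least-squares solution;
#' `method = "wls"` performs one reweighting iteration with weights equal to
#' the squared predicted signal, which counters the log-transform's
#' heteroscedasticity and mirrors common DTI fitting practice. With noiseless
#' data both methods recover the generating tensor exactly (the log-linear
#' model is exact).
#'
#' Signals are floored at `1e-6 * S0` (per-voxel mean b=0 signal) before the
#' logarithm. Negative fitted diagonal diffusivities are kept as-is: the ALPS
#' computation averages raw axis diffusivities, and clamping would bias the
#' ratio. They are clamped only when deriving eigenvalue maps in
#' [scalar_maps()].
#'
#' The diagonal elements `Dxx`, `Dyy`, `Dzz` are reported in the scanner
#' frame (not eigenvalues), which is what the ALPS index requires.
#'
#' @param dwi A `dwi_phantom`, or any list with elements `signal` (4D array),
#'   `gtab` ([gradient_table()]) and `affine`.
#' @param mask Logical 3D array of voxels to fit, or `NULL` to fit every
#'   voxel whose mean b=0 signal is positive.
#' @param method `"wls"` (default) or `"ols"`.
#' @return An object of class `tensor_field`: list of 3D arrays `dxx`, `dyy`,
#'   `dzz`, `dxy`, `dxz`, `dyz` (mm^2/s, `NA` outside the mask), `log_s0`,
#'   plus `mask`, `affine` and `method`.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("wls", "ols")) {
  method <- match.arg(method)
  gtab <- dwi$gtab
  stopifnot(inherits(gtab, "gradient_table"))
  sig <- dwi$signal
  dims <- dim(sig)
  if (length(dims) != 4L || dims[4] != length(gtab$bvals))
    stop("signal must be 4D with one volume per gradient-table entry")
  nz <- gtab$bvals > 0
  dirs <- gtab$bvecs[nz, , drop = FALSE]
  # antipodal directions are equivalent for diffusion encoding: canonicalize
  # each vector's overall sign before counting distinct directions
  sgn <- sign(dirs[, 1])
  sgn[sgn == 0] <- sign(dirs[sgn == 0, 2])
  sgn[sgn == 0] <- sign(dirs[sgn == 0, 3])
  ndir <- nrow(unique(round(dirs * sgn, 6)))
  if (ndir < 6L)
    stop("need >= 6 distinct nonzero-b directions (found ", ndir, ")")

  g <- gtab$bvecs; b <- gtab$bvals
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qx <- qr(X)
  if (qx$rank < 7L) {
    bad <- apply(g[nz, , drop = FALSE], 1, paste, collapse = ",")
    stop("rank-deficient tensor design matrix (rank ", qx$rank,
         " < 7); direction set: ", paste(unique(bad), collapse = "; "))
  }

  smat <- matrix(sig, prod(dims[1:3]), dims[4])
  s0 <- rowMeans(smat[, !nz, drop = FALSE])
  if (is.null(mask)) mask <- array(s0 > 0, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("mask contains no voxels")
  floor_s <- pmax(1e-6 * s0[idx], .Machine$double.xmin)
  Y <- log(pmax(t(smat[idx, , drop = FALSE]), rep(floor_s, each = dims[4])))

  theta <- qr.coef(qx, Y)                                   # 7 x nvox OLS
  if (method == "wls") {
    W <- exp(2 * (X %*% theta))                             # predicted^2
    # normal equations assembled in bulk: 28 unique entries of X'WX
    pairs <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
    P <- X[, pairs[, 1]] * X[, pairs[, 2]]                  # nvol x 28
    M <- crossprod(P, W)                                    # 28 x nvox
    R <- crossprod(X, W * Y)                                # 7 x nvox
    theta_w <- theta
    A <- matrix(0, 7, 7)
    for (v in seq_len(ncol(Y))) {
      A[cbind(pairs[, 1], pairs[, 2])] <- M[, v]
      A[cbind(pairs[, 2], pairs[, 1])] <- M[, v]
      est <- tryCatch(solve(A, R[, v]), error = function(e) NULL)
      if (!is.null(est)) theta_w[, v] <- est
    }
    theta <- theta_w
  }

  blank <- array(NA_real_, dims[1:3])
  put <- function(row) { a <- blank; a[idx] <- theta[row, ]; a }
  structure(list(log_s0 = put(1), dxx = put(2), dyy = put(3), dzz = put(4),
                 dxy = put(5), dxz = put(6), dyz = put(7),
                 mask = mask, affine = dwi$affine, method = method),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("Tensor field: grid ", paste(dim(x$mask), collapse = "x"), ", ",
      sum(x$mask), " fitted voxels (", x$method, ")\n", sep = "")
  md <- (x$dxx + x$dyy + x$dzz) / 3
  cat("  median MD inside mask: ",
      format(stats::median(md[x$mask], na.rm = TRUE), digits = 4),
      " mm^2/s\n", sep = "")
  invisible(x)
}

#' Scalar maps from a tensor field
#'
#' Per-voxel eigendecomposition of the symmetric tensor. Eigenvalues are
#' clamped below at zero before computing fractional anisotropy
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` and mean
#' diffusivity `MD = mean(lambda)`. Degenerate (all-zero) tensors yield
#' `FA = 0` by convention. The direction-encoded color triplet is
#' `|e1| * FA`, with `e1` the principal eigenvector.
#'
#' @param tf A `tensor_field` from [fit_tensor()].
#' @return An object of class `scalar_maps`: list with 3D arrays `fa`, `md`,
#'   4D arrays `e1` and `color` (last dimension 3), and `affine`.
#' @export
scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$mask)
  fa <- md <- array(NA_real_, dims)
  e1 <- color <- array(NA_real_, c(dims, 3))
  idx <- which(tf$mask)
  n <- prod(dims)
  for (v in idx) {
    D <- matrix(c(tf$dxx[v], tf$dxy[v], tf$dxz[v],
                  tf$dxy[v], tf$dyy[v], tf$dyz[v],
                  tf$dxz[v], tf$dyz[v], tf$dzz[v]), 3, 3)
    if (anyNA(D)) next
    ed <- eigen(D, symmetric = TRUE)
    lam <- pmax(ed$values, 0)
    md[v] <- mean(lam)
    nrm <- sqrt(sum(lam^2))
    fa[v] <- if (nrm > 0) sqrt(1.5 * sum((lam - mean(lam))^2)) / nrm else 0
    vec <- ed$vectors[, 1]
    e1[v + n * (0:2)] <- vec
    color[v + n * (0:2)] <- abs(vec) * fa[v]
  }
  structure(list(fa = fa, md = md, e1 = e1, color = color,
                 affine = tf$affine), class = "scalar_maps")
}

#' @export
plot.tensor_field <- function(x, slice = NULL, ...) {
  sm <- scalar_maps(x)
  if (is.null(slice)) slice <- ceiling(dim(x$mask)[3] / 2)
  fa <- sm$fa[, , slice]
  fa[is.na(fa)] <- 0
  graphics::image(fa, col = grDevices::grey.colors(128, 0, 1), asp = 1,
                  main = paste("FA, slice", slice), ...)
  invisible(sm)
}
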