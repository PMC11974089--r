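#' Diffusion gradient tables
#'
#' A gradient table couples the b-value (diffusion weighting, s/mm^2) of every
#' volume in a 4D diffusion-weighted acquisition with its unit encoding
#' direction. Volumes with `b = 0` carry no diffusion weighting and have a
#' zero direction vector. The same table drives both the Stejskal-Tanner
#' forward simulator ([synthesize_dwi()]) and the tensor fitter
#' ([fit_tensor()]).
#'
#' @param bvals Numeric vector of b-values, one per volume, in s/mm^2.
#' @param bvecs Numeric matrix with one row per volume and three columns
#'   (x, y, z). Rows for nonzero b-values must have unit Euclidean norm
#'   (tolerance 1e-6); rows for `b = 0` volumes must be zero.
#' @return An object of class `gradient_table`: a list with elements `bvals`
#'   and `bvecs`.
#' @seealso [make_gradient_table()] for generating well-spread direction sets,
#'   [read_bval_bvec()] / [write_bval_bvec()] for FSL-dialect text files.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  if (nrow(bvecs) != length(bvals))
    stop("bvecs must have one row per b-value (", length(bvals),
         " b-values, ", nrow(bvecs), " direction rows)")
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns")
  if (any(bvals < 0))
    stop("b-values must be nonnegative")
  if (!any(bvals == 0))
    stop("gradient table must contain at least one b=0 volume")
  nz <- bvals > 0
  norms <- sqrt(rowSums(bvecs^2))
  if (any(abs(norms[nz] - 1) > 1e-6))
    stop("nonzero-b directions must be unit vectors (max |norm - 1| = ",
         format(max(abs(norms[nz] - 1))), ")")
  if (any(norms[!nz] > 1e-12))
    stop("b=0 volumes must have zero direction vectors")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' Generate an approximately uniform diffusion-encoding scheme
#'
#' Places `n_directions` unit vectors on the sphere by the Fibonacci
#' (golden-angle) spiral, which spreads points nearly uniformly, and prepends
#' `n_b0` unweighted volumes. An optional seeded random rotation is applied to
#' the whole set so that repeated tables with different seeds are not axis
#' locked; the output is deterministic for a fixed seed.
#'
#' At least 6 distinct directions are required to determine the 6 independent
#' components of a symmetric diffusion tensor.
#'
#' @param n_directions Number of diffusion-encoding directions (>= 6).
#' @param b b-value for the weighted volumes, s/mm^2 (default 1000).
#' @param n_b0 Number of unweighted (b = 0) volumes to prepend (default 1).
#' @param seed Integer seed for the random rotation, or `NULL` for no
#'   rotation.
#' @return A [gradient_table()] with `n_b0 + n_directions` volumes.
#' @examples
#' gt <- make_gradient_table(48, b = 1000, n_b0 = 1, seed = 7)
#' length(gt$bvals)  # 49
#' @export
make_gradient_table <- function(n_directions, b = 1000, n_b0 = 1, seed = NULL) {
  if (n_directions < 6)
    stop("n_directions must be >= 6: a symmetric tensor has 6 independent ",
         "components and is underdetermined with fewer directions")
  if (n_b0 < 1)
    stop("at least one b=0 volume is required")
  i <- seq_len(n_directions) - 0.5
  phi <- pi * (1 + sqrt(5)) * i       # golden angle increments
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    rot <- local({
      set.seed(seed)
      qr.Q(qr(matrix(stats::rnorm(9), 3)))
    })
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    dirs <- dirs %*% rot
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_table(c(rep(0, n_b0), rep(b, n_directions)),
                 rbind(matrix(0, n_b0, 3), dirs))
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat("Gradient table: ", length(x$bvals), " volumes (", nb0, " b=0, ",
      length(x$bvals) - nb0, " weighted, max b = ", max(x$bvals),
      " s/mm^2)\n", sep = "")
  invisible(x)
}

#' Read and write FSL-dialect bval/bvec files
#'
#' The FSL convention stores b-values as a single space-separated row and
#' directions as three rows (x, y, z components across volumes).
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return `read_bval_bvec()` returns a [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L)
    stop("bvec file must have exactly 3 rows (x, y, z)")
  gradient_table(bvals, t(bv))
}

#' @rdname read_bval_bvec
#' @param gtab A [gradient_table()].
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  bv <- t(gtab$bvecs)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval = bval_path, bvec = bvec_path))
}
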