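#' Define a volume of interest for the ALPS computation
#'
#' A VOI is an in-plane square of `edge x edge` voxels on a single axial
#' slice, given by its center voxel. All voxel coordinates are 0-based, and
#' the box is half-open: an `edge = 2` VOI centered at `c(10, 20)` covers
#' x in \{9, 10\}, y in \{19, 20\}. The classical ALPS prescription uses
#' four 4-voxel VOIs per subject (projection and association fiber regions in
#' each hemisphere), which the default `edge = 2` realizes as a 2x2x1 square
#' on the slice at the level of the lateral ventricles.
#'
#' @param side `"left"` or `"right"` hemisphere.
#' @param fiber `"projection"` or `"association"`.
#' @param slice 0-based axial slice index.
#' @param center_xy 0-based voxel (x, y) center.
#' @param edge In-plane edge length in voxels (>= 2 so the VOI holds at
#'   least 4 voxels).
#' @return An object of class `alps_voi`.
#' @export
alps_voi <- function(side, fiber, slice, center_xy, edge = 2L) {
  side <- match.arg(side, c("left", "right"))
  fiber <- match.arg(fiber, c("projection", "association"))
  edge <- as.integer(edge)
  if (edge < 2L) stop("edge must be >= 2 so that the VOI holds >= 4 voxels")
  structure(list(side = side, fiber = fiber, slice = as.integer(slice),
                 center_xy = as.integer(center_xy), edge = edge),
            class = "alps_voi")
}

# 1-based array index sets of a VOI; errors if outside `dims`
.voi_indices <- function(voi, dims) {
  start <- voi$center_xy - voi$edge %/% 2 + 1L    # to 1-based
  xs <- start[1]:(start[1] + voi$edge - 1L)
  ys <- start[2]:(start[2] + voi$edge - 1L)
  z <- voi$slice + 1L
  if (min(xs) < 1L || max(xs) > dims[1] || min(ys) < 1L || max(ys) > dims[2]
      || z < 1L || z > dims[3])
    stop(voi$side, " ", voi$fiber, " VOI extends outside the volume")
  list(x = xs, y = ys, z = z)
}

#' Assemble the four ALPS VOIs
#'
#' @param ... Four [alps_voi()] objects: one projection and one association
#'   VOI for each hemisphere.
#' @return An object of class `alps_voi_set` (named list
#'   `left.projection`, `left.association`, `right.projection`,
#'   `right.association`).
#' @export
alps_voi_set <- function(...) {
  vois <- list(...)
  if (length(vois) == 1L && !inherits(vois[[1]], "alps_voi"))
    vois <- vois[[1]]
  if (!all(vapply(vois, inherits, TRUE, "alps_voi")))
    stop("all elements must be alps_voi objects")
  names(vois) <- vapply(vois, function(v) paste(v$side, v$fiber, sep = "."),
                        "")
  need <- c("left.projection", "left.association",
            "right.projection", "right.association")
  if (!setequal(names(vois), need))
    stop("need exactly one projection and one association VOI per ",
         "hemisphere; got: ", paste(names(vois), collapse = ", "))
  structure(vois[need], class = "alps_voi_set")
}

#' Automatic VOI placement on a phantom label mask
#'
#' Real-data VOIs are placed by a reader; on phantoms, placement is
#' automatic: for each hemisphere and fiber band, the VOI is centered on the
#' in-plane centroid of the band's labeled voxels on the chosen slice.
#'
#' @param labels Integer 3D label array (see [phantom_labels()]).
#' @param slice 0-based slice, or `NULL` for the middle slice (the phantom's
#'   lateral-ventricle level).
#' @param edge VOI edge in voxels.
#' @return An `alps_voi_set`.
#' @export
auto_alps_vois <- function(labels, slice = NULL, edge = 2L) {
  dims <- dim(labels)
  if (is.null(slice)) slice <- ceiling(dims[3] / 2) - 1L
  L <- phantom_labels()
  mid <- dims[1] %/% 2
  mk <- function(side, fiber) {
    lab <- if (fiber == "projection") L[["WM_projection"]] else
      L[["WM_association"]]
    sl <- labels[, , slice + 1L]
    hemi_x <- if (side == "left") seq_len(mid) else (mid + 1L):dims[1]
    hit <- which(sl[hemi_x, ] == lab, arr.ind = TRUE)
    if (!nrow(hit))
      stop("no ", fiber, " band voxels on slice ", slice, " (", side, ")")
    ctr <- round(colMeans(hit))
    ctr[1] <- ctr[1] + if (side == "left") 0L else mid
    alps_voi(side, fiber, slice, ctr - 1L, edge)  # back to 0-based
  }
  alps_voi_set(mk("left", "projection"), mk("left", "association"),
               mk("right", "projection"), mk("right", "association"))
}

#' Mean axis diffusivities over the ALPS VOIs
#'
#' For each hemisphere, computes the arithmetic mean over the VOI voxels of
#' the scanner-frame diagonal diffusivities the ALPS index uses: `Dxx` over
#' the projection VOI, `Dxx` over the association VOI, `Dyy` over the
#' projection VOI, and `Dzz` over the association VOI.
#'
#' @param tf A `tensor_field`.
#' @param vois An `alps_voi_set`.
#' @return Named list with elements `left` and `right`, each a named numeric
#'   `c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)` in mm^2/s.
#' @export
extract_voi_diffusivities <- function(tf, vois) {
  stopifnot(inherits(tf, "tensor_field"), inherits(vois, "alps_voi_set"))
  dims <- dim(tf$mask)
  voi_mean <- function(voi, comp) {
    ix <- .voi_indices(voi, dims)
    if (!all(tf$mask[ix$x, ix$y, ix$z]))
      stop(voi$side, " ", voi$fiber, " VOI includes voxels outside the fit mask")
    vals <- tf[[comp]][ix$x, ix$y, ix$z]
    if (any(!is.finite(vals))) {
      bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
      stop("non-finite ", comp, " at voxel (",
           ix$x[bad[1]] - 1L, ",", ix$y[bad[2]] - 1L, ",", voi$slice,
           ") in the ", voi$side, " ", voi$fiber, " VOI")
    }
    mean(vals)
  }
  one_side <- function(side) {
    pr <- vois[[paste0(side, ".projection")]]
    as_ <- vois[[paste0(side, ".association")]]
    c(dxx_proj = voi_mean(pr, "dxx"), dxx_assoc = voi_mean(as_, "dxx"),
      dyy_proj = voi_mean(pr, "dyy"), dzz_assoc = voi_mean(as_, "dzz"))
  }
  list(left = one_side("left"), right = one_side("right"))
}

#' The DTI-ALPS index
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`: the ratio
#' of the mean perivascular-direction (x) diffusivity in the two fiber
#' regions to the mean diffusivity perpendicular to both the fibers and the
#' perivascular direction. An isotropic medium gives 1; preferential
#' diffusion along the perivascular axis raises the index.
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc VOI-mean diffusivities,
#'   mm^2/s (see [extract_voi_diffusivities()]).
#' @return Unitless index.
#' @examples
#' alps_index(1.2e-3, 1.0e-3, 0.8e-3, 0.8e-3)  # 1.375
#' @export
alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(vals))) stop("all four diffusivities must be finite")
  den <- mean(c(dyy_proj, dzz_assoc))
  if (den <= 0)
    stop("denominator mean(Dyy_proj, Dzz_assoc) is ", format(den),
         " <= 0: unphysical fit")
  mean(c(dxx_proj, dxx_assoc)) / den
}

#' Per-subject ALPS indices
#'
#' Computes the ALPS index in each hemisphere, labels the hemispheres by the
#' tumor side (`tumor`/`contralateral`) or as `left`/`right` for controls,
#' and returns the bilateral mean. When several VOI sets are supplied (for
#' example, placements by two readers), the per-hemisphere indices are
#' averaged across sets.
#'
#' @param tf A `tensor_field`.
#' @param vois An `alps_voi_set`, or a list of them.
#' @param tumor_side `"left"`, `"right"`, or `NULL` for a control subject.
#' @return An object of class `alps_result`: list with `left`, `right`,
#'   `tumor_side`, `contralateral` (the latter two `NA` for controls),
#'   `bilateral_mean`, `side` annotation, and the per-hemisphere VOI-mean
#'   diffusivities of the first VOI set.
#' @export
subject_alps <- function(tf, vois, tumor_side = NULL) {
  if (inherits(vois, "alps_voi_set")) vois <- list(vois)
  if (!all(vapply(vois, inherits, TRUE, "alps_voi_set")))
    stop("vois must be an alps_voi_set or a list of them")
  per_set <- lapply(vois, function(vs) {
    d <- extract_voi_diffusivities(tf, vs)
    c(left = do.call(alps_index, as.list(unname(d$left))),
      right = do.call(alps_index, as.list(unname(d$right))))
  })
  idx <- colMeans(do.call(rbind, per_set))
  res <- list(left = idx[["left"]], right = idx[["right"]],
              tumor_side = NA_real_, contralateral = NA_real_,
              bilateral_mean = mean(idx), side = tumor_side %||% "control",
              diffusivities = extract_voi_diffusivities(tf, vois[[1]]))
  if (!is.null(tumor_side)) {
    tumor_side <- match.arg(tumor_side, c("left", "right"))
    res$tumor_side <- idx[[tumor_side]]
    res$contralateral <- idx[[setdiff(c("left", "right"), tumor_side)]]
  }
  structure(res, class = "alps_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alps_result <- function(x, ...) {
  cat("ALPS index: left = ", format(x$left, digits = 4), ", right = ",
      format(x$right, digits = 4), ", bilateral mean = ",
      format(x$bilateral_mean, digits = 4), "\n", sep = "")
  if (!is.na(x$tumor_side))
    cat("  tumor side (", x$side, ") = ", format(x$tumor_side, digits = 4),
        ", contralateral = ", format(x$contralateral, digits = 4), "\n",
        sep = "")
  invisible(x)
}

#' Read/write VOI definitions as JSON
#'
#' Each VOI is an object with fields `side`, `fiber`, `slice`, `center_xy`
#' and `edge` (voxel indices 0-based).
#'
#' @param vois An `alps_voi_set`.
#' @param path JSON file path.
#' @export
write_vois <- function(vois, path) {
  stopifnot(inherits(vois, "alps_voi_set"))
  jsonlite::write_json(lapply(unclass(vois), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vois
#' @export
read_vois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  alps_voi_set(lapply(raw, function(v)
    alps_voi(v$side, v$fiber, v$slice, unlist(v$center_xy), v$edge)))
}
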