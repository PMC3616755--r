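#' Read a brain MR volume
#'
#' Reads NIfTI-1 (\code{.nii}, \code{.nii.gz}) or Analyze 7.5
#' (\code{.hdr}/\code{.img}) volumes into an \code{\link{image_grid}}.
#' Analyze files carry no reliable orientation, so they are loaded with an
#' identity direction matrix and flagged \code{needs_reorient}; callers must
#' apply \code{\link{reorient}} with an explicit orientation before geometric
#' processing.
#'
#' @param path file path.
#' @return An \code{\link{image_grid}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path) && !file.exists(sub("\\.hdr$", ".img", path)))
    stop("file not found: ", path)
  is_analyze <- grepl("\\.(hdr|img)(\\.gz)?$", path, ignore.case = TRUE)
  img <- tryCatch({
    if (is_analyze) RNifti::readAnalyze(path) else RNifti::readNifti(path)
  }, error = function(e) stop("unreadable or unsupported volume '", path,
                              "': ", conditionMessage(e)))
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  if (is_analyze) {
    pd <- RNifti::pixdim(img)[1:3]
    pd[!is.finite(pd) | pd <= 0] <- 1
    return(image_grid(vox, spacing = pd, needs_reorient = TRUE))
  }
  xf <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  M <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1
  direction <- M %*% diag(1 / spacing)
  image_grid(vox, spacing = spacing, origin = xf[1:3, 4], direction = direction)
}

#' Write a volume to NIfTI-1
#'
#' @param img an \code{\link{image_grid}}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @param datatype storage type passed to \code{RNifti::writeNifti}
#'   (\code{"float"}, \code{"uint8"}, \code{"int16"}, ...).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(img, path, datatype = "float") {
  stopifnot(is_image_grid(img))
  xf <- diag(4)
  xf[1:3, 1:3] <- img$direction %*% diag(img$spacing)
  xf[1:3, 4] <- img$origin
  n <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(n) <- img$spacing
  RNifti::qform(n) <- structure(xf, code = 2L)
  RNifti::sform(n) <- structure(xf, code = 2L)
  RNifti::writeNifti(n, path, datatype = datatype)
  invisible(path)
}

#' Right-handed axis reorientations
#'
#' A reorientation is an axis permutation plus per-axis flips. Only the 24
#' right-handed combinations (permutation sign times the product of flips
#' equal to +1) are valid rigid reorientations.
#'
#' @return List of 24 \code{orientation} objects in a deterministic order
#'   (permutations in lexicographic order, flip patterns in binary order).
#' @export
enumerate_orientations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    psign <- perm_sign(p)
    for (bits in 0:7) {
      fl <- 1 - 2 * c(bitwAnd(bits, 4L) > 0, bitwAnd(bits, 2L) > 0,
                      bitwAnd(bits, 1L) > 0)
      if (psign * prod(fl) == 1)
        out[[length(out) + 1L]] <- orientation(p, fl)
    }
  }
  out
}

perm_sign <- function(p) {
  s <- 1
  for (i in 1:2) for (j in (i + 1):3) if (p[i] > p[j]) s <- -s
  s
}

#' @rdname enumerate_orientations
#' @param axis_permutation permutation of 1:3; output axis \code{a} takes its
#'   data from input axis \code{axis_permutation[a]}.
#' @param axis_flips length-3 vector of +1/-1.
#' @export
orientation <- function(axis_permutation, axis_flips) {
  stopifnot(sort(axis_permutation) == 1:3, axis_flips %in% c(-1, 1))
  if (perm_sign(axis_permutation) * prod(axis_flips) != 1)
    stop("orientation must be right-handed")
  structure(list(axis_permutation = as.integer(axis_permutation),
                 axis_flips = as.integer(axis_flips)),
            class = "orientation")
}

#' Reorient a volume
#'
#' Permutes and flips the voxel array axes and updates the direction matrix
#' and origin so that the world coordinate of every voxel is unchanged.
#'
#' @param img an \code{\link{image_grid}}.
#' @param o an \code{\link{orientation}}.
#' @return Reoriented \code{\link{image_grid}} (with \code{needs_reorient}
#'   cleared).
#' @export
reorient <- function(img, o) {
  stopifnot(is_image_grid(img), inherits(o, "orientation"))
  p <- o$axis_permutation
  fl <- o$axis_flips
  vox <- aperm(img$voxels, p)
  dn <- dim(vox)
  if (fl[1] == -1) vox <- vox[dn[1]:1, , , drop = FALSE]
  if (fl[2] == -1) vox <- vox[, dn[2]:1, , drop = FALSE]
  if (fl[3] == -1) vox <- vox[, , dn[3]:1, drop = FALSE]
  # old index = M %*% new index + c  (0-based)
  M <- matrix(0, 3, 3)
  cc <- numeric(3)
  for (a in 1:3) {
    M[p[a], a] <- fl[a]
    cc[p[a]] <- if (fl[a] == 1) 0 else dn[a] - 1
  }
  DS <- img$direction %*% diag(img$spacing)
  DSM <- DS %*% M
  spacing_new <- img$spacing[p]
  direction_new <- DSM %*% diag(1 / spacing_new)
  origin_new <- as.numeric(DS %*% cc) + img$origin
  image_grid(vox, spacing = spacing_new, origin = origin_new,
             direction = direction_new, needs_reorient = FALSE)
}

#' Orientation that canonicalizes a grid to RAS
#'
#' Searches the 24 right-handed reorientations for the one whose application
#' brings the direction matrix closest to identity (maximal trace). For a
#' grid whose direction is already a signed permutation this is exact.
#'
#' @param img an \code{\link{image_grid}}.
#' @return An \code{\link{orientation}}.
#' @export
canonical_orientation <- function(img) {
  best <- NULL
  best_tr <- -Inf
  for (o in enumerate_orientations()) {
    p <- o$axis_permutation
    M <- matrix(0, 3, 3)
    for (a in 1:3) M[p[a], a] <- o$axis_flips[a]
    D <- img$direction %*% M
    tr <- sum(diag(D))
    if (tr > best_tr) { best_tr <- tr; best <- o }
  }
  best
}

#' Resample a volume to the pipeline's standard geometry
#'
#' Trilinear resampling onto an axis-aligned grid of given spacing and shape,
#' centered on the input field of view; voxels falling outside the input get
#' zero. Inputs must already be in RAS (identity direction).
#'
#' @param img an \code{\link{image_grid}} in RAS.
#' @param spacing standard spacing (mm), default 1 mm isotropic.
#' @param shape standard volume shape, default \code{c(256, 256, 256)}.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return An \code{\link{image_grid}} with identity direction.
#' @export
resample_standard <- function(img, spacing = c(1, 1, 1),
                              shape = c(256, 256, 256), interp = "linear") {
  stopifnot(is_image_grid(img))
  if (img$needs_reorient) stop("volume requires explicit reorientation first")
  if (max(abs(img$direction - diag(3))) > 1e-6)
    stop("resample_standard expects a RAS (identity-direction) volume; reorient first")
  d_in <- grid_dim(img)
  center <- voxel_to_world(img, matrix((d_in - 1) / 2, 1))[1, ]
  origin <- center - spacing * (shape - 1) / 2
  out_geom <- image_grid(array(0, shape), spacing = spacing, origin = origin)
  resample_to(img, out_geom, interp = interp)
}

#' Resample one volume onto another grid's geometry
#'
#' @param img source \code{\link{image_grid}}.
#' @param geom target geometry (an \code{\link{image_grid}}; voxel values
#'   ignored).
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @param fill value for target voxels outside the source field of view.
#' @return An \code{\link{image_grid}} on \code{geom}'s grid.
#' @export
resample_to <- function(img, geom, interp = "linear", fill = 0) {
  pts_world <- grid_world_coords(geom)
  pts_vox <- world_to_voxel(img, pts_world)
  v <- if (interp == "nearest") {
    cpp_nearest(img$voxels, grid_dim(img), pts_vox, fill)
  } else {
    cpp_trilinear(img$voxels, grid_dim(img), pts_vox, fill)
  }
  with_voxels(geom, v)
}
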