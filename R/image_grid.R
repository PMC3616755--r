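#' 3D image volume with geometry
#'
#' The unit every pipeline stage consumes and produces: a 3D scalar array
#' plus the affine voxel-to-world map \code{world = direction %*%
#' diag(spacing) %*% index + origin}, with 0-based voxel indices at voxel
#' centers and the world frame in RAS millimetres.
#'
#' @param voxels 3D numeric (or logical) array.
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping voxel axes to world axes.
#' @param needs_reorient logical; TRUE when the source format carried no
#'   orientation information (Analyze 7.5) and explicit reorientation is
#'   required before geometric processing.
#' @return An object of class \code{image_grid}.
#' @export
image_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3), needs_reorient = FALSE) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, all(dim(direction) == c(3L, 3L)))
  if (any(spacing <= 0)) stop("spacing components must be strictly positive")
  if (is.logical(voxels)) storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction,
                 needs_reorient = isTRUE(needs_reorient)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin:", paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  if (x$needs_reorient) cat("  (orientation unknown; reorientation required)\n")
  invisible(x)
}

#' @rdname image_grid
#' @param x object to test.
#' @export
is_image_grid <- function(x) inherits(x, "image_grid")

#' Dimensions of an image grid
#' @param img an \code{image_grid}.
#' @return integer length-3 vector.
#' @export
grid_dim <- function(img) dim(img$voxels)

#' Voxel-to-world and world-to-voxel coordinate maps
#'
#' @param img an \code{image_grid}.
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of world RAS coordinates in mm.
#' @export
voxel_to_world <- function(img, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% t(img$direction %*% diag(img$spacing)), 2L, img$origin, "+")
}

#' @rdname voxel_to_world
#' @param pts N x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(img, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  M <- solve(img$direction %*% diag(img$spacing))
  sweep(pts, 2L, img$origin, "-") %*% t(M)
}

#' 4x4 homogeneous voxel-to-world affine of a grid
#' @param img an \code{image_grid}.
#' @return 4x4 matrix.
#' @export
grid_affine <- function(img) {
  A <- diag(4)
  A[1:3, 1:3] <- img$direction %*% diag(img$spacing)
  A[1:3, 4] <- img$origin
  A
}

#' All 0-based voxel-center coordinates of a grid, in world mm
#' @param img an \code{image_grid}.
#' @return N x 3 matrix (N = prod(dim)) in array (column-major) order.
#' @export
grid_world_coords <- function(img) {
  d <- grid_dim(img)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(img, idx)
}

# Shared-geometry check used by voxelwise operations.
same_geometry <- function(a, b, tol = 1e-4) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Clone a grid's geometry with new voxel data
#' @param img an \code{\link{image_grid}} supplying the geometry.
#' @param voxels replacement array (or vector of matching length).
#' @return An \code{\link{image_grid}}.
#' @export
with_voxels <- function(img, voxels) {
  out <- img
  if (is.logical(voxels)) storage.mode(voxels) <- "double"
  dim(voxels) <- grid_dim(img)
  out$voxels <- voxels
  out
}
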