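# Volume filtering and differential operators. All sigma/fwhm arguments are
# in mm and converted to voxels with the grid spacing.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with reflected borders.
#'
#' @param img an \code{\link{image_grid}} or a 3D array.
#' @param sigma_mm scalar or length-3 standard deviation in mm (arrays are
#'   treated as unit spacing).
#' @param spacing spacing override when \code{img} is a bare array.
#' @return Same type as \code{img}.
#' @export
gauss_smooth <- function(img, sigma_mm, spacing = c(1, 1, 1)) {
  if (is_image_grid(img)) {
    v <- cpp_gauss3(img$voxels, grid_dim(img),
                    rep(sigma_mm, length.out = 3) / img$spacing)
    return(with_voxels(img, v))
  }
  out <- cpp_gauss3(img, dim(img), rep(sigma_mm, length.out = 3) / spacing)
  dim(out) <- dim(img)
  out
}

# Central-difference gradient, mm^-1 scaled; returns list(gx, gy, gz) arrays.
array_gradient <- function(a, spacing = c(1, 1, 1)) {
  d <- dim(a)
  gx <- a; gy <- a; gz <- a
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / (2 * spacing[1])
  gx[c(1, d[1]), , ] <- 0
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / (2 * spacing[2])
  gy[, c(1, d[2]), ] <- 0
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / (2 * spacing[3])
  gz[, , c(1, d[3])] <- 0
  list(gx = gx, gy = gy, gz = gz)
}

# Signed Euclidean distance (mm) to the boundary of a logical region:
# negative inside, positive outside.
signed_distance <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  if (!any(mask)) return(array(1e6, dm))
  if (all(mask)) return(array(-1e6, dm))
  d_out <- sqrt(cpp_edt_sq(as.logical(mask), dm, spacing))   # dist to region
  d_in <- sqrt(cpp_edt_sq(!mask, dm, spacing))               # dist to complement
  out <- d_out - d_in
  dim(out) <- dm
  out
}

# Downsample an image_grid by an integer factor (smooth-then-sample).
downsample <- function(img, factor) {
  if (factor <= 1) return(img)
  sm <- gauss_smooth(img, 0.4 * factor * img$spacing)
  d <- grid_dim(img)
  shape <- pmax(2L, as.integer(floor(d / factor)))
  spacing <- img$spacing * factor
  center <- voxel_to_world(img, matrix((d - 1) / 2, 1))[1, ]
  origin <- center - spacing * (shape - 1) / 2
  geom <- image_grid(array(0, shape), spacing = spacing, origin = origin,
                     direction = img$direction)
  resample_to(sm, geom)
}
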