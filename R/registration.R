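# Intensity-based registration: pairwise affine (12-parameter, multi-resolution
# gradient descent on SSD), unbiased groupwise affine, and demons-style dense
# displacement refinement. All registration runs in canonical axis-aligned
# space (identity direction); resample/reorient first.
#
# Affine convention: a 4x4 "pull" matrix T maps fixed-space world coordinates
# to moving-space world coordinates, so warped(x) = moving(T x). The forward
# map (moving into fixed/common space) is solve(T).

assert_canonical <- function(img) {
  if (max(abs(img$direction - diag(3))) > 1e-6)
    stop("operation requires canonical (identity-direction) geometry")
  invisible(img)
}

affine_params_to_matrix <- function(par, center) {
  tr <- par[1:3]; rot <- par[4:6]; lsc <- par[7:9]; sh <- par[10:12]
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(exp(lsc))
  H <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx %*% S %*% H
  T <- diag(4)
  T[1:3, 1:3] <- M
  T[1:3, 4] <- center - M %*% center + tr
  T
}

# Subsampled fixed-grid world coords + intensities for SSD evaluation.
ssd_samples <- function(img, max_samples = 24000L) {
  d <- grid_dim(img)
  n <- prod(d)
  stride <- max(1L, as.integer(ceiling((n / max_samples)^(1 / 3))))
  ii <- seq(1L, d[1], by = stride) - 1L
  jj <- seq(1L, d[2], by = stride) - 1L
  kk <- seq(1L, d[3], by = stride) - 1L
  idx <- as.matrix(expand.grid(ii, jj, kk))
  pts <- voxel_to_world(img, idx)
  vals <- img$voxels[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 1L)]
  list(pts = pts, vals = vals)
}

#' Pairwise 12-parameter affine registration
#'
#' Minimizes the sum of squared intensity differences between the fixed image
#' and the warped moving image by quasi-Newton descent over translation,
#' rotation, log-scale and shear, coarse-to-fine over a Gaussian pyramid.
#'
#' @param fixed,moving \code{\link{image_grid}}s in canonical space.
#' @param init optional initial 4x4 pull transform (fixed world -> moving
#'   world).
#' @param levels downsampling factors, coarse to fine.
#' @param maxit optimizer iterations per level.
#' @return 4x4 pull matrix; \code{solve()} of it maps moving into fixed space.
#' @export
affine_register <- function(fixed, moving, init = diag(4), levels = c(4, 2),
                            maxit = 60) {
  assert_canonical(fixed); assert_canonical(moving)
  center <- voxel_to_world(fixed, matrix((grid_dim(fixed) - 1) / 2, 1))[1, ]
  Tcur <- init
  par <- rep(0, 12)
  for (f in levels) {
    fx <- downsample(fixed, f)
    mv <- downsample(moving, f)
    smp <- ssd_samples(fx)
    Minv <- solve(mv$direction %*% diag(mv$spacing))
    obj <- function(p) {
      Tp <- Tcur %*% affine_params_to_matrix(p, center)
      mpts <- sweep(smp$pts %*% t(Tp[1:3, 1:3]), 2L, Tp[1:3, 4], "+")
      vox <- sweep(mpts, 2L, mv$origin, "-") %*% t(Minv)
      w <- cpp_trilinear(mv$voxels, grid_dim(mv), vox, 0)
      mean((w - smp$vals)^2)
    }
    fit <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-8,
                                       parscale = c(rep(2, 3), rep(0.02, 9))))
    par <- fit$par
  }
  Tcur %*% affine_params_to_matrix(par, center)
}

#' Groupwise affine registration to an unbiased common space
#'
#' Iteratively registers every timepoint to the running group-mean image and
#' recenters the transforms so the average matrix logarithm is zero, keeping
#' the common space unbiased by any single timepoint.
#'
#' @param series list of >= 2 \code{\link{image_grid}}s on a common grid.
#' @param iters number of register/recenter/update-mean rounds.
#' @param levels,maxit passed to \code{\link{affine_register}}.
#' @return List with \code{affines} (forward 4x4 maps, native -> common),
#'   \code{pulls} (common -> native), and \code{mean} (group-mean image).
#' @export
groupwise_affine <- function(series, iters = 2, levels = c(4, 2), maxit = 60) {
  if (length(series) < 2) stop("groupwise_affine requires at least 2 images")
  lapply(series, assert_canonical)
  geom <- series[[1]]
  n <- length(series)
  mean_img <- with_voxels(geom, Reduce(`+`, lapply(series, `[[`, "voxels")) / n)
  pulls <- replicate(n, diag(4), simplify = FALSE)
  for (r in seq_len(iters)) {
    for (i in seq_len(n)) {
      pulls[[i]] <- affine_register(mean_img, series[[i]], init = pulls[[i]],
                                    levels = levels, maxit = maxit)
    }
    Lbar <- Reduce(`+`, lapply(pulls, pracma::logm)) / n
    G <- pracma::expm(-Lbar)
    pulls <- lapply(pulls, function(T) T %*% G)
    warped <- lapply(seq_len(n), function(i)
      warp_affine(series[[i]], pulls[[i]], geom))
    mean_img <- with_voxels(geom, Reduce(`+`, lapply(warped, `[[`, "voxels")) / n)
  }
  list(affines = lapply(pulls, solve), pulls = pulls, mean = mean_img)
}

#' Warp an image through an affine pull transform
#'
#' @param moving source image.
#' @param pull 4x4 matrix mapping target world coords to source world coords.
#' @param geom target geometry.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return \code{\link{image_grid}} on \code{geom}'s grid.
#' @export
warp_affine <- function(moving, pull, geom, interp = "linear") {
  pts <- grid_world_coords(geom)
  mpts <- sweep(pts %*% t(pull[1:3, 1:3]), 2L, pull[1:3, 4], "+")
  vox <- world_to_voxel(moving, mpts)
  v <- if (interp == "nearest") cpp_nearest(moving$voxels, grid_dim(moving), vox, 0)
       else cpp_trilinear(moving$voxels, grid_dim(moving), vox, 0)
  with_voxels(geom, v)
}

# ---------------------------------------------------------------------------
# Dense displacement fields

#' Dense deformation field
#'
#' Voxelwise displacement in mm on a reference grid: a field \code{u} on grid
#' G maps the world point \code{x} of each G voxel to \code{x + u(x)} in the
#' source space, so warping pulls source intensities back onto G.
#'
#' @param ux,uy,uz 3D arrays of displacement components (mm).
#' @param geometry reference \code{\link{image_grid}} (voxels ignored).
#' @return Object of class \code{deformation_field}.
#' @export
def_field <- function(ux, uy, uz, geometry) {
  stopifnot(all(dim(ux) == grid_dim(geometry)))
  structure(list(ux = ux, uy = uy, uz = uz, geometry = geometry),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  m <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat("<deformation_field> ", paste(dim(x$ux), collapse = " x "),
      sprintf(", |u| mean %.3f max %.3f mm\n", mean(m), max(m)), sep = "")
  invisible(x)
}

zero_field <- function(geom) {
  z <- array(0, grid_dim(geom))
  def_field(z, z, z, geom)
}

field_from_affine <- function(pull, geom) {
  pts <- grid_world_coords(geom)
  mpts <- sweep(pts %*% t(pull[1:3, 1:3]), 2L, pull[1:3, 4], "+")
  u <- mpts - pts
  d <- grid_dim(geom)
  def_field(array(u[, 1], d), array(u[, 2], d), array(u[, 3], d), geom)
}

#' Warp an image through a deformation field
#'
#' @param moving source image.
#' @param field \code{\link{def_field}} on the target grid.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return \code{\link{image_grid}} on the field's grid.
#' @export
warp_field <- function(moving, field, interp = "linear") {
  geom <- field$geometry
  pts <- grid_world_coords(geom) +
    cbind(as.numeric(field$ux), as.numeric(field$uy), as.numeric(field$uz))
  vox <- world_to_voxel(moving, pts)
  v <- if (interp == "nearest") cpp_nearest(moving$voxels, grid_dim(moving), vox, 0)
       else cpp_trilinear(moving$voxels, grid_dim(moving), vox, 0)
  with_voxels(geom, v)
}

#' Compose two deformation fields
#'
#' \code{compose_fields(f1, f2)(x) = f1(x) + f2(x + f1(x))}: follow \code{f1}
#' first, then \code{f2} from where it lands. Both fields must live on
#' compatible grids (\code{f2} is interpolated).
#'
#' @param f1,f2 \code{\link{def_field}} objects.
#' @return A \code{\link{def_field}} on \code{f1}'s grid.
#' @export
compose_fields <- function(f1, f2) {
  geom <- f1$geometry
  pts <- grid_world_coords(geom) +
    cbind(as.numeric(f1$ux), as.numeric(f1$uy), as.numeric(f1$uz))
  vox <- world_to_voxel(f2$geometry, pts)
  d <- grid_dim(geom)
  ax <- array(cpp_trilinear(f2$ux, dim(f2$ux), vox, 0), d)
  ay <- array(cpp_trilinear(f2$uy, dim(f2$uy), vox, 0), d)
  az <- array(cpp_trilinear(f2$uz, dim(f2$uz), vox, 0), d)
  def_field(f1$ux + ax, f1$uy + ay, f1$uz + az, geom)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration \code{v <- -u(x + v)}.
#'
#' @param field a \code{\link{def_field}}.
#' @param iters fixed-point iterations.
#' @return A \code{\link{def_field}} on the same grid.
#' @export
invert_field <- function(field, iters = 10) {
  geom <- field$geometry
  pts0 <- grid_world_coords(geom)
  d <- grid_dim(geom)
  vx <- array(0, d); vy <- array(0, d); vz <- array(0, d)
  for (it in seq_len(iters)) {
    pts <- pts0 + cbind(as.numeric(vx), as.numeric(vy), as.numeric(vz))
    vox <- world_to_voxel(geom, pts)
    vx <- -array(cpp_trilinear(field$ux, d, vox, 0), d)
    vy <- -array(cpp_trilinear(field$uy, d, vox, 0), d)
    vz <- -array(cpp_trilinear(field$uz, d, vox, 0), d)
  }
  def_field(vx, vy, vz, geom)
}

# Smooth each displacement component (sigma in mm on the field's grid).
smooth_field <- function(field, sigma_mm) {
  sp <- field$geometry$spacing
  def_field(gauss_smooth(field$ux, sigma_mm, sp),
            gauss_smooth(field$uy, sigma_mm, sp),
            gauss_smooth(field$uz, sigma_mm, sp),
            field$geometry)
}

# Resample a field onto another geometry (components interpolated linearly).
resample_field <- function(field, geom) {
  gx <- resample_to(with_voxels(field$geometry, field$ux), geom)
  gy <- resample_to(with_voxels(field$geometry, field$uy), geom)
  gz <- resample_to(with_voxels(field$geometry, field$uz), geom)
  def_field(gx$voxels, gy$voxels, gz$voxels, geom)
}

#' Demons-style nonrigid registration
#'
#' Intensity-difference-driven displacement updates with Gaussian field
#' smoothing, coarse to fine. Estimates a field \code{u} on the fixed grid
#' such that \code{moving(x + u(x)) ~ fixed(x)}.
#'
#' @param fixed,moving \code{\link{image_grid}}s in canonical space.
#' @param init optional initial \code{\link{def_field}} (e.g. from an affine
#'   stage).
#' @param levels downsampling factors, coarse to fine.
#' @param iters per-level iteration counts (recycled).
#' @param sigma_field Gaussian smoothing of the field per iteration, mm.
#' @param max_step per-iteration displacement cap in voxels.
#' @return A \code{\link{def_field}} on the fixed grid.
#' @export
demons_register <- function(fixed, moving, init = NULL, levels = c(4, 2),
                            iters = c(30, 15), sigma_field = 2,
                            max_step = 1) {
  assert_canonical(fixed); assert_canonical(moving)
  iters <- rep(iters, length.out = length(levels))
  field <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- downsample(fixed, f)
    mv <- downsample(moving, f)   # both sides must see the same smoothing
    d <- grid_dim(fx)
    sp <- fx$spacing
    field <- if (is.null(field)) {
      if (is.null(init)) zero_field(fx) else resample_field(init, fx)
    } else resample_field(field, fx)
    g <- array_gradient(fx$voxels, sp)
    g2 <- g$gx^2 + g$gy^2 + g$gz^2
    alpha2 <- 1 / mean(sp)^2
    cap <- max_step * mean(sp)
    for (it in seq_len(iters[li])) {
      w <- warp_field(mv, field)
      diff <- w$voxels - fx$voxels
      den <- g2 + alpha2 * diff^2
      den[den < 1e-9] <- 1e-9
      s <- diff / den
      dx <- -s * g$gx; dy <- -s * g$gy; dz <- -s * g$gz
      m <- sqrt(dx^2 + dy^2 + dz^2)
      sc <- ifelse(m > cap, cap / m, 1)
      field <- def_field(field$ux + dx * sc, field$uy + dy * sc,
                         field$uz + dz * sc, fx)
      field <- smooth_field(field, sigma_field)
    }
  }
  resample_field(field, fixed)
}
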