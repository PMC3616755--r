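# Synthetic longitudinal head phantom: concentric spherical tissue
# compartments (scalp, skull, CSF, GM, WM) with per-timepoint GM thinning,
# smooth multiplicative bias, additive Gaussian noise, and rigid
# inter-timepoint jitter. Emits full ground truth plus a synthetic atlas
# (template, brain-probability map, tissue priors, ROI labels, cerebellum
# mask) so every pipeline stage is testable without external data.

#' Phantom specification
#'
#' Defaults describe the package's reference test object: a 96^3 1 mm grid,
#' four timepoints at 0/6/12/24 months, a 3 mm cortical shell (GM outer
#' radius 33 mm over a 30 mm WM core) thinning by 0.025 mm/month
#' (3.0 -> 2.4 mm over 24 months), 20% smooth multiplicative bias, noise
#' standard deviation 3 on tissue means of 40/80/120 (CSF/GM/WM), and rigid
#' jitter up to 2 mm / 2 degrees per follow-up timepoint.
#'
#' @param shape grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param timepoints acquisition times in months.
#' @param radii named numeric: \code{scalp}, \code{skull}, \code{csf} (brain
#'   outer), \code{gm_outer}, \code{wm}, in mm, strictly decreasing.
#' @param gm_thinning_rate GM outer radius shrinkage, mm/month.
#' @param intensities named numeric tissue means: \code{background},
#'   \code{csf}, \code{gm}, \code{wm}, \code{skull}, \code{scalp}.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_amplitude multiplicative bias amplitude (field is
#'   \code{1 + amplitude * sin products}).
#' @param bias_freq bias spatial frequency (cycles across the field of view).
#' @param jitter_mm,jitter_deg maximal rigid translation/rotation per
#'   follow-up timepoint (timepoint 1 is never jittered).
#' @param cereb_center,cereb_radius cerebellum blob center offset from the
#'   head center (mm) and radius (mm).
#' @param texture_amplitude named numeric (\code{wm}, \code{gm}, \code{csf}):
#'   amplitude of the smooth parenchymal texture field per tissue. The
#'   texture is a fixed property of the anatomy (identical across
#'   timepoints), emulating the locally distinctive image content of real
#'   parenchyma that feature-based registration relies on.
#' @param texture_sigma correlation length of the texture field, mm.
#' @param n_rois parcel count per hemisphere for the synthetic atlas.
#' @param smooth_mm partial-volume smoothing of the anatomy, mm.
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(1, 1, 1),
                         timepoints = c(0, 6, 12, 24),
                         radii = c(scalp = 44, skull = 40, csf = 36,
                                   gm_outer = 33, wm = 30),
                         gm_thinning_rate = 0.025,
                         intensities = c(background = 0, csf = 40, gm = 80,
                                         wm = 120, skull = 20, scalp = 90),
                         noise_sd = 3, bias_amplitude = 0.2, bias_freq = 1,
                         jitter_mm = 2, jitter_deg = 2,
                         cereb_center = c(0, -20, -16), cereb_radius = 7,
                         texture_amplitude = c(wm = 12, gm = 8, csf = 4),
                         texture_sigma = 3,
                         n_rois = 10, smooth_mm = 0.8, seed = 42) {
  spec <- list(shape = shape, spacing = spacing, timepoints = timepoints,
               radii = radii, gm_thinning_rate = gm_thinning_rate,
               intensities = intensities, noise_sd = noise_sd,
               bias_amplitude = bias_amplitude, bias_freq = bias_freq,
               jitter_mm = jitter_mm, jitter_deg = jitter_deg,
               cereb_center = cereb_center, cereb_radius = cereb_radius,
               texture_amplitude = texture_amplitude,
               texture_sigma = texture_sigma,
               n_rois = n_rois, smooth_mm = smooth_mm, seed = seed)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$radii
  if (!all(diff(r[c("wm", "gm_outer", "csf", "skull", "scalp")]) > 0))
    stop("radii must be strictly decreasing scalp > skull > csf > gm_outer > wm")
  th <- r[["gm_outer"]] - r[["wm"]] -
    spec$gm_thinning_rate * range(spec$timepoints)
  if (any(th <= 0.5) || any(th >= 8))
    stop("GM thickness must stay within (0.5, 8) mm over all timepoints")
  invisible(spec)
}

# Rigid pull transform: rotation (deg, about world axes through `center`)
# then translation.
rigid_pull <- function(trans, rot_deg, center) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx
  T <- diag(4)
  T[1:3, 1:3] <- M
  T[1:3, 4] <- center - M %*% center + trans
  T
}

#' Generate a synthetic longitudinal head MRI series with ground truth
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with elements:
#'   \describe{
#'     \item{series}{list of \code{\link{image_grid}}s, one per timepoint.}
#'     \item{truth}{per-timepoint ground truth: \code{brain_mask},
#'       \code{cereb_mask}, \code{tissue} (0 bg / 1 CSF / 2 GM / 3 WM),
#'       \code{roi_labels}, \code{thickness} (mm, GM voxels), \code{bias}
#'       (multiplicative field), \code{pull} (rigid pull transform,
#'       native -> anatomy space), \code{gm_outer} radius.}
#'     \item{atlas}{noise/bias/jitter-free baseline anatomy: \code{template},
#'       \code{brain_prob}, \code{priors} (list csf/gm/wm), \code{labels},
#'       \code{cereb_mask}.}
#'     \item{spec}{the spec used.}
#'   }
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  shape <- spec$shape
  geom <- image_grid(array(0, shape), spacing = spec$spacing,
                     origin = -(shape - 1) * spec$spacing / 2)
  pts <- grid_world_coords(geom)
  center <- c(0, 0, 0)
  rho <- array(sqrt(rowSums(pts^2)), shape)
  r <- spec$radii
  ints <- spec$intensities

  # Fixed asymmetric WM texture (deep structures): breaks the rotational
  # symmetry of the shells so rigid pose is identifiable by registration,
  # without disturbing the spherical tissue interfaces or thickness truth.
  blob_centers <- rbind(c(12, 8, -5), c(-10, -13, 5), c(4, -7, 13), c(-8, 11, 9))
  blob_amp <- c(30, -28, 26, -24)
  blob_sigma <- 5
  wm_texture <- array(0, shape)
  for (b in seq_len(nrow(blob_centers))) {
    d2 <- rowSums(sweep(pts, 2L, blob_centers[b, ])^2)
    wm_texture <- wm_texture +
      array(blob_amp[b] * exp(-d2 / (2 * blob_sigma^2)), shape)
  }
  # smooth parenchymal texture, unit-variance, fixed across timepoints
  parenchyma <- gauss_smooth(array(rnorm(prod(shape)), shape),
                             spec$texture_sigma, spec$spacing)
  parenchyma <- parenchyma / sd(parenchyma)

  anatomy_at <- function(gm_outer) {
    tissue <- array(0L, shape)                       # 0 bg, 1 CSF, 2 GM, 3 WM
    tissue[rho < r[["csf"]]] <- 1L
    tissue[rho < gm_outer] <- 2L
    tissue[rho < r[["wm"]]] <- 3L
    head_lab <- array(0L, shape)                     # 4 skull, 5 scalp
    head_lab[rho < r[["scalp"]]] <- 5L
    head_lab[rho < r[["skull"]]] <- 4L
    head_lab[tissue > 0L] <- tissue[tissue > 0L]
    lut <- c(ints[["background"]], ints[["csf"]], ints[["gm"]],
             ints[["wm"]], ints[["skull"]], ints[["scalp"]])
    intensity <- array(lut[head_lab + 1L], shape)
    intensity[tissue == 3L] <- intensity[tissue == 3L] + wm_texture[tissue == 3L]
    ta <- spec$texture_amplitude
    for (cl in 1:3) {
      amp <- ta[[c("csf", "gm", "wm")[cl]]]
      sel <- tissue == cl
      intensity[sel] <- intensity[sel] + amp * parenchyma[sel]
    }
    list(tissue = tissue, intensity = intensity)
  }

  # ROI parcellation: hemispheres by x sign, angular sectors in (y, z).
  ang <- array(atan2(pts[, 3], pts[, 2]), shape)     # (-pi, pi]
  sector <- pmin(spec$n_rois - 1L,
                 floor((ang + pi) / (2 * pi) * spec$n_rois))
  hemi <- array(as.integer(pts[, 1] >= 0), shape)
  roi_all <- array(as.integer(1L + sector + hemi * spec$n_rois), shape)

  cereb_mask0 <- array(sqrt(rowSums(sweep(pts, 2L, spec$cereb_center)^2)),
                       shape) < spec$cereb_radius
  brain0 <- rho < r[["csf"]]
  cereb_mask0 <- cereb_mask0 & brain0

  fov <- shape * spec$spacing
  ph <- 2 * pi * spec$bias_freq
  bias <- array(1 + spec$bias_amplitude *
                  sin(ph * (pts[, 1] + fov[1] / 2) / fov[1]) *
                  sin(ph * (pts[, 2] + fov[2] / 2) / fov[2]) *
                  sin(ph * (pts[, 3] + fov[3] / 2) / fov[3]), shape)

  nt <- length(spec$timepoints)
  series <- vector("list", nt)
  truth <- vector("list", nt)
  for (t in seq_len(nt)) {
    month <- spec$timepoints[t]
    gm_outer <- r[["gm_outer"]] - spec$gm_thinning_rate * month
    an <- anatomy_at(gm_outer)
    clean <- gauss_smooth(an$intensity, spec$smooth_mm, spec$spacing)
    biased <- clean * bias
    if (t == 1L || (spec$jitter_mm == 0 && spec$jitter_deg == 0)) {
      pull <- diag(4)
    } else {
      pull <- rigid_pull(runif(3, -spec$jitter_mm, spec$jitter_mm),
                         runif(3, -spec$jitter_deg, spec$jitter_deg), center)
    }
    anat_img <- with_voxels(geom, biased)
    native <- warp_affine(anat_img, pull, geom)
    noisy <- native$voxels + rnorm(length(native$voxels), sd = spec$noise_sd)
    noisy[noisy < 0] <- 0
    series[[t]] <- with_voxels(geom, noisy)

    pull_lab <- function(a) {
      w <- warp_affine(with_voxels(geom, a), pull, geom, interp = "nearest")
      w$voxels
    }
    tissue_t <- array(as.integer(round(pull_lab(an$tissue))), shape)
    brain_t <- tissue_t > 0L
    roi_t <- array(as.integer(round(pull_lab(roi_all))), shape)
    roi_t[!brain_t] <- 0L
    cereb_t <- pull_lab(cereb_mask0) > 0.5
    thick <- array(NA_real_, shape)
    thick[tissue_t == 2L] <- gm_outer - r[["wm"]]
    bias_t <- pull_lab(bias)
    truth[[t]] <- list(brain_mask = brain_t, cereb_mask = cereb_t,
                       tissue = tissue_t, roi_labels = roi_t,
                       thickness = thick, bias = array(bias_t, shape),
                       pull = pull, gm_outer = gm_outer)
  }

  an0 <- anatomy_at(r[["gm_outer"]])
  template <- with_voxels(geom, gauss_smooth(an0$intensity, spec$smooth_mm,
                                             spec$spacing))
  prob <- gauss_smooth(ifelse(brain0, 1, 0), 2, spec$spacing)
  prob[prob < 0] <- 0; prob[prob > 1] <- 1
  priors <- lapply(1:3, function(cl) {
    p <- gauss_smooth(ifelse(an0$tissue == cl, 1, 0), 1.5, spec$spacing)
    p[p < 0] <- 0; p[p > 1] <- 1
    with_voxels(geom, p)
  })
  names(priors) <- c("csf", "gm", "wm")
  atlas_labels <- an0$tissue
  roi0 <- roi_all
  roi0[an0$tissue == 0L] <- 0L

  list(series = series, truth = truth,
       atlas = list(template = template,
                    brain_prob = with_voxels(geom, prob),
                    priors = priors,
                    tissue = with_voxels(geom, atlas_labels),
                    labels = with_voxels(geom, roi0),
                    cereb_mask = with_voxels(geom, cereb_mask0)),
       spec = spec)
}
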