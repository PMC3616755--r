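# Joint WM/GM/CSF segmentation of a brain-extracted series: three coupled
# level sets per timepoint (WM/GM, GM/CSF, CSF/background interfaces), local
# Gaussian intensity models, a spatial cortical-thickness constraint keeping
# thickness in [t_min, t_max] mm, and a temporal constraint pulling each
# timepoint's thickness toward the interval spanned by its immediate
# neighbours. The CSF/background interface is fixed by the extraction mask.
#
# Labels: 0 background, 1 CSF, 2 GM, 3 WM.

#' Segmentation weights
#'
#' @param lambda_data data-fitting weight.
#' @param lambda_spatial_thick,lambda_temporal_thick thickness-constraint
#'   weights (mm^-1 scaled penalties).
#' @param mu_smooth curvature regularization weight.
#' @param dt iteration step.
#' @param t_min,t_max biologically plausible cortical-thickness band, mm.
#' @param window_fwhm Gaussian window FWHM for local intensity statistics, mm.
#' @return Parameter list.
#' @export
seg_weights <- function(lambda_data = 1.0, lambda_spatial_thick = 0.5,
                        lambda_temporal_thick = 0.5, mu_smooth = 0.4,
                        dt = 0.4, t_min = 1, t_max = 6.5, window_fwhm = 5) {
  stopifnot(t_min < t_max)
  list(lambda_data = lambda_data,
       lambda_spatial_thick = lambda_spatial_thick,
       lambda_temporal_thick = lambda_temporal_thick,
       mu_smooth = mu_smooth, dt = dt, t_min = t_min, t_max = t_max,
       window_fwhm = window_fwhm)
}

# Class regions from a level-set state (mutually exclusive, nested).
state_regions <- function(state) {
  wm <- state$phi_wm < 0
  gm <- !wm & state$phi_gm < 0
  csf <- !wm & !gm & state$phi_csf < 0
  list(wm = wm, gm = gm, csf = csf)
}

#' Labels from a level-set state
#' @param state a \code{levelset_state}.
#' @return Integer array: 0 bg, 1 CSF, 2 GM, 3 WM.
#' @export
state_labels <- function(state) {
  r <- state_regions(state)
  lab <- array(0L, dim(state$phi_wm))
  lab[r$csf] <- 1L
  lab[r$gm] <- 2L
  lab[r$wm] <- 3L
  lab
}

#' Initialize coupled level sets from atlas priors and global statistics
#'
#' Posterior per voxel is proportional to the atlas prior times a global
#' three-class Gaussian likelihood fitted by EM on the masked intensities;
#' hard labels by maximum posterior; each level set starts as the signed
#' Euclidean distance to its interface, with nesting by construction.
#'
#' @param brain skull-stripped \code{\link{image_grid}} (zero outside brain).
#' @param priors list of probability \code{image_grid}s \code{csf}, \code{gm},
#'   \code{wm} (voxelwise sum <= 1).
#' @param mask optional brain-mask array (default: \code{brain > 0}).
#' @return A \code{levelset_state}: list of \code{phi_wm}, \code{phi_gm},
#'   \code{phi_csf} signed-distance arrays (mm) plus the \code{mask} and EM
#'   \code{model}.
#' @export
init_levelsets <- function(brain, priors, mask = NULL) {
  m <- if (is.null(mask)) brain$voxels > 0 else mask
  v <- brain$voxels[m]
  em <- tryCatch(em_gauss3(v), error = function(e) NULL)
  if (is.null(em) || any(!is.finite(unlist(em))) ||
      any(em$sd < 1e-8) || any(diff(sort(em$mean)) < 1e-6)) {
    warning("EM degenerated; falling back to quantile split")
    qs <- quantile(v, c(1, 2) / 3, names = FALSE)
    lab_m <- 1L + findInterval(v, qs)
    em <- list(mean = tapply(v, lab_m, mean),
               sd = pmax(tapply(v, lab_m, sd), 1e-3),
               prop = tabulate(lab_m, 3) / length(v))
  }
  o <- order(em$mean)   # ascending: CSF, GM, WM
  lik <- vapply(1:3, function(k)
    stats::dnorm(v, em$mean[o[k]], em$sd[o[k]]) + 1e-12, numeric(length(v)))
  post <- lik
  pr_names <- c("csf", "gm", "wm")
  for (k in 1:3) {
    pk <- priors[[pr_names[k]]]
    post[, k] <- lik[, k] * (pk$voxels[m] + 0.01)   # floored atlas prior
  }
  # spatial regularization: where the voxelwise posterior is ambiguous,
  # decide from 1.5 mm-smoothed posteriors so isolated misassignments
  # (noise, textured WM) cannot seed island regions that would pollute the
  # local statistics; decisive voxels keep their own label (so clean
  # separable classes are labeled exactly)
  dm <- grid_dim(brain)
  post <- post / rowSums(post)
  lab <- array(0L, dm)
  sm <- vapply(1:3, function(k) {
    a <- array(0, dm); a[m] <- post[, k]
    as.numeric(gauss_smooth(a, 1.5, brain$spacing))
  }, numeric(prod(dm)))
  hard <- max.col(post)
  soft <- max.col(sm[as.vector(m), , drop = FALSE])
  conf <- post[cbind(seq_len(nrow(post)), hard)]
  lab[m] <- ifelse(conf >= 0.99, hard, soft)
  wm_r <- lab == 3L
  gm_r <- wm_r | lab == 2L
  state <- list(
    phi_wm = signed_distance(wm_r, brain$spacing),
    phi_gm = signed_distance(gm_r, brain$spacing),
    phi_csf = signed_distance(m, brain$spacing),
    mask = m,
    model = list(mean = em$mean[o], sd = em$sd[o]))
  class(state) <- "levelset_state"
  state
}

# Three-class EM for a 1D Gaussian mixture.
em_gauss3 <- function(v, iters = 40) {
  qs <- quantile(v, c(0.2, 0.5, 0.8), names = FALSE)
  mu <- qs
  sg <- rep(sd(v) / 3, 3) + 1e-6
  pp <- rep(1 / 3, 3)
  for (it in seq_len(iters)) {
    dens <- vapply(1:3, function(k) pp[k] * stats::dnorm(v, mu[k], sg[k]),
                   numeric(length(v)))
    tot <- rowSums(dens) + 1e-300
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 2)) stop("degenerate class")
    mu <- colSums(r * v) / nk
    sg <- sqrt(colSums(r * (v - rep(mu, each = length(v)))^2) / nk) + 1e-6
    pp <- nk / length(v)
  }
  list(mean = mu, sd = sg, prop = pp)
}

#' Spatially-varying class statistics
#'
#' Gaussian-window-weighted mean and variance of the intensities over each
#' current class region, computed as smoothed-indicator ratios.
#'
#' @param brain intensity \code{\link{image_grid}}.
#' @param state \code{levelset_state}.
#' @param window_fwhm Gaussian window FWHM, mm.
#' @return List per class (\code{wm}, \code{gm}, \code{csf}) of \code{mean}
#'   and \code{var} arrays, plus window parameters.
#' @export
fit_local_stats <- function(brain, state, window_fwhm = 15) {
  sig <- window_fwhm * FWHM_TO_SIGMA
  reg <- state_regions(state)
  # estimate statistics on interface-eroded cores so partial-volume voxels do
  # not inflate class variances asymmetrically (which would bias the
  # likelihood-equal point off the true boundary)
  h <- 0.9 * mean(brain$spacing)
  core <- list(wm = reg$wm & state$phi_wm < -h,
               gm = reg$gm & state$phi_wm > h & state$phi_gm < -h,
               csf = reg$csf & state$phi_gm > h & state$phi_csf < -h)
  v <- brain$voxels
  glob_var <- var(v[state$mask])
  out <- list()
  for (cl in names(reg)) {
    chi <- core[[cl]]
    if (!any(chi)) chi <- reg[[cl]]
    if (!any(chi)) { warning("class region empty: ", cl); out[[cl]] <- NULL; next }
    ind <- array(as.numeric(chi), dim(v))
    den <- gauss_smooth(ind, sig, brain$spacing)
    num <- gauss_smooth(ind * v, sig, brain$spacing)
    num2 <- gauss_smooth(ind * v * v, sig, brain$spacing)
    gm_mean <- mean(v[chi])
    gv <- var(v[chi])
    if (!is.finite(gv)) gv <- glob_var
    w <- pmin(1, den / 1e-3)          # fade to global stats where no support
    mu <- ifelse(den > 1e-6, num / pmax(den, 1e-6), gm_mean)
    mu <- w * mu + (1 - w) * gm_mean
    vv <- ifelse(den > 1e-6, num2 / pmax(den, 1e-6) - mu^2, gv)
    vv <- w * vv + (1 - w) * gv
    floor_v <- max(0.05 * glob_var, 1e-4)
    out[[cl]] <- list(mean = mu, var = pmax(vv, floor_v))
  }
  out$window_fwhm <- window_fwhm
  out
}

#' Cortical thickness from a level-set state
#'
#' Thickness at a GM voxel is the sum of its unsigned distances to the WM/GM
#' and GM/CSF interfaces. Distances from a voxel-center Euclidean distance
#' transform overshoot the true (sub-voxel) interface by half a voxel
#' projected on the interface normal; each term is corrected by
#' \code{(h/2) * max|n_i|} with \code{n} the local level-set normal, which is
#' exact for flat interfaces and unbiased on curved ones.
#'
#' @param state \code{levelset_state} with reinitialized (signed-distance)
#'   level sets.
#' @param spacing voxel spacing (mm) used for the quantization correction.
#' @return List with \code{thickness} (array, NA outside GM) and \code{full}
#'   (the same quantity evaluated everywhere, used by the constraints).
#' @export
estimate_thickness <- function(state, spacing = c(1, 1, 1)) {
  full <- thickness_field(state$phi_wm, state$phi_gm, spacing)
  reg <- state_regions(state)
  th <- array(NA_real_, dim(full))
  th[reg$gm] <- full[reg$gm]
  list(thickness = th, full = full)
}

# Quantization offset of a voxel-center EDT: half a voxel along the dominant
# axis of the interface normal.
edt_offset <- function(phi, spacing) {
  g <- array_gradient(phi, spacing)
  mag <- pmax(sqrt(g$gx^2 + g$gy^2 + g$gz^2), 1e-9)
  0.5 * mean(spacing) * pmax(abs(g$gx), abs(g$gy), abs(g$gz)) / mag
}

# Cortical-thickness field: the signed difference of the two corrected
# signed distances equals the local shell thickness everywhere (inside WM,
# in GM, and in CSF), unlike |phi_wm| + |phi_gm| which grows away from the
# shell and would feed spurious "too thick" signals to the constraints at
# off-shell voxels inside the Dirac band.
thickness_field <- function(phi_wm, phi_gm, spacing) {
  tilde <- function(phi) sign(phi) * pmax(abs(phi) - edt_offset(phi, spacing), 0)
  pmax(tilde(phi_wm) - tilde(phi_gm), 0)
}

#' Global cortical thickness as volume over mid-surface area
#'
#' The GM volume divided by the area of the mid-cortical surface (the zero
#' level of the average of the two signed distances). Because volume is
#' sub-voxel accurate while pointwise distance maps are quantized to the
#' voxel lattice, this summary resolves thickness changes well below one
#' voxel and is the recommended quantity for longitudinal trend fitting.
#'
#' @param state \code{levelset_state} with reinitialized level sets.
#' @param spacing voxel spacing, mm.
#' @return Scalar thickness, mm.
#' @export
thickness_global <- function(state, spacing = c(1, 1, 1)) {
  reg <- state_regions(state)
  v_gm <- sum(reg$gm) * prod(spacing)
  phi_mid <- (state$phi_wm + state$phi_gm) / 2
  g <- array_gradient(phi_mid, spacing)
  area <- sum(dirac_eps(phi_mid) * sqrt(g$gx^2 + g$gy^2 + g$gz^2)) *
    prod(spacing)
  v_gm / area
}

# Mean curvature of a level-set function times |grad phi| (curvature flow
# speed), via central differences.
curvature_speed <- function(phi, spacing) {
  g <- array_gradient(phi, spacing)
  mag <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  mag <- pmax(mag, 1e-6)
  d <- array_gradient(g$gx / mag, spacing)$gx +
       array_gradient(g$gy / mag, spacing)$gy +
       array_gradient(g$gz / mag, spacing)$gz
  d * mag
}

# Smoothed Dirac delta for interface-localized updates.
dirac_eps <- function(phi, eps = 1.5) eps / (pi * (eps^2 + phi^2))

#' Evolve the coupled level sets for one timepoint
#'
#' Gradient-flow updates: local Gaussian log-likelihood data term between the
#' two classes adjoining each interface, curvature regularization, a
#' quadratic-out-of-band spatial thickness penalty, and (when neighbour
#' thickness maps are supplied) a clamp-to-neighbour-interval temporal
#' penalty. Nesting is re-enforced by min/max projection after every update;
#' level sets are reinitialized to signed distances every 20 iterations.
#'
#' @param brain intensity \code{\link{image_grid}}.
#' @param state \code{levelset_state}.
#' @param stats \code{\link{fit_local_stats}} output (refitted every 10
#'   iterations internally).
#' @param neighbor_thickness NULL, or list of 1-2 thickness arrays
#'   (\code{full} maps) already resampled into this timepoint's frame.
#' @param w \code{\link{seg_weights}}.
#' @param iters iteration count.
#' @return Updated \code{levelset_state} with an \code{energy} trace
#'   attribute.
#' @export
evolve_segmentation <- function(brain, state, stats = NULL,
                                neighbor_thickness = NULL,
                                w = seg_weights(), iters = 40) {
  sp <- brain$spacing
  v <- brain$voxels
  if (is.null(stats)) stats <- fit_local_stats(brain, state, w$window_fwhm)
  energy <- numeric(0)
  Tfull <- NULL
  nb_lo <- nb_hi <- NULL
  if (!is.null(neighbor_thickness) && length(neighbor_thickness) > 0) {
    # the temporal clamp compares smoothed thickness fields: thickness is a
    # property of the cortical sheet, and smoothing keeps voxel-level noise in
    # the neighbour maps from acting as a stochastic forcing
    nb_s <- lapply(neighbor_thickness, function(a)
      gauss_smooth(a, 4, brain$spacing))
    nb_lo <- Reduce(pmin, nb_s)
    nb_hi <- Reduce(pmax, nb_s)
  }
  for (it in seq_len(iters)) {
    if (it > 1 && (it - 1) %% 10 == 0)
      stats <- fit_local_stats(brain, state, w$window_fwhm)
    # data term per interface: Gaussian log-likelihood difference of the two
    # adjoining classes under a shared (pooled) local variance, so the
    # decision boundary is the midpoint of the local means and is not skewed
    # by asymmetric partial-volume variance inflation
    d_wm <- dirac_eps(state$phi_wm)
    d_gm <- dirac_eps(state$phi_gm)
    v_wg <- (stats$wm$var + stats$gm$var) / 2
    v_gc <- (stats$gm$var + stats$csf$var) / 2
    e_wm_g <- ((v - stats$wm$mean)^2 - (v - stats$gm$mean)^2) / (2 * v_wg)
    e_gm_c <- ((v - stats$gm$mean)^2 - (v - stats$csf$mean)^2) / (2 * v_gc)
    upd_wm <- w$lambda_data * e_wm_g
    upd_gm <- w$lambda_data * e_gm_c

    # constraint thickness from freshly reinitialized distances: between
    # reinitializations the evolving phi values saturate under the clipped
    # data updates and are not metric distances, which would inflate the
    # constraint fields and turn the clamp into a spurious thinning force.
    # Recomputed every third iteration (the labels move sub-voxel per step).
    if (it %% 3 == 1 || is.null(Tfull))
      Tfull <- thickness_field(signed_distance(state$phi_wm < 0, sp),
                               signed_distance(state$phi_gm < 0, sp), sp)
    # positive signed error = too thick -> reduce thickness
    sp_err <- pmax(Tfull - w$t_max, 0) - pmax(w$t_min - Tfull, 0)
    upd_wm <- upd_wm - w$lambda_spatial_thick * sp_err
    upd_gm <- upd_gm + w$lambda_spatial_thick * sp_err
    if (!is.null(nb_lo)) {
      Tsm <- gauss_smooth(Tfull, 4, sp)
      excess <- Tsm - pmin(pmax(Tsm, nb_lo), nb_hi)
      upd_wm <- upd_wm - w$lambda_temporal_thick * excess
      upd_gm <- upd_gm + w$lambda_temporal_thick * excess
    }
    dphi_wm <- w$dt * (d_wm * upd_wm +
                       w$mu_smooth * curvature_speed(state$phi_wm, sp) *
                         (d_wm * pi * 1.5))
    dphi_gm <- w$dt * (d_gm * upd_gm +
                       w$mu_smooth * curvature_speed(state$phi_gm, sp) *
                         (d_gm * pi * 1.5))
    lim <- 0.5 * min(sp)
    state$phi_wm <- state$phi_wm + pmin(lim, pmax(-lim, dphi_wm))
    state$phi_gm <- state$phi_gm + pmin(lim, pmax(-lim, dphi_gm))
    # nesting projection (inner regions shrink to fit)
    state$phi_gm <- pmax(state$phi_gm, state$phi_csf)
    state$phi_wm <- pmax(state$phi_wm, state$phi_gm)
    if (it %% 20 == 0) state <- reinit_state(state, sp)
    reg <- state_regions(state)
    e_data <- sum(((v - stats$wm$mean)^2 / (2 * v_wg))[reg$wm]) +
      sum(((v - stats$gm$mean)^2 / (2 * v_gc))[reg$gm]) +
      sum(((v - stats$csf$mean)^2 / (2 * v_gc))[reg$csf])
    energy <- c(energy,
                e_data + w$lambda_spatial_thick * sum(sp_err[reg$gm]^2))
  }
  state <- reinit_state(state, sp)
  attr(state, "energy") <- energy
  state
}

reinit_state <- function(state, spacing) {
  state$phi_wm <- signed_distance(state$phi_wm < 0, spacing)
  state$phi_gm <- signed_distance(state$phi_gm < 0, spacing)
  state
}

#' Demons registration of tissue label maps
#'
#' Registers consecutive segmentations by demons on smoothed label-indicator
#' composites; the returned field maps timepoint-t coordinates to t+1 and is
#' used to pull the neighbour's thickness map into the current frame.
#'
#' @param seg_t,seg_t1 integer label \code{image_grid}s on one grid.
#' @param levels,iters demons schedule.
#' @return A \code{\link{def_field}} on \code{seg_t}'s grid.
#' @export
register_tissue_maps <- function(seg_t, seg_t1, levels = c(2), iters = c(25)) {
  comp <- function(seg) {
    out <- array(0, grid_dim(seg))
    for (cl in 1:3) {
      ind <- array(as.numeric(seg$voxels == cl), grid_dim(seg))
      out <- out + cl * gauss_smooth(ind, 1.0, seg$spacing)
    }
    with_voxels(seg, out)
  }
  a <- comp(seg_t)
  b <- comp(seg_t1)
  # affine initialization carries the global modes that diffusion-regularized
  # demons propagates only slowly
  A <- affine_register(a, b, levels = c(4), maxit = 40)
  demons_register(a, b, init = field_from_affine(A, a), levels = levels,
                  iters = iters, sigma_field = 2, max_step = 1)
}

#' Joint 4D tissue segmentation of a longitudinal series
#'
#' Three-step optimization: (1) independent 3D coupled-level-set segmentation
#' per timepoint (data + spatial thickness constraint); (2) pairwise
#' registration of consecutive tissue maps to transfer neighbour thickness;
#' (3) 4D evolution adding the temporal thickness-consistency term. Steps 2
#' and 3 alternate until fewer than 0.1% of voxels change label or
#' \code{outer_iters} is reached. A single timepoint runs the 3D path only.
#'
#' @param series list of skull-stripped \code{image_grid}s (common grid).
#' @param priors list of prior probability \code{image_grid}s (\code{csf},
#'   \code{gm}, \code{wm}), shared by all timepoints (pre-aligned).
#' @param w \code{\link{seg_weights}}.
#' @param outer_iters maximum alternations of steps 2-3.
#' @param init_iters,temporal_iters level-set iterations for the 3D
#'   initialization and each 4D pass.
#' @param masks optional list of brain-mask arrays.
#' @param temporal_endpoints apply the temporal term at the first/last
#'   timepoints using their single neighbour (the in-between interval then
#'   degenerates to a pull toward that neighbour, which drags genuine atrophy at
#'   the series ends). Default FALSE: endpoints keep data + spatial terms.
#' @return List with \code{labels} (list of integer \code{image_grid}),
#'   \code{thickness} (list of \code{\link{estimate_thickness}} outputs),
#'   \code{states}, and \code{energy} traces.
#' @export
segment_series_4d <- function(series, priors, w = seg_weights(),
                              outer_iters = 3, init_iters = 40,
                              temporal_iters = 15, masks = NULL,
                              temporal_endpoints = FALSE) {
  nt <- length(series)
  if (is.null(masks)) masks <- lapply(series, function(im) im$voxels > 0)
  # crop to the union bounding box of the masks (+margin) for speed
  bb <- mask_bbox(Reduce(`|`, masks), margin = 4L)
  ser_c <- lapply(series, crop_grid, bb = bb)
  pri_c <- lapply(priors, crop_grid, bb = bb)
  msk_c <- lapply(masks, function(m) crop_array(m, bb))

  states <- vector("list", nt)
  energy <- vector("list", nt)
  for (t in seq_len(nt)) {
    st <- init_levelsets(ser_c[[t]], pri_c, mask = msk_c[[t]])
    st <- evolve_segmentation(ser_c[[t]], st,
                              w = w, iters = init_iters)
    energy[[t]] <- attr(st, "energy")
    states[[t]] <- st
  }
  labs <- lapply(states, state_labels)
  if (nt > 1) {
    for (outer in seq_len(outer_iters)) {
      segs <- lapply(seq_len(nt), function(t)
        with_voxels(ser_c[[t]], labs[[t]]))
      thick <- lapply(states, function(s)
        estimate_thickness(s, ser_c[[1]]$spacing)$full)
      new_states <- states
      for (t in seq_len(nt)) {
        # the in-between constraint needs both neighbours; endpoints evolve
        # without the temporal term (a single neighbour would degenerate the
        # clamp interval to equality and flatten true atrophy)
        nb <- NULL
        nb_idx <- c(t - 1, t + 1)
        nb_idx <- nb_idx[nb_idx >= 1 & nb_idx <= nt]
        if (!temporal_endpoints && (t == 1 || t == nt)) nb_idx <- integer(0)
        if (length(nb_idx) > 0 && w$lambda_temporal_thick > 0) {
          nb <- lapply(nb_idx, function(u) {
            fld <- register_tissue_maps(segs[[t]], segs[[u]])
            warp_field(with_voxels(ser_c[[t]], thick[[u]]), fld)$voxels
          })
        }
        st <- evolve_segmentation(ser_c[[t]], states[[t]],
                                  neighbor_thickness = nb, w = w,
                                  iters = temporal_iters)
        energy[[t]] <- c(energy[[t]], attr(st, "energy"))
        new_states[[t]] <- st
      }
      states <- new_states
      new_labs <- lapply(states, state_labels)
      changed <- sum(mapply(function(a, b) sum(a != b), labs, new_labs))
      labs <- new_labs
      if (changed / (nt * prod(dim(labs[[1]]))) < 0.001) break
    }
  }
  # embed back into the full grid
  out_labels <- vector("list", nt)
  out_thick <- vector("list", nt)
  for (t in seq_len(nt)) {
    full_lab <- array(0L, grid_dim(series[[t]]))
    full_lab[bb$x, bb$y, bb$z] <- labs[[t]]
    out_labels[[t]] <- with_voxels(series[[t]], full_lab)
    th <- estimate_thickness(states[[t]], series[[t]]$spacing)
    full_th <- array(NA_real_, grid_dim(series[[t]]))
    full_th[bb$x, bb$y, bb$z] <- th$thickness
    out_thick[[t]] <- full_th
  }
  list(labels = out_labels, thickness = out_thick, states = states,
       energy = energy, bbox = bb)
}

mask_bbox <- function(m, margin = 4L) {
  d <- dim(m)
  ix <- which(apply(m, 1, any)); iy <- which(apply(m, 2, any))
  iz <- which(apply(m, 3, any))
  list(x = max(1, min(ix) - margin):min(d[1], max(ix) + margin),
       y = max(1, min(iy) - margin):min(d[2], max(iy) + margin),
       z = max(1, min(iz) - margin):min(d[3], max(iz) + margin))
}

crop_grid <- function(img, bb) {
  v <- img$voxels[bb$x, bb$y, bb$z, drop = FALSE]
  origin <- voxel_to_world(img, matrix(c(bb$x[1], bb$y[1], bb$z[1]) - 1, 1))[1, ]
  image_grid(v, spacing = img$spacing, origin = origin,
             direction = img$direction)
}

crop_array <- function(a, bb) a[bb$x, bb$y, bb$z, drop = FALSE]
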