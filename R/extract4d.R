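# Consistent 4D skull stripping: per-timepoint deformable surfaces evolved
# simultaneously under a temporal-smoothness force, initialized from a common
# sphere estimated after probability-map stripping, plus atlas-driven
# cerebellum removal.

#' Warp a brain-probability map onto a target image
#'
#' Affine registration followed by demons-style nonrigid refinement. When the
#' atlas template image accompanying the probability map is supplied, the
#' transform is estimated template -> target and applied to the map;
#' otherwise the probability map itself drives the registration against a
#' rescaled target.
#'
#' @param prob probability \code{\link{image_grid}} (values in [0, 1]).
#' @param target target image.
#' @param template optional atlas template aligned with \code{prob}.
#' @param levels,iters demons schedule.
#' @return Warped probability map on the target grid, clipped to [0, 1].
#' @export
warp_probability_map <- function(prob, target, template = NULL,
                                 levels = c(4, 2), iters = c(40, 20)) {
  if (any(prob$voxels < -1e-6) || any(prob$voxels > 1 + 1e-6))
    stop("probability map must lie in [0, 1]")
  moving <- if (is.null(template)) {
    sc <- quantile(target$voxels[target$voxels > 0], 0.98)
    target_n <- with_voxels(target, pmin(1, target$voxels / sc))
    prob
  } else template
  fixed <- if (is.null(template)) {
    sc <- quantile(target$voxels[target$voxels > 0], 0.98)
    with_voxels(target, pmin(1, target$voxels / sc))
  } else target
  A <- affine_register(fixed, moving, levels = levels)
  f0 <- field_from_affine(A, fixed)
  fd <- demons_register(fixed, moving, init = f0, levels = levels,
                        iters = iters)
  warped <- warp_field(prob, fd)
  with_voxels(target, pmin(1, pmax(0, warped$voxels)))
}

#' Equivalent-sphere estimate of a brain mask
#'
#' @param img intensity image.
#' @param mask nonempty binary mask (array or \code{image_grid}).
#' @return List with \code{cog} (intensity-weighted centroid, world mm) and
#'   \code{radius} (equivalent-volume sphere radius, mm).
#' @export
estimate_sphere <- function(img, mask) {
  m <- if (is_image_grid(mask)) mask$voxels > 0.5 else mask
  if (!any(m)) stop("empty mask")
  w <- img$voxels[m]
  if (all(w <= 0)) w <- rep(1, length(w))
  pts <- grid_world_coords(img)[as.vector(m), , drop = FALSE]
  cog <- colSums(pts * w) / sum(w)
  vol <- sum(m) * prod(img$spacing)
  list(cog = cog, radius = (3 * vol / (4 * pi))^(1 / 3))
}

#' Average several sphere estimates
#' @param estimates list of sphere estimates.
#' @return Single sphere estimate (mean cog, mean radius).
#' @export
common_sphere <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  cogs <- do.call(rbind, lapply(estimates, `[[`, "cog"))
  list(cog = colMeans(cogs),
       radius = mean(vapply(estimates, `[[`, numeric(1), "radius")))
}

#' Force weights for surface evolution
#'
#' @param w_smooth,w_intensity,w_prob,w_temporal nonnegative force weights.
#' @param step_size vertex step per iteration, mm.
#' @param iters iteration count (the classic convention is 1000; phantom runs
#'   converge far earlier).
#' @param d_min,d_max inward sampling depths (mm) for the local min/max
#'   intensity of the intensity force.
#' @param bt fractional intensity threshold.
#' @return List of evolution parameters.
#' @export
force_weights <- function(w_smooth = 1.0, w_intensity = 0.3, w_prob = 0.3,
                          w_temporal = 0.5, step_size = 0.1, iters = 1000,
                          d_min = 7, d_max = 3, bt = 0.3) {
  stopifnot(w_smooth >= 0, w_intensity >= 0, w_prob >= 0, w_temporal >= 0)
  list(w_smooth = w_smooth, w_intensity = w_intensity, w_prob = w_prob,
       w_temporal = w_temporal, step_size = step_size, iters = iters,
       d_min = d_min, d_max = d_max, bt = bt)
}

# Robust intensity anchors for the intensity force of one image.
intensity_anchors <- function(img, mask) {
  v <- img$voxels
  t2 <- quantile(v, 0.02, names = FALSE)
  t98 <- quantile(v, 0.98, names = FALSE)
  m <- if (is.null(mask)) v > t2 + 0.1 * (t98 - t2) else mask
  tm <- median(v[m])
  list(t2 = t2, t98 = t98, tm = tm)
}

# One evolution step for one timepoint: returns the displacement excluding
# the temporal force. All operations are vectorized over vertices.
surface_forces <- function(vertices, topo, triangles, img, prob, anchors, w) {
  n_hat <- vertex_normals(vertices, triangles)
  cen <- neighbor_centroid(vertices, topo)
  s <- cen - vertices
  sn_len <- rowSums(s * n_hat)
  s_n <- n_hat * sn_len
  s_t <- s - s_n
  # curvature-adaptive attenuation of the normal smoothing component
  l2 <- rowSums(s^2)
  r_curv <- l2 / (2 * pmax(abs(sn_len), 1e-9))
  rmin <- 3.33; rmax <- 10
  E <- (1 / rmin + 1 / rmax) / 2
  Fc <- 6 / (1 / rmin - 1 / rmax)
  f2 <- 0.5 * (1 + tanh(Fc * (1 / pmax(r_curv, 1e-9) - E)))
  smooth_disp <- s_t + s_n * f2

  # intensity force: local min along the inward normal (depth d_min) vs local
  # max (depth d_max), compared against a fractional threshold
  depths_min <- seq(0, w$d_min, by = 1)
  depths_max <- seq(0, w$d_max, by = 1)
  nv <- nrow(vertices)
  Imin <- rep(Inf, nv); Imax <- rep(-Inf, nv)
  for (d in depths_min) {
    p <- vertices - n_hat * d
    val <- cpp_trilinear(img$voxels, grid_dim(img), world_to_voxel(img, p), 0)
    Imin <- pmin(Imin, val)
    if (d <= w$d_max) Imax <- pmax(Imax, val)
  }
  Imin <- pmax(anchors$t2, pmin(anchors$tm, Imin))
  Imax <- pmin(anchors$tm, Imax)
  tl <- (Imax - anchors$t2) * w$bt + anchors$t2
  f3 <- 2 * (Imin - tl) / pmax(Imax - anchors$t2, 1e-9)

  pv <- cpp_trilinear(prob$voxels, grid_dim(prob),
                      world_to_voxel(prob, vertices), 0)
  w$w_smooth * smooth_disp +
    n_hat * (w$w_intensity * f3 + w$w_prob * (pv - 0.5))
}

#' Evolve one brain surface on a single image (3D path)
#'
#' The per-timepoint reduction of \code{\link{evolve_surfaces_4d}}: identical
#' arithmetic, no temporal force.
#'
#' @param img intensity image.
#' @param prob brain-probability map on the same grid.
#' @param init initial \code{surface_mesh}.
#' @param w \code{\link{force_weights}} (temporal weight ignored).
#' @return Evolved \code{surface_mesh}.
#' @export
evolve_surface_3d <- function(img, prob, init, w = force_weights()) {
  topo <- mesh_topology(init)
  anchors <- intensity_anchors(img, prob$voxels >= 0.5)
  vert <- init$vertices
  for (it in seq_len(w$iters)) {
    disp <- surface_forces(vert, topo, init$triangles, img, prob, anchors, w)
    vert <- vert + w$step_size * disp
  }
  out <- init
  out$vertices <- vert
  out$self_intersection_suspect <- mesh_self_intersection_suspect(out)
  out
}

#' Simultaneous evolution of per-timepoint brain surfaces
#'
#' Four forces act on every vertex: spatial smoothing (neighbor centroid,
#' tangential part fully applied, normal part attenuated by local curvature),
#' an intensity force comparing local min/max intensities sampled along the
#' inward normal against adaptive thresholds, a probability-map force
#' proportional to P - 0.5 along the normal, and a temporal-smoothness force
#' pulling each vertex toward the mean of its corresponding vertices at the
#' immediate temporal neighbors. Updates are synchronous across timepoints.
#'
#' @param series list of intensity images (one per timepoint).
#' @param probs list of brain-probability maps on matching grids.
#' @param init a \code{surface_series}: list of \code{surface_mesh} with
#'   identical topology (typically `n` copies of the common sphere).
#' @param w \code{\link{force_weights}}.
#' @return List of evolved \code{surface_mesh} (same topology), with a
#'   \code{self_intersection_suspect} flag per mesh.
#' @export
evolve_surfaces_4d <- function(series, probs, init, w = force_weights()) {
  nt <- length(series)
  stopifnot(length(probs) == nt, length(init) == nt)
  tri <- init[[1]]$triangles
  for (m in init) stopifnot(identical(m$triangles, tri))
  topo <- mesh_topology(init[[1]])
  anchors <- lapply(seq_len(nt), function(i)
    intensity_anchors(series[[i]], probs[[i]]$voxels >= 0.5))
  verts <- lapply(init, `[[`, "vertices")
  for (it in seq_len(w$iters)) {
    disps <- vector("list", nt)
    for (t in seq_len(nt)) {
      disps[[t]] <- surface_forces(verts[[t]], topo, tri, series[[t]],
                                   probs[[t]], anchors[[t]], w)
      if (w$w_temporal > 0 && nt > 1) {
        nb <- if (t == 1) verts[[2]]
              else if (t == nt) verts[[nt - 1]]
              else (verts[[t - 1]] + verts[[t + 1]]) / 2
        disps[[t]] <- disps[[t]] + w$w_temporal * (nb - verts[[t]])
      }
    }
    for (t in seq_len(nt)) verts[[t]] <- verts[[t]] + w$step_size * disps[[t]]
  }
  lapply(seq_len(nt), function(t) {
    out <- init[[t]]
    out$vertices <- verts[[t]]
    out$self_intersection_suspect <- mesh_self_intersection_suspect(out)
    out
  })
}

#' Remove the cerebellum from skull-stripped masks via a warped atlas mask
#'
#' Registers the atlas template to the group mean of the brain-extracted
#' series (affine + demons), carries the cerebellum mask through to each
#' timepoint's space, and subtracts it from each brain mask.
#'
#' @param brain_series list of skull-stripped intensity images (common grid).
#' @param brain_masks list of binary brain-mask \code{image_grid}s.
#' @param atlas atlas template image.
#' @param cereb_mask binary cerebellum mask on the atlas grid.
#' @param pulls optional list of affine pulls (common -> native) when the
#'   series was aligned previously; identity assumed otherwise.
#' @return List of binary \code{image_grid} masks with the cerebellum
#'   removed (subset of the input masks).
#' @export
remove_cerebellum <- function(brain_series, brain_masks, atlas, cereb_mask,
                              pulls = NULL) {
  nt <- length(brain_series)
  if (!any(cereb_mask$voxels > 0.5)) return(brain_masks)
  if (nt >= 2) {
    ga <- groupwise_affine(brain_series, iters = 1)
    mean_img <- ga$mean
    pulls_n <- ga$pulls
  } else {
    mean_img <- brain_series[[1]]
    pulls_n <- list(diag(4))
  }
  A <- affine_register(mean_img, atlas, levels = c(4, 2))
  f0 <- field_from_affine(A, mean_img)
  fd <- demons_register(mean_img, atlas, init = f0, levels = c(4, 2),
                        iters = c(40, 20))
  cereb_mean <- warp_field(cereb_mask, fd)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    # mean-space cerebellum into native space through the affine pull inverse
    cn <- warp_affine(cereb_mean, solve(pulls_n[[t]]), brain_masks[[t]],
                      interp = "linear")
    keep <- brain_masks[[t]]$voxels > 0.5 & cn$voxels < 0.5
    out[[t]] <- with_voxels(brain_masks[[t]], array(as.numeric(keep),
                                                    grid_dim(brain_masks[[t]])))
  }
  out
}

#' Consistent 4D brain extraction
#'
#' Full extraction stage: groupwise affine alignment to a common space,
#' probability-map warping and stripping per timepoint, common-sphere
#' initialization, simultaneous surface evolution, rasterization, and mapping
#' of the masks back to native space.
#'
#' @param series preprocessed timepoint images (common canonical grid).
#' @param atlas list with \code{template} and \code{brain_prob}
#'   \code{image_grid}s (and optionally \code{cereb_mask}).
#' @param w \code{\link{force_weights}}.
#' @param subdivisions icosphere subdivision level.
#' @param remove_cereb remove the cerebellum when the atlas has a mask.
#' @param align run the groupwise affine stage (disable for series known to
#'   share one pose, e.g. motion-free phantoms).
#' @return List with \code{masks} (native-space binary masks per timepoint),
#'   \code{meshes} (evolved surfaces in common space), \code{alignment}
#'   (groupwise affine result), and \code{probs} (warped probability maps).
#' @export
extract_series <- function(series, atlas, w = force_weights(iters = 300),
                           subdivisions = 4, remove_cereb = FALSE,
                           align = TRUE) {
  nt <- length(series)
  aligned <- series
  if (align && nt >= 2) {
    ga <- groupwise_affine(series, iters = 2)
    aligned <- lapply(seq_len(nt), function(i)
      warp_affine(series[[i]], ga$pulls[[i]], series[[i]]))
  } else {
    ga <- list(pulls = list(diag(4)), affines = list(diag(4)),
               mean = series[[1]])
  }
  probs <- lapply(aligned, function(im)
    warp_probability_map(atlas$brain_prob, im, template = atlas$template))
  spheres <- lapply(seq_len(nt), function(i)
    estimate_sphere(aligned[[i]], probs[[i]]$voxels >= 0.5))
  cs <- common_sphere(spheres)
  init <- replicate(nt, tessellate_sphere(cs, subdivisions), simplify = FALSE)
  meshes <- evolve_surfaces_4d(aligned, probs, init, w)
  masks <- vector("list", nt)
  for (t in seq_len(nt)) {
    mask_common <- mesh_to_mask(meshes[[t]], aligned[[t]])
    # back to native space: native voxel x pulls from common via forward map
    masks[[t]] <- warp_affine(mask_common, ga$affines[[t]], series[[t]],
                              interp = "nearest")
  }
  if (remove_cereb && !is.null(atlas$cereb_mask)) {
    brains <- lapply(seq_len(nt), function(t)
      with_voxels(series[[t]], series[[t]]$voxels * (masks[[t]]$voxels > 0.5)))
    masks <- remove_cerebellum(brains, masks, atlas$template,
                               atlas$cereb_mask)
  }
  list(masks = masks, meshes = meshes, alignment = ga, probs = probs)
}
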