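# Consistent ROI labeling: longitudinal groupwise registration of the series
# to an unbiased group-mean image (key-point selection, robust NCC matching,
# kernel smoothing of temporal trajectories, TPS densification, group-mean
# update), symmetric pairwise atlas-to-mean registration with the same
# machinery, deformation composition, and nearest-neighbour label mapping.

#' Hierarchical key-point selection
#'
#' Saliency is the smallest eigenvalue of the local image structure tensor
#' (3D Shi-Tomasi cornerness), evaluated over a Gaussian pyramid. This scores
#' points whose position is determined in all three directions by the local
#' intensity pattern, and intrinsically suppresses smooth edges and ridges,
#' whose tangential position is ambiguous and which would corrupt feature
#' matching. Per level, voxels are picked greedily by saliency subject to a
#' minimum pairwise separation, stratified over spatial cells so no single
#' structure monopolizes the point set; finer levels add points where coarse
#' coverage is sparse.
#'
#' @param img an \code{\link{image_grid}}.
#' @param n_per_level points requested per pyramid level (coarse to fine).
#' @param levels pyramid depth.
#' @param r_min minimum separation between key points, voxels (at full
#'   resolution).
#' @return List with \code{points} (K x 3, 0-based full-resolution voxel
#'   coords) and \code{saliency} (descending within each level).
#' @export
select_keypoints <- function(img, n_per_level = c(60, 60), levels = 2,
                             r_min = 5) {
  n_per_level <- rep(n_per_level, length.out = levels)
  pts <- matrix(numeric(0), 0, 3)
  sal <- numeric(0)
  for (lv in seq_len(levels)) {
    f <- 2^(levels - lv)           # coarse first
    im <- if (f > 1) downsample(img, f) else img
    v <- im$voxels
    s <- structure_tensor_lmin(v, im$spacing)
    if (max(s) <= 1e-12) next
    # stratified candidates: the strongest voxel per spatial cell, so one
    # dominant edge class cannot monopolize the point set
    cell_mm <- 12
    cs <- pmax(1L, as.integer(round(cell_mm / im$spacing)))
    d <- dim(v)
    ai <- arrayInd(seq_along(s), d)
    cellid <- (ai[, 1] - 1) %/% cs[1] +
      1000L * ((ai[, 2] - 1) %/% cs[2]) +
      1000000L * ((ai[, 3] - 1) %/% cs[3])
    keep <- s > 0.02 * max(s)
    o <- order(s, decreasing = TRUE)
    o <- o[keep[o]]
    o <- o[!duplicated(cellid[o])]          # best candidate per cell
    cand <- (ai[o, , drop = FALSE] - 1) * f # full-res voxel coords
    picked <- 0L
    for (i in seq_along(o)) {
      p <- cand[i, ]
      if (nrow(pts) > 0 &&
          min(rowSums(sweep(pts, 2L, p)^2)) < r_min^2) next
      pts <- rbind(pts, p)
      sal <- c(sal, s[o[i]])
      picked <- picked + 1L
      if (picked >= n_per_level[lv]) break
    }
  }
  list(points = pts, saliency = sal)
}

# Smallest eigenvalue of the Gaussian-windowed structure tensor, per voxel
# (analytic symmetric 3x3 eigenvalues).
structure_tensor_lmin <- function(v, spacing, window_mm = 3) {
  g <- array_gradient(gauss_smooth(v, mean(spacing), spacing), spacing)
  sm <- function(a) gauss_smooth(a, window_mm, spacing)
  Jxx <- sm(g$gx * g$gx); Jyy <- sm(g$gy * g$gy); Jzz <- sm(g$gz * g$gz)
  Jxy <- sm(g$gx * g$gy); Jxz <- sm(g$gx * g$gz); Jyz <- sm(g$gy * g$gz)
  q <- (Jxx + Jyy + Jzz) / 3
  p1 <- Jxy^2 + Jxz^2 + Jyz^2
  p2 <- (Jxx - q)^2 + (Jyy - q)^2 + (Jzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 1e-30) / 6)
  bxx <- (Jxx - q) / p; byy <- (Jyy - q) / p; bzz <- (Jzz - q) / p
  bxy <- Jxy / p; bxz <- Jxz / p; byz <- Jyz / p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  lmin <- q + 2 * p * cos(phi + 2 * pi / 3)
  lmin[p2 < 1e-30] <- 0
  pmax(lmin, 0)
}

#' Robust key-point matching by patch NCC
#'
#' For every key point, the best normalized cross-correlation of a local
#' patch within a search radius; matches are kept when NCC clears a threshold
#' and the backward match lands within one voxel of the start (mutual-best).
#'
#' @param mean_img,target \code{\link{image_grid}}s on one grid.
#' @param kps \code{\link{select_keypoints}} output on \code{mean_img}.
#' @param search_radius search radius, voxels.
#' @param patch patch half-width (patch side is \code{2*patch+1}).
#' @param ncc_min acceptance threshold on NCC.
#' @param distinct_min required NCC margin between the best match and the
#'   best competitor at least 2 voxels away; rejects aperture-ambiguous
#'   points (e.g. on smooth spherical edges) whose tangential position is
#'   not determined by the local patch.
#' @return data.frame with columns \code{x,y,z} (key point, 0-based voxels),
#'   \code{mx,my,mz} (matched point in target), \code{ncc}.
#' @export
match_keypoints <- function(mean_img, target, kps, search_radius = 8,
                            patch = 3, ncc_min = 0.6, distinct_min = 0.005) {
  stopifnot(all(grid_dim(mean_img) == grid_dim(target)))
  p0 <- round(kps$points)
  fwd <- cpp_ncc_match(mean_img$voxels, target$voxels, grid_dim(mean_img),
                       matrix(as.integer(p0), ncol = 3), patch, search_radius)
  mp <- p0 + fwd[, 1:3, drop = FALSE]
  bwd <- cpp_ncc_match(target$voxels, mean_img$voxels, grid_dim(mean_img),
                       matrix(as.integer(round(mp)), ncol = 3), patch,
                       search_radius)
  back <- mp + bwd[, 1:3, drop = FALSE]
  rt <- sqrt(rowSums((back - p0)^2))
  keep <- fwd[, 4] >= ncc_min & bwd[, 4] >= ncc_min & rt <= 1 &
    (fwd[, 4] - fwd[, 5]) >= distinct_min &
    (bwd[, 4] - bwd[, 5]) >= distinct_min
  if (!any(keep)) stop("degenerate matching: no key-point match survived")
  data.frame(x = p0[keep, 1], y = p0[keep, 2], z = p0[keep, 3],
             mx = mp[keep, 1], my = mp[keep, 2], mz = mp[keep, 3],
             ncc = fwd[keep, 4])
}

#' Kernel smoothing of key-point trajectories over time
#'
#' Nadaraya-Watson smoothing of each key point's matched positions along the
#' timepoint index with a Gaussian kernel.
#'
#' @param tb numeric array K x T x 3 of matched positions.
#' @param bandwidth kernel bandwidth in units of timepoint index.
#' @return Smoothed array of the same shape.
#' @export
smooth_trajectories <- function(tb, bandwidth = 1.0) {
  nt <- dim(tb)[2]
  if (nt == 1) return(tb)
  W <- outer(seq_len(nt), seq_len(nt),
             function(a, b) exp(-0.5 * ((a - b) / bandwidth)^2))
  out <- tb
  for (d in 1:3) {
    X <- tb[, , d]
    avail <- !is.na(X)
    X0 <- ifelse(avail, X, 0)
    num <- X0 %*% t(W)
    den <- avail %*% t(W)
    out[, , d] <- num / pmax(den, 1e-12)
  }
  out
}

#' Thin-plate-spline deformation field from control points
#'
#' Standard 3D TPS with kernel U(r) = r and an exact affine part;
#' \code{regularization = 0} interpolates the control displacements exactly.
#'
#' @param control_src,control_dst K x 3 matrices (mm, world coords), K >= 4
#'   non-coplanar.
#' @param geometry target \code{\link{image_grid}}; the field is evaluated at
#'   every voxel center.
#' @param regularization ridge added to the kernel matrix diagonal.
#' @return A \code{\link{def_field}} mapping \code{geometry} coords by the
#'   interpolated displacements (src -> dst).
#' @export
tps_field <- function(control_src, control_dst, geometry,
                      regularization = 0) {
  fit <- tps_fit(control_src, control_dst, regularization)
  pts <- grid_world_coords(geometry)
  disp <- cpp_tps_eval(pts, fit$ctrl, fit$W, fit$A)
  d <- grid_dim(geometry)
  def_field(array(disp[, 1], d), array(disp[, 2], d), array(disp[, 3], d),
            geometry)
}

# Solve the TPS system for displacement interpolation.
tps_fit <- function(src, dst, regularization = 0) {
  K <- nrow(src)
  stopifnot(K >= 4, nrow(dst) == K)
  D <- as.matrix(dist(src))
  P <- cbind(1, src)
  L <- rbind(cbind(D + diag(regularization, K), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst - src, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    warning("degenerate TPS system; regularized solve")
    solve(L + diag(1e-6, K + 4), rhs)
  })
  list(ctrl = src, W = sol[1:K, , drop = FALSE],
       A = sol[(K + 1):(K + 4), , drop = FALSE])
}

# Evaluate a TPS fit at arbitrary points (rows, mm).
tps_eval_points <- function(fit, pts) {
  cpp_tps_eval(matrix(pts, ncol = 3), fit$ctrl, fit$W, fit$A)
}

# Robust control-point trim: fit a global affine to the displacements and
# drop correspondences whose residual exceeds 3 x MAD (floored at 2 mm, so
# genuine smooth nonrigid deviation from the affine is kept).
trim_matches <- function(src, dst) {
  if (nrow(src) < 8) return(rep(TRUE, nrow(src)))
  fit <- stats::lm.fit(cbind(1, src), dst - src)
  res <- sqrt(rowSums(fit$residuals^2))
  thr <- max(3 * stats::mad(res), 2)
  res <= thr
}

#' Longitudinal groupwise nonrigid registration
#'
#' Repeats: key-point selection on the current group mean, NCC matching to
#' every (warped) timepoint, assembly of per-key-point temporal trajectories,
#' kernel smoothing along time, TPS densification per timepoint, mean-field
#' subtraction (unbiased common space), image warping and group-mean update.
#'
#' @param series affine-prealigned \code{\link{image_grid}}s.
#' @param rounds number of groupwise rounds.
#' @param bandwidth trajectory smoothing bandwidth (timepoints).
#' @param n_per_level,levels,r_min,search_radius,patch,ncc_min key-point and
#'   matching controls (see \code{\link{select_keypoints}},
#'   \code{\link{match_keypoints}}).
#' @return List with \code{fields_m2t} (mean -> timepoint pull fields, one
#'   per timepoint), \code{fields_t2m} (timepoint -> mean), \code{mean}
#'   (group-mean image), and \code{diagnostics} (per-round data.frame).
#' @export
groupwise_register <- function(series, rounds = 5, bandwidth = 1.0,
                               n_per_level = c(60, 60), levels = 2,
                               r_min = 5, search_radius = 8, patch = 3,
                               ncc_min = 0.6) {
  nt <- length(series)
  geom <- series[[1]]
  mean_img <- with_voxels(geom, Reduce(`+`, lapply(series, `[[`, "voxels")) / nt)
  fields <- replicate(nt, zero_field(geom), simplify = FALSE)
  diag_rows <- list()
  for (r in seq_len(rounds)) {
    warped <- lapply(seq_len(nt), function(t) warp_field(series[[t]], fields[[t]]))
    kps <- select_keypoints(mean_img, n_per_level, levels, r_min)
    if (nrow(kps$points) < 4) stop("too few key points on the group mean")
    matches <- lapply(warped, function(wimg)
      match_keypoints(mean_img, wimg, kps, search_radius, patch, ncc_min))
    # assemble trajectories for every key point matched at >= 2 timepoints
    # (>= 1 when nt == 1); entries missing at a timepoint are filled by the
    # kernel smoother over the available ones
    allkeys <- unique(unlist(lapply(matches, function(m) paste(m$x, m$y, m$z))))
    cnt <- rowSums(vapply(matches, function(m)
      allkeys %in% paste(m$x, m$y, m$z), logical(length(allkeys))))
    keys <- allkeys[cnt >= min(2, nt)]
    if (length(keys) < 4) stop("degenerate matching: too few common key points")
    tb <- array(NA_real_, c(length(keys), nt, 3))
    for (t in seq_len(nt)) {
      m <- matches[[t]]
      rows <- match(keys, paste(m$x, m$y, m$z))
      ok <- !is.na(rows)
      tb[ok, t, ] <- as.matrix(m[rows[ok], c("mx", "my", "mz")])
    }
    src_vox <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
    tbs <- smooth_trajectories(tb, bandwidth)
    src_mm <- voxel_to_world(geom, src_vox)
    upd <- vector("list", nt)
    for (t in seq_len(nt)) {
      dst_mm <- voxel_to_world(geom, tbs[, t, ])
      keep_t <- trim_matches(src_mm, dst_mm)
      upd[[t]] <- tps_field(src_mm[keep_t, , drop = FALSE],
                            dst_mm[keep_t, , drop = FALSE], geom)
    }
    # unbiased common space: subtract the average update
    avg <- upd[[1]]
    if (nt > 1) {
      ax <- Reduce(`+`, lapply(upd, `[[`, "ux")) / nt
      ay <- Reduce(`+`, lapply(upd, `[[`, "uy")) / nt
      az <- Reduce(`+`, lapply(upd, `[[`, "uz")) / nt
      avg <- def_field(ax, ay, az, geom)
      upd <- lapply(upd, function(u)
        def_field(u$ux - avg$ux, u$uy - avg$uy, u$uz - avg$uz, geom))
    } else upd <- list(zero_field(geom))
    fields <- lapply(seq_len(nt), function(t) compose_fields(upd[[t]], fields[[t]]))
    warped <- lapply(seq_len(nt), function(t) warp_field(series[[t]], fields[[t]]))
    mean_img <- with_voxels(geom, Reduce(`+`, lapply(warped, `[[`, "voxels")) / nt)
    ge <- array_gradient(mean_img$voxels, geom$spacing)
    diag_rows[[r]] <- data.frame(
      round = r, keypoints = length(keys),
      mean_ncc = mean(vapply(matches, function(m) mean(m$ncc), numeric(1))),
      mean_field_mm = mean(vapply(fields, function(f)
        mean(sqrt(f$ux^2 + f$uy^2 + f$uz^2)), numeric(1))),
      sharpness = mean(ge$gx^2 + ge$gy^2 + ge$gz^2))
  }
  fields_t2m <- lapply(fields, invert_field)
  list(fields_m2t = fields, fields_t2m = fields_t2m, mean = mean_img,
       diagnostics = do.call(rbind, diag_rows))
}

#' Symmetric pairwise registration of an atlas to the group mean
#'
#' The key-point/NCC/TPS machinery run in both directions; the backward field
#' is inverted and averaged with the forward one.
#'
#' @param atlas,mean_img \code{\link{image_grid}}s on one grid.
#' @param rounds refinement rounds per direction.
#' @param ... matching controls passed on.
#' @return List with \code{field_m2a} (mean -> atlas pull field),
#'   \code{field_a2m}, and \code{symmetric_residual_mm}.
#' @export
register_atlas_to_mean <- function(atlas, mean_img, rounds = 3, ...) {
  f_fwd <- pairwise_tps(mean_img, atlas, rounds, ...)   # mean -> atlas
  f_bwd <- pairwise_tps(atlas, mean_img, rounds, ...)   # atlas -> mean
  f_bwd_inv <- invert_field(f_bwd)
  field_m2a <- def_field((f_fwd$ux + f_bwd_inv$ux) / 2,
                         (f_fwd$uy + f_bwd_inv$uy) / 2,
                         (f_fwd$uz + f_bwd_inv$uz) / 2, f_fwd$geometry)
  field_a2m <- invert_field(field_m2a)
  comp <- compose_fields(field_m2a, field_a2m)
  res <- mean(sqrt(comp$ux^2 + comp$uy^2 + comp$uz^2))
  list(field_m2a = field_m2a, field_a2m = field_a2m,
       symmetric_residual_mm = res)
}

# Iterated keypoint/NCC/TPS refinement of a pull field fixed -> moving.
pairwise_tps <- function(fixed, moving, rounds = 3, n_per_level = c(60, 60),
                         levels = 2, r_min = 5, search_radius = 8, patch = 3,
                         ncc_min = 0.6) {
  geom <- fixed
  field <- zero_field(geom)
  for (r in seq_len(rounds)) {
    warped <- warp_field(moving, field)
    kps <- select_keypoints(fixed, n_per_level, levels, r_min)
    m <- match_keypoints(fixed, warped, kps, search_radius, patch, ncc_min)
    src_mm <- voxel_to_world(geom, as.matrix(m[, c("x", "y", "z")]))
    dst_mm <- voxel_to_world(geom, as.matrix(m[, c("mx", "my", "mz")]))
    keep <- trim_matches(src_mm, dst_mm)
    upd <- tps_field(src_mm[keep, , drop = FALSE],
                     dst_mm[keep, , drop = FALSE], geom)
    field <- compose_fields(upd, field)
  }
  field
}

#' Nearest-neighbour label propagation through a deformation field
#'
#' @param labels integer-valued \code{\link{image_grid}}.
#' @param field \code{\link{def_field}} on the target grid (target -> label
#'   space).
#' @return Integer \code{\link{image_grid}} on the field's grid; the output
#'   label set is a subset of the input's.
#' @export
propagate_labels <- function(labels, field) {
  out <- warp_field(labels, field, interp = "nearest")
  with_voxels(out, array(as.integer(round(out$voxels)), grid_dim(out)))
}

#' Label a longitudinal series from an atlas
#'
#' Full labeling stage: groupwise registration of the (prealigned) series to
#' the group mean, symmetric atlas-to-mean registration, composition of each
#' timepoint's field with the mean-to-atlas field, and nearest-neighbour
#' label propagation onto every timepoint.
#'
#' @param series affine-prealigned timepoint images.
#' @param atlas_img atlas template image on the same grid.
#' @param atlas_labels integer ROI labels on the atlas grid.
#' @param rounds,bandwidth groupwise controls.
#' @param ... matching controls.
#' @return List with \code{labels} (list of integer \code{image_grid}),
#'   \code{group} (groupwise result), \code{atlas_reg} (symmetric pairwise
#'   result).
#' @export
label_series <- function(series, atlas_img, atlas_labels, rounds = 5,
                         bandwidth = 1.0, ...) {
  gw <- groupwise_register(series, rounds = rounds, bandwidth = bandwidth, ...)
  ar <- register_atlas_to_mean(atlas_img, gw$mean, ...)
  labs <- vector("list", length(series))
  for (t in seq_along(series)) {
    # timepoint -> mean -> atlas, then pull labels back
    f_t2a <- compose_fields(gw$fields_t2m[[t]], ar$field_m2a)
    labs[[t]] <- propagate_labels(atlas_labels, f_t2a)
  }
  list(labels = labs, group = gw, atlas_reg = ar)
}
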