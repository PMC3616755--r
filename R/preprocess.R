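# Intensity normalization of a serial image set: smooth multiplicative
# bias-field correction per image (an N3-style scheme: iterative histogram
# sharpening in the log domain alternated with a smooth B-spline field fit),
# then piecewise-linear histogram matching of follow-ups to the baseline.

#' N3-style bias field correction
#'
#' Iteratively estimates a smooth multiplicative gain field. Each iteration
#' (a) sharpens the histogram of masked log-intensities by Wiener
#' deconvolution against a Gaussian blur kernel and forms the conditional
#' expectation of the "true" log-intensity given the observed one, and (b)
#' fits a smooth tensor-product cubic B-spline field (control-point spacing
#' \code{control_spacing} mm) to the residual between observed and expected
#' log intensity. The fitted log-field is zero-mean over the mask, so the
#' corrected image keeps the masked mean intensity.
#'
#' @param img nonnegative \code{\link{image_grid}}.
#' @param mask logical array or binary \code{\link{image_grid}} of voxels to
#'   fit on (nonempty).
#' @param iters maximum iterations.
#' @param fwhm Gaussian blur FWHM in log-intensity units for histogram
#'   sharpening.
#' @param control_spacing B-spline knot spacing, mm.
#' @param nbins histogram bins.
#' @param tol stop when the maximum absolute field update drops below this.
#' @return List with \code{corrected} (\code{image_grid}), and \code{bias}
#'   (class \code{bias_field}: \code{log_field} array plus
#'   \code{control_spacing}).
#' @export
correct_bias <- function(img, mask, iters = 50, fwhm = 0.15,
                         control_spacing = 40, nbins = 200, tol = 1e-3) {
  stopifnot(is_image_grid(img))
  m <- if (is_image_grid(mask)) mask$voxels > 0.5 else mask
  if (!any(m)) stop("bias correction mask is empty")
  v <- img$voxels
  if (min(v) < 0) stop("image must be nonnegative")
  dm <- grid_dim(img)
  eps <- max(v) * 1e-6 + 1e-12
  logv <- log(v + eps)
  sigma <- fwhm * FWHM_TO_SIGMA

  # fit on a deterministic subsample of the mask (enough for a smooth field)
  lin_all <- which(m)
  stride <- max(1L, length(lin_all) %/% 30000L)
  lin <- lin_all[seq(1L, length(lin_all), by = stride)]
  bs <- bs_basis((arrayInd(lin, dm) - 1L), dm, img$spacing, control_spacing)
  logv_s <- logv[lin]
  field_s <- numeric(length(lin))
  phi <- NULL
  for (it in seq_len(iters)) {
    resid <- logv_s - field_s
    expected <- sharpen_expectation(resid, sigma, nbins)
    evidence <- field_s + (resid - expected)
    phi <- bs_fit(bs, evidence)
    new_field <- bs_eval(bs, phi)
    new_field <- new_field - mean(new_field)
    delta <- max(abs(new_field - field_s))
    field_s <- new_field
    if (delta < tol) break
  }

  # reconstruct the smooth field over the whole grid at half resolution,
  # then fix the gain constant so the masked mean intensity is preserved
  cd <- pmax(2L, as.integer(ceiling(dm / 2)))
  cidx <- as.matrix(expand.grid((seq_len(cd[1]) - 1) * 2,
                                (seq_len(cd[2]) - 1) * 2,
                                (seq_len(cd[3]) - 1) * 2))
  cidx[, 1] <- pmin(cidx[, 1], dm[1] - 1)
  cidx[, 2] <- pmin(cidx[, 2], dm[2] - 1)
  cidx[, 3] <- pmin(cidx[, 3], dm[3] - 1)
  bsg <- bs_basis(cidx, dm, img$spacing, control_spacing)
  coarse <- array(bs_eval(bsg, phi), cd)
  cgeom <- image_grid(coarse, spacing = img$spacing * 2,
                      origin = img$origin, direction = img$direction)
  field <- resample_to(cgeom, img)$voxels
  field <- field - mean(field[m])
  dim(field) <- dm
  # gain normalization: a constant offset so corrected and input have the
  # same masked mean intensity (a zero-mean log field alone leaves a Jensen
  # gap of about half the field variance)
  corr0 <- (img$voxels + eps) / exp(field)
  field <- field + log(mean(corr0[m]) / mean(img$voxels[m] + eps))

  corrected <- with_voxels(img, pmax(0, (img$voxels + eps) / exp(field) - eps))
  bias <- structure(list(log_field = field, control_spacing = control_spacing),
                    class = "bias_field")
  list(corrected = corrected, bias = bias)
}

# Histogram sharpening: Wiener-deconvolve the histogram of u against a
# Gaussian of sd `sigma`, then return E[true | observed] per data point.
sharpen_expectation <- function(u, sigma, nbins) {
  rng <- range(u)
  if (diff(rng) < 1e-9) return(u)
  pad <- nbins %/% 2
  h <- diff(rng) / (nbins - 1)
  centers <- seq(rng[1], rng[2], length.out = nbins)
  bin <- pmin(nbins, pmax(1L, as.integer(round((u - rng[1]) / h)) + 1L))
  f <- tabulate(bin, nbins)
  n <- nbins + 2 * pad
  fp <- c(rep(0, pad), f, rep(0, pad))
  # circular Gaussian kernel, centered at index 1
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * h
  g <- exp(-0.5 * (x / sigma)^2)
  g <- g / sum(g)
  Fg <- fft(g)
  Ff <- fft(fp)
  # Wiener deconvolution of the observed histogram
  wiener <- Conj(Fg) / (Mod(Fg)^2 + 0.1)
  fu <- Re(fft(Ff * wiener, inverse = TRUE)) / n
  fu[fu < 0] <- 0
  fu <- fu[(pad + 1):(pad + nbins)]
  # E[u | v]: smooth both fu and u*fu with the blur kernel, take the ratio
  num <- blur_circ(fu * centers, g, pad)
  den <- blur_circ(fu, g, pad)
  den[den < 1e-12] <- 1e-12
  emap <- num / den
  approx(centers, emap, xout = u, rule = 2)$y
}

# Circular convolution with a kernel already laid out for the padded length
# (centered at index 1, wrap-around).
blur_circ <- function(f, g, pad) {
  n <- length(f) + 2 * pad
  fp <- c(rep(0, pad), f, rep(0, pad))
  out <- Re(fft(fft(fp) * fft(g), inverse = TRUE)) / n
  out[(pad + 1):(pad + length(f))]
}

# Cubic B-spline basis values for parameter t in [0,1) at the 4 support knots.
bspline_w <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Tensor-product cubic B-spline scattered-data machinery (BA-style
# approximation). bs_basis precomputes, for a set of 0-based voxel index
# triplets, the 64 support control-point linear indices and basis weights;
# bs_fit produces control values from data by squared-weight averaging;
# bs_eval evaluates the spline at the setup's points.
bs_basis <- function(idx, dm, spacing, control_spacing) {
  nctl <- integer(3); cell <- list(); wts <- list()
  for (a in 1:3) {
    sp_vox <- control_spacing / spacing[a]
    x <- idx[, a] / sp_vox
    cell[[a]] <- floor(x)
    wts[[a]] <- bspline_w(x - cell[[a]])
    nctl[a] <- as.integer(floor((dm[a] - 1) / sp_vox)) + 4L
  }
  n <- nrow(idx)
  W <- matrix(0, n, 64)
  Lin <- matrix(0L, n, 64)
  q <- 1L
  for (k in 1:4) for (j in 1:4) for (i in 1:4) {
    W[, q] <- wts[[1]][, i] * wts[[2]][, j] * wts[[3]][, k]
    Lin[, q] <- as.integer(cell[[1]] + (i - 1L) +
                           nctl[1] * (cell[[2]] + (j - 1L) +
                                      nctl[2] * (cell[[3]] + (k - 1L))) + 1L)
    q <- q + 1L
  }
  n <- nrow(idx)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), 64), j = as.vector(Lin),
                            x = as.vector(W), dims = c(n, prod(nctl)))
  AtA <- Matrix::crossprod(A)
  ridge <- 1e-4 * mean(Matrix::diag(AtA)) + 1e-10
  chol <- Matrix::Cholesky(AtA + ridge * Matrix::Diagonal(prod(nctl)),
                           LDL = FALSE)
  list(W = W, Lin = Lin, A = A, chol = chol, nctl = nctl)
}

# Least-squares control values (ridge-stabilized; boundary controls with no
# data support shrink to zero).
bs_fit <- function(bs, r) {
  as.numeric(Matrix::solve(bs$chol, Matrix::crossprod(bs$A, r)))
}

bs_eval <- function(bs, phi) {
  rowSums(bs$W * matrix(phi[bs$Lin], nrow(bs$W), 64))
}

#' Histogram matching by monotone quantile mapping
#'
#' Maps the moving image's masked intensity quantiles onto the reference's
#' with a piecewise-linear nondecreasing map, applied to the whole volume.
#'
#' @param moving,reference \code{\link{image_grid}}s.
#' @param moving_mask,reference_mask logical arrays (or binary image_grids);
#'   default: intensity > 0 support.
#' @param n_quantiles number of quantile anchors, evenly spaced in (0, 1).
#' @return The remapped moving \code{\link{image_grid}}.
#' @export
match_histogram <- function(moving, reference, moving_mask = NULL,
                            reference_mask = NULL, n_quantiles = 256) {
  as_mask <- function(mk, img) {
    if (is.null(mk)) return(img$voxels > 0)
    if (is_image_grid(mk)) mk$voxels > 0.5 else mk
  }
  mm <- as_mask(moving_mask, moving)
  rm_ <- as_mask(reference_mask, reference)
  if (!any(mm) || !any(rm_)) stop("histogram-matching masks must be nonempty")
  p <- seq_len(n_quantiles) / (n_quantiles + 1)
  # range endpoints anchor the map so extremes are mapped, not clamped
  qm <- c(min(moving$voxels[mm]),
          quantile(moving$voxels[mm], p, names = FALSE),
          max(moving$voxels[mm]))
  qr <- c(min(reference$voxels[rm_]),
          quantile(reference$voxels[rm_], p, names = FALSE),
          max(reference$voxels[rm_]))
  if (diff(range(qm)) < 1e-12) {
    if (diff(range(qr)) > 1e-12)
      stop("degenerate map: constant moving intensities, non-constant reference")
    return(moving)
  }
  qr <- cummax(qr)  # enforce nondecreasing map
  keep <- !duplicated(qm)
  out <- approx(qm[keep], qr[keep], xout = as.numeric(moving$voxels),
                rule = 2)$y
  with_voxels(moving, out)
}

#' Preprocess a longitudinal series
#'
#' Bias-corrects every timepoint, then histogram-matches each follow-up to
#' the baseline (star topology).
#'
#' @param series list of \code{\link{image_grid}}s, baseline first.
#' @param masks optional list of fitting masks (default: intensity above the
#'   10% quantile of positive values, per image).
#' @param bias_iters,quantiles tuning for the two steps.
#' @return List with \code{series} (corrected+matched), \code{bias} (list of
#'   \code{bias_field}), and \code{ks} (per-image Kolmogorov-Smirnov
#'   statistic against the baseline after matching).
#' @export
preprocess_series <- function(series, masks = NULL, bias_iters = 50,
                              quantiles = 256) {
  if (is.null(masks)) {
    masks <- lapply(series, function(im) {
      pos <- im$voxels[im$voxels > 0]
      im$voxels > quantile(pos, 0.1)
    })
  }
  corrected <- vector("list", length(series))
  bias <- vector("list", length(series))
  for (i in seq_along(series)) {
    cb <- correct_bias(series[[i]], masks[[i]], iters = bias_iters)
    corrected[[i]] <- cb$corrected
    bias[[i]] <- cb$bias
  }
  out <- corrected
  ks <- numeric(length(series))
  for (i in seq_along(series)) {
    if (i > 1) {
      out[[i]] <- match_histogram(corrected[[i]], corrected[[1]],
                                  masks[[i]], masks[[1]],
                                  n_quantiles = quantiles)
    }
    ks[i] <- ks_statistic(out[[i]]$voxels[masks[[i]]],
                          out[[1]]$voxels[masks[[1]]])
  }
  list(series = out, bias = bias, ks = ks)
}

# Two-sample KS statistic (statistic only; no ties warning machinery).
ks_statistic <- function(a, b) {
  ec <- stats::ecdf(b)
  x <- sort(a)
  max(abs(ec(x) - seq_along(x) / length(x)))
}
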