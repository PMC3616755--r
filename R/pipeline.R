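# Pipeline orchestration: the five stages (preprocess -> extract -> segment
# -> label -> roi) run in order on a subject's series, each stage writing its
# artifacts under the output directory so any stage can be re-run or resumed
# independently.

#' Pipeline configuration
#'
#' @param standard_spacing,standard_shape canonical grid (the classic
#'   full-size standard is 1 mm^3 / 256^3; the test profile is 96^3).
#' @param seed top-level seed threaded to every stochastic component.
#' @param bias_iters,quantiles preprocess controls.
#' @param extract_w \code{\link{force_weights}} for extraction.
#' @param seg_w \code{\link{seg_weights}} for segmentation.
#' @param label_rounds,label_bandwidth labeling controls.
#' @param roi_defs named list of ROI definitions (basic label id vectors);
#'   NULL = one ROI per basic label found in the atlas.
#' @param remove_cereb remove the cerebellum after extraction.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(standard_spacing = c(1, 1, 1),
                            standard_shape = c(96, 96, 96),
                            seed = 1,
                            bias_iters = 50, quantiles = 256,
                            extract_w = force_weights(iters = 300),
                            seg_w = seg_weights(),
                            label_rounds = 4, label_bandwidth = 1.0,
                            roi_defs = NULL, remove_cereb = FALSE) {
  structure(list(standard_spacing = standard_spacing,
                 standard_shape = standard_shape, seed = seed,
                 bias_iters = bias_iters, quantiles = quantiles,
                 extract_w = extract_w, seg_w = seg_w,
                 label_rounds = label_rounds,
                 label_bandwidth = label_bandwidth,
                 roi_defs = roi_defs, remove_cereb = remove_cereb),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected.
#'
#' @param path JSON file with any subset of \code{\link{pipeline_config}}'s
#'   arguments (\code{extract_w}/\code{seg_w} given as parameter objects).
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$extract_w)) raw$extract_w <- do.call(force_weights, raw$extract_w)
  if (!is.null(raw$seg_w)) raw$seg_w <- do.call(seg_weights, raw$seg_w)
  do.call(pipeline_config, raw)
}

#' Run the full longitudinal pipeline
#'
#' Stages run in order; each stage's outputs are written as NIfTI/CSV under
#' \code{out_dir} and feed the next stage. A stage whose outputs already
#' exist is skipped (resumability); delete its files to force a re-run.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param series_paths character vector of per-timepoint volume paths
#'   (baseline first), or a list of \code{image_grid}s.
#' @param atlas list with \code{template}, \code{brain_prob}, \code{priors}
#'   (csf/gm/wm), \code{labels}, optionally \code{cereb_mask} — as paths or
#'   \code{image_grid}s.
#' @param times timepoints in months.
#' @param out_dir output directory.
#' @return Invisibly, a list with the per-stage artifact paths and the ROI
#'   table; also writes \code{pipeline_log.json}.
#' @export
run_pipeline <- function(config, series_paths, atlas, times, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list(config = utils::capture.output(utils::str(config)))
  tic <- function() Sys.time()
  took <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 1)

  load_img <- function(x) {
    if (is_image_grid(x)) return(x)
    img <- read_volume(x)
    if (img$needs_reorient) stop("input requires explicit reorientation: ", x)
    img <- reorient(img, canonical_orientation(img))
    resample_standard(img, config$standard_spacing, config$standard_shape)
  }
  nt <- length(series_paths)
  series <- lapply(series_paths, load_img)
  atlas_imgs <- lapply(atlas, function(a) {
    if (is.list(a) && !is_image_grid(a)) lapply(a, load_img) else load_img(a)
  })

  stage_file <- function(stage, i, what = "nii.gz")
    file.path(out_dir, sprintf("tp%02d_%s.%s", i, stage, what))

  # ---- preprocess ----
  pp_files <- vapply(seq_len(nt), function(i) stage_file("hm", i), "")
  t0 <- tic()
  if (!all(file.exists(pp_files))) {
    pp <- preprocess_series(series, bias_iters = config$bias_iters,
                            quantiles = config$quantiles)
    for (i in seq_len(nt)) {
      write_volume(pp$series[[i]], stage_file("hm", i))
      write_volume(with_voxels(series[[i]],
                               exp(pp$bias[[i]]$log_field)),
                   stage_file("biasfield", i))
    }
    log$preprocess <- list(seconds = took(t0), ks = pp$ks)
    pre <- pp$series
  } else {
    pre <- lapply(pp_files, read_volume)
    log$preprocess <- list(skipped = TRUE)
  }

  # ---- extract ----
  mask_files <- vapply(seq_len(nt), function(i) stage_file("brainmask", i), "")
  t0 <- tic()
  if (!all(file.exists(mask_files))) {
    ex <- extract_series(pre, atlas_imgs, w = config$extract_w,
                         remove_cereb = config$remove_cereb)
    for (i in seq_len(nt)) {
      write_volume(ex$masks[[i]], stage_file("brainmask", i), datatype = "uint8")
      write_volume(with_voxels(pre[[i]],
                               pre[[i]]$voxels * (ex$masks[[i]]$voxels > 0.5)),
                   stage_file("brain", i))
    }
    log$extract <- list(seconds = took(t0))
    masks <- ex$masks
  } else {
    masks <- lapply(mask_files, read_volume)
    log$extract <- list(skipped = TRUE)
  }
  brains <- lapply(seq_len(nt), function(i)
    with_voxels(pre[[i]], pre[[i]]$voxels * (masks[[i]]$voxels > 0.5)))

  # ---- segment ----
  seg_files <- vapply(seq_len(nt), function(i) stage_file("seg", i), "")
  t0 <- tic()
  if (!all(file.exists(seg_files))) {
    # align brains to common space for shared priors
    ga <- if (nt >= 2) groupwise_affine(brains, iters = 1) else
      list(pulls = list(diag(4)), affines = list(diag(4)), mean = brains[[1]])
    aligned <- lapply(seq_len(nt), function(i)
      warp_affine(brains[[i]], ga$pulls[[i]], brains[[i]]))
    A <- affine_register(ga$mean, atlas_imgs$template, levels = c(4, 2))
    f0 <- field_from_affine(A, ga$mean)
    fd <- demons_register(ga$mean, atlas_imgs$template, init = f0,
                          levels = c(4, 2), iters = c(40, 20))
    priors <- lapply(atlas_imgs$priors, function(p) {
      wp <- warp_field(p, fd)
      with_voxels(wp, pmin(1, pmax(0, wp$voxels)))
    })
    sg <- segment_series_4d(aligned, priors, w = config$seg_w)
    segs <- vector("list", nt)
    for (i in seq_len(nt)) {
      segs[[i]] <- warp_affine(sg$labels[[i]], ga$affines[[i]], brains[[i]],
                               interp = "nearest")
      write_volume(segs[[i]], stage_file("seg", i), datatype = "uint8")
      th <- sg$thickness[[i]]
      th[is.na(th)] <- 0
      thn <- warp_affine(with_voxels(aligned[[i]], th), ga$affines[[i]],
                         brains[[i]])
      write_volume(thn, stage_file("thickness", i))
    }
    utils::write.csv(data.frame(iteration = seq_along(unlist(sg$energy)),
                                energy = unlist(sg$energy)),
                     file.path(out_dir, "segmentation_energy.csv"),
                     row.names = FALSE)
    log$segment <- list(seconds = took(t0))
  } else {
    segs <- lapply(seg_files, read_volume)
    log$segment <- list(skipped = TRUE)
  }

  # ---- label ----
  lab_files <- vapply(seq_len(nt), function(i) stage_file("labels", i), "")
  t0 <- tic()
  if (!all(file.exists(lab_files))) {
    ga <- if (nt >= 2) groupwise_affine(brains, iters = 1) else
      list(pulls = list(diag(4)), affines = list(diag(4)), mean = brains[[1]])
    aligned <- lapply(seq_len(nt), function(i)
      warp_affine(brains[[i]], ga$pulls[[i]], brains[[i]]))
    A <- affine_register(ga$mean, atlas_imgs$template, levels = c(4, 2))
    atlas_al <- warp_affine(atlas_imgs$template, A, ga$mean)
    labs_al <- warp_affine(atlas_imgs$labels, A, ga$mean, interp = "nearest")
    lb <- label_series(aligned, atlas_al, labs_al,
                       rounds = config$label_rounds,
                       bandwidth = config$label_bandwidth)
    labels <- vector("list", nt)
    for (i in seq_len(nt)) {
      labels[[i]] <- warp_affine(lb$labels[[i]], ga$affines[[i]], brains[[i]],
                                 interp = "nearest")
      write_volume(labels[[i]], stage_file("labels", i), datatype = "uint16")
    }
    utils::write.csv(lb$group$diagnostics,
                     file.path(out_dir, "labeling_diagnostics.csv"),
                     row.names = FALSE)
    log$label <- list(seconds = took(t0))
  } else {
    labels <- lapply(lab_files, read_volume)
    log$label <- list(skipped = TRUE)
  }

  # ---- roi ----
  t0 <- tic()
  roi_defs <- config$roi_defs
  if (is.null(roi_defs)) {
    ids <- sort(unique(as.integer(labels[[1]]$voxels)))
    ids <- ids[ids > 0]
    roi_defs <- stats::setNames(as.list(ids), paste0("roi_", ids))
  }
  tab <- roi_table(labels, times, roi_defs, seg_series = segs, tissue_id = 2L)
  export_table(tab, file.path(out_dir, "roi_volumes.csv"))
  log$roi <- list(seconds = took(t0))

  jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(out_dir = out_dir, roi_table = tab, log = log))
}
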