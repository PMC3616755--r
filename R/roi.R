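# ROI volumetry over time. This module is tabular: functions take/return
# tibbles so results chain with the pipe, and trend fits follow the
# tidy()/glance() convention.

#' Measure ROI volumes from a label image
#'
#' Each ROI is a named union of basic label ids; shared voxels are counted
#' once.
#'
#' @param labels integer label \code{\link{image_grid}}.
#' @param roi_defs named list mapping ROI name -> integer vector of basic
#'   label ids.
#' @return A tibble with \code{roi}, \code{n_voxels}, \code{volume_mm3}.
#' @export
measure_volumes <- function(labels, roi_defs) {
  stopifnot(is_image_grid(labels))
  lab <- as.integer(round(labels$voxels))
  present <- sort(unique(lab[lab > 0]))
  unknown <- setdiff(unlist(roi_defs), present)
  if (length(unknown) > 0)
    stop("unknown basic label id(s): ", paste(unknown, collapse = ", "))
  vv <- prod(labels$spacing)
  counts <- tabulate(lab, nbins = max(present))
  n <- unname(vapply(roi_defs, function(ids) sum(counts[ids]), numeric(1)))
  tibble::tibble(roi = names(roi_defs), n_voxels = as.integer(n),
                 volume_mm3 = n * vv)
}

#' Mask an ROI with a tissue class
#'
#' Voxelwise AND of ROI membership and tissue label equality — e.g. the
#' hippocampal GM used for atrophy trends.
#'
#' @param labels ROI label \code{\link{image_grid}}.
#' @param seg tissue segmentation \code{image_grid} (0 bg / 1 CSF / 2 GM /
#'   3 WM) on the same grid.
#' @param roi_ids integer vector of basic ROI label ids.
#' @param tissue_id tissue class to intersect with.
#' @return Binary \code{\link{image_grid}}.
#' @export
mask_roi_with_tissue <- function(labels, seg, roi_ids, tissue_id = 2L) {
  if (!same_geometry(labels, seg)) stop("label/segmentation geometry mismatch")
  m <- (round(labels$voxels) %in% roi_ids) &
    (round(seg$voxels) == tissue_id)
  with_voxels(labels, array(as.numeric(m), grid_dim(labels)))
}

#' Longitudinal ROI table
#'
#' Assembles per-timepoint ROI volumes (optionally tissue-masked) with
#' baseline normalization.
#'
#' @param label_series list of ROI label \code{image_grid}s, one per
#'   timepoint (baseline first).
#' @param times timepoints in months.
#' @param roi_defs named list of basic-label-id vectors.
#' @param seg_series optional list of tissue segmentations; with
#'   \code{tissue_id}, volumes are tissue-masked ROI volumes.
#' @param tissue_id tissue class for masking (default GM).
#' @param subject subject identifier.
#' @return ROITable tibble: \code{subject}, \code{time_months}, \code{roi},
#'   \code{volume_mm3}, \code{normalized_volume} (baseline = 1).
#' @export
roi_table <- function(label_series, times, roi_defs, seg_series = NULL,
                      tissue_id = 2L, subject = "subject1") {
  stopifnot(length(label_series) == length(times))
  rows <- lapply(seq_along(times), function(t) {
    labs <- label_series[[t]]
    if (!is.null(seg_series)) {
      vols <- vapply(roi_defs, function(ids) {
        m <- mask_roi_with_tissue(labs, seg_series[[t]], ids, tissue_id)
        sum(m$voxels) * prod(labs$spacing)
      }, numeric(1))
      tibble::tibble(subject = subject, time_months = times[t],
                     roi = names(roi_defs), volume_mm3 = vols)
    } else {
      v <- measure_volumes(labs, roi_defs)
      tibble::tibble(subject = subject, time_months = times[t],
                     roi = v$roi, volume_mm3 = v$volume_mm3)
    }
  })
  tab <- do.call(rbind, rows)
  base <- tab[tab$time_months == min(times), c("roi", "volume_mm3")]
  names(base)[2] <- "baseline"
  tab <- merge(tab, base, by = "roi", sort = FALSE)
  if (any(tab$baseline <= 0)) stop("zero baseline volume")
  tab$normalized_volume <- tab$volume_mm3 / tab$baseline
  tab$baseline <- NULL
  tibble::as_tibble(tab[order(tab$roi, tab$time_months),
                        c("subject", "time_months", "roi", "volume_mm3",
                          "normalized_volume")])
}

#' Baseline normalization and linear trend of a volume series
#'
#' Normalizes volumes by the baseline (first time) value and fits an ordinary
#' least-squares line to the normalized series.
#'
#' @param volumes per-timepoint volumes.
#' @param times timepoints in months (>= 2 for a slope).
#' @return Object of class \code{roi_trend}: list with \code{normalized},
#'   \code{times}, \code{slope} (per month), \code{intercept}, and the
#'   underlying \code{lm} fit.
#' @export
normalize_and_trend <- function(volumes, times) {
  stopifnot(length(volumes) == length(times), length(times) >= 2)
  base <- volumes[which.min(times)]
  if (base <= 0) stop("zero baseline volume")
  normalized <- volumes / base
  fit <- lm(normalized ~ times)
  structure(list(normalized = normalized, times = times,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), fit = fit),
            class = "roi_trend")
}

#' @export
print.roi_trend <- function(x, ...) {
  cat("<roi_trend> slope", format(x$slope, digits = 4), "per month,",
      "intercept", format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x an object.
#' @param ... unused.
#' @return One row per model term: \code{term}, \code{estimate},
#'   \code{std.error}, \code{statistic}, \code{p.value}.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.roi_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope_per_month"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.roi_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 n_timepoints = length(x$times),
                 slope_per_month = x$slope)
}

#' Write / read an ROI table as CSV
#'
#' @param table ROITable tibble (see \code{\link{roi_table}}).
#' @param path output path.
#' @return \code{path} invisibly; \code{read_roi_table} returns the tibble.
#' @export
export_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_table
#' @export
read_roi_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Plot longitudinal ROI volume trajectories
#'
#' @param table ROITable tibble.
#' @param normalized plot normalized (baseline = 1) volumes.
#' @return A ggplot object.
#' @export
plot_roi_trends <- function(table, normalized = TRUE) {
  yvar <- if (normalized) "normalized_volume" else "volume_mm3"
  ggplot2::ggplot(table, ggplot2::aes(x = .data$time_months,
                                      y = .data[[yvar]],
                                      colour = .data$roi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (months)",
                  y = if (normalized) "volume / baseline" else
                    expression(volume ~ (mm^3)),
                  colour = "ROI") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_roi_trends
#' @param object an \code{roi_trend}.
#' @param ... unused.
#' @export
autoplot.roi_trend <- function(object, ...) {
  df <- data.frame(time_months = object$times,
                   normalized_volume = object$normalized)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_months,
                                   y = .data$normalized_volume)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "time (months)", y = "volume / baseline") +
    ggplot2::theme_minimal()
}
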