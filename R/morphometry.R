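# Iba-1 soma segmentation and morphometry.
#
# Somata are dark (stained) regions on a bright, unevenly stained
# background, so thresholding is adaptive: a pixel is foreground when
# its locally blurred intensity falls sufficiently far below a
# large-window local background estimate.

.box_kernel <- function(w) matrix(1 / (w * w), w, w)

#' Segment microglial somata in a stained histology image
#'
#' (1) blur with a small mean filter; (2) estimate the local background
#' with a large mean filter; (3) mark pixels whose blurred intensity
#' deviates below the local background by more than `offset_fraction`
#' of the background; (4) label connected components; (5) keep regions
#' whose area lies within the configured soma bounds, rejecting thin
#' processes (too small after blurring) and clumps or background blobs
#' (too large). `method = "global"` replaces the local background with
#' the global image mean and is kept as a negative control for uneven
#' staining. The manual-correction step of interactive workflows is
#' externalized as `edits`, a list of region ids to drop.
#'
#' @param image Numeric matrix (grayscale, dark = stained). RGB input
#'   must be reduced to one channel first, see [stain_channel()].
#' @param pixel_size_um Pixel edge, micrometers.
#' @param window_px Blur window (odd), pixels.
#' @param bg_window_px Background-estimation window (odd), pixels; must
#'   be large relative to a soma diameter.
#' @param offset_fraction Required fractional deviation below the local
#'   background.
#' @param min_area_um2,max_area_um2 Soma area bounds, um^2.
#' @param method `"adaptive"` (default) or `"global"`.
#' @param edits Optional list with `drop`, integer region ids to remove
#'   (the reproducible stand-in for manual correction).
#' @return Object of class `soma_segmentation`: `labels` (integer
#'   matrix, 0 = background), `regions`
#'   (`data.frame(id, cx_um, cy_um, area_um2)`),
#'   `total_stained_area_um2` (all foreground incl. processes) and
#'   `pixel_size_um`.
#' @export
segment_somata <- function(image, pixel_size_um, window_px = 5,
                           bg_window_px = 75, offset_fraction = 0.25,
                           min_area_um2 = 12, max_area_um2 = 150,
                           method = c("adaptive", "global"),
                           edits = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), pixel_size_um > 0,
            window_px %% 2 == 1, bg_window_px %% 2 == 1)
  if (window_px > min(dim(image)) || bg_window_px > min(dim(image)))
    stop("filter window larger than the image")
  blur <- EBImage::filter2(image, .box_kernel(window_px),
                           boundary = "replicate")
  bg <- if (method == "adaptive") {
    EBImage::filter2(image, .box_kernel(bg_window_px),
                     boundary = "replicate")
  } else {
    matrix(mean(image), nrow(image), ncol(image))
  }
  fg <- blur < bg * (1 - offset_fraction)
  px_area <- pixel_size_um^2
  total_stained <- sum(fg) * px_area
  labels <- EBImage::bwlabel(fg)
  labels <- matrix(as.integer(labels), nrow(image), ncol(image))
  nreg <- max(labels)
  if (nreg == 0) {
    return(structure(list(labels = labels,
                          regions = data.frame(id = integer(0),
                                               cx_um = numeric(0),
                                               cy_um = numeric(0),
                                               area_um2 = numeric(0)),
                          total_stained_area_um2 = total_stained,
                          pixel_size_um = pixel_size_um),
                     class = "soma_segmentation"))
  }
  areas_px <- tabulate(labels, nbins = nreg)
  areas_um2 <- areas_px * px_area
  keep <- which(areas_um2 >= min_area_um2 & areas_um2 <= max_area_um2)
  if (!is.null(edits$drop)) keep <- setdiff(keep, edits$drop)
  # centroids (pixel-center convention, um)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cx <- rowsum(idx[, 1] - 0.5, lab)[, 1] / areas_px * pixel_size_um
  cy <- rowsum(idx[, 2] - 0.5, lab)[, 1] / areas_px * pixel_size_um
  regions <- data.frame(id = keep, cx_um = cx[keep], cy_um = cy[keep],
                        area_um2 = areas_um2[keep])
  rownames(regions) <- NULL
  labels[!(labels %in% keep)] <- 0L
  structure(list(labels = labels, regions = regions,
                 total_stained_area_um2 = total_stained,
                 pixel_size_um = pixel_size_um),
            class = "soma_segmentation")
}

#' @export
print.soma_segmentation <- function(x, ...) {
  cat(sprintf("<soma_segmentation> %d somata, stained area %.0f um^2\n",
              nrow(x$regions), x$total_stained_area_um2))
  invisible(x)
}

#' Extract one channel (or optical density) from an RGB slide image
#'
#' Simple stain extraction: pick a channel of an `[x, y, 3]` array, or
#' an optical-density transform `-log10(channel)` for absorbance-like
#' intensity. Full color deconvolution is out of scope.
#'
#' @param image Numeric array `x y 3` (values in (0, 1]) or a matrix
#'   (returned as is).
#' @param channel 1 (red), 2 (green) or 3 (blue).
#' @param optical_density Return `-log10(values)` instead of intensity.
#' @return Numeric matrix.
#' @export
stain_channel <- function(image, channel = 3, optical_density = FALSE) {
  m <- if (length(dim(image)) == 3) image[, , channel] else image
  if (optical_density) m <- -log10(pmax(m, 1e-6))
  m
}

#' Soma statistics within a rectangular ROI
#'
#' Statistics are computed over regions whose centroid falls inside the
#' ROI, so two tangent ROIs partition the somata with no double
#' counting.
#'
#' @param seg A [segment_somata()] result.
#' @param roi_um `list(x = c(x0, x1), y = c(y0, y1))` in micrometers, or
#'   NULL for the whole image.
#' @return List with `count`, `median_area_um2`, `iqr_area_um2`
#'   (length 2) and `soma_area_um2` (summed areas); size statistics are
#'   NA when the ROI holds no soma.
#' @export
roi_soma_stats <- function(seg, roi_um = NULL) {
  stopifnot(inherits(seg, "soma_segmentation"))
  r <- seg$regions
  if (!is.null(roi_um)) {
    sel <- r$cx_um >= roi_um$x[1] & r$cx_um <= roi_um$x[2] &
      r$cy_um >= roi_um$y[1] & r$cy_um <= roi_um$y[2]
    r <- r[sel, ]
  }
  if (!nrow(r)) {
    return(list(count = 0L, median_area_um2 = NA_real_,
                iqr_area_um2 = c(NA_real_, NA_real_),
                soma_area_um2 = 0))
  }
  list(count = nrow(r),
       median_area_um2 = stats::median(r$area_um2),
       iqr_area_um2 = unname(stats::quantile(r$area_um2, c(0.25, 0.75))),
       soma_area_um2 = sum(r$area_um2))
}

#' Per-slice LPS-vs-vehicle soma size difference
#'
#' The morphometric marker of microglial activation: per slice, the
#' difference of median soma areas (LPS side minus PBS side), summarized
#' per animal as the median and IQR across slices.
#'
#' @param lps_stats,pbs_stats `data.frame(slice, median_area_um2)` for
#'   the same slice set (order-independent, matched on `slice`).
#' @return List with `per_slice` (`data.frame(slice, diff_um2)`),
#'   `median_diff_um2` and `iqr_diff_um2`.
#' @export
soma_size_difference <- function(lps_stats, pbs_stats) {
  stopifnot(is.data.frame(lps_stats), is.data.frame(pbs_stats))
  if (!setequal(lps_stats$slice, pbs_stats$slice) ||
      nrow(lps_stats) != nrow(pbs_stats))
    stop("LPS and PBS sides must cover the same slice set")
  lps <- lps_stats[order(lps_stats$slice), ]
  pbs <- pbs_stats[order(pbs_stats$slice), ]
  d <- lps$median_area_um2 - pbs$median_area_um2
  list(per_slice = data.frame(slice = lps$slice, diff_um2 = d),
       median_diff_um2 = stats::median(d),
       iqr_diff_um2 = unname(stats::quantile(d, c(0.25, 0.75))))
}

#' Rule-based Iba1 responder classification
#'
#' Surrogate for the expert pathologist's judgment: an animal is called
#' `"Iba1+"` when the soma-size difference exceeds the threshold in a
#' majority of its slices. The threshold (default 0 um^2) is a
#' documented configuration choice, not a validated diagnostic cutoff.
#'
#' @param per_slice_diff Numeric vector of per-slice LPS - PBS median
#'   soma-size differences, um^2.
#' @param threshold_um2 Per-slice positivity threshold.
#' @return `"Iba1+"` or `"Iba1-"`.
#' @export
classify_iba1 <- function(per_slice_diff, threshold_um2 = 0) {
  if (!length(per_slice_diff)) return(NA_character_)
  if (mean(per_slice_diff > threshold_um2) > 0.5) "Iba1+" else "Iba1-"
}
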