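# Rectangular analysis ROIs in scanner (mm) coordinates.

#' Rectangular region of interest in image coordinates
#'
#' The analysis unit of the pipeline: a 1.25 x 1.25 mm square placed
#' over an injection site. Coordinates are in mm with the origin at the
#' image corner (x along the first array dimension).
#'
#' @param center_mm Length-2 center, mm.
#' @param width_mm,height_mm Edge lengths, mm.
#' @param side Optional label, e.g. `"LPS"` or `"PBS"`.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(center_mm, width_mm = 1.25, height_mm = 1.25,
                     side = NA_character_) {
  stopifnot(length(center_mm) == 2, width_mm > 0, height_mm > 0)
  structure(list(center_mm = as.numeric(center_mm), width_mm = width_mm,
                 height_mm = height_mm, side = side),
            class = "roi_spec")
}

#' Convert an ROI to a whole-pixel index window
#'
#' With the default geometry (20 mm / 128 px = 0.15625 mm/px) a 1.25 mm
#' ROI maps to exactly 8 pixels.
#'
#' @param roi An [roi_spec()].
#' @param geometry See [default_geometry()].
#' @return List with integer index vectors `ix` and `iy`.
#' @export
roi_pixels <- function(roi, geometry = default_geometry()) {
  px <- geometry$mm_per_px
  half <- c(roi$width_mm, roi$height_mm) / 2
  lo <- roi$center_mm - half
  n <- pmax(1L, as.integer(round(c(roi$width_mm, roi$height_mm) / px)))
  start <- as.integer(floor(lo / px + 1e-9)) + 1L
  ix <- start[1]:(start[1] + n[1] - 1L)
  iy <- start[2]:(start[2] + n[2] - 1L)
  if (min(ix) < 1 || min(iy) < 1 || max(ix) > geometry$matrix[1] ||
      max(iy) > geometry$matrix[2])
    stop("ROI extends outside the field of view")
  list(ix = ix, iy = iy)
}

#' Logical mask for an ROI
#'
#' @inheritParams roi_pixels
#' @return Logical matrix on the image grid.
#' @export
roi_mask <- function(roi, geometry = default_geometry()) {
  w <- roi_pixels(roi, geometry)
  m <- matrix(FALSE, geometry$matrix[1], geometry$matrix[2])
  m[w$ix, w$iy] <- TRUE
  m
}
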