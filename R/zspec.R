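# CEST stack normalization, spline interpolation, B0 correction and
# MTR asymmetry.

#' CEST/WASSR image stack
#'
#' The on-disk unit of a CEST or WASSR experiment: one 2D image per
#' saturation offset, plus the unsaturated reference image M_0 and the
#' acquisition geometry. Arrays are indexed `[x, y, offset]` with x
#' along the first image dimension.
#'
#' @param volumes Numeric array `nx x ny x n_offsets`.
#' @param offsets Offsets, ppm, one per volume, strictly increasing.
#' @param reference `nx x ny` unsaturated image.
#' @param geometry List with `fov_mm` (length 2), `matrix` (length 2)
#'   and `slice_thickness_mm`.
#' @return Object of class `cest_stack`.
#' @export
cest_stack <- function(volumes, offsets,
                       reference,
                       geometry = default_geometry()) {
  volumes <- as.array(volumes)
  if (length(dim(volumes)) != 3) stop("volumes must be a 3D array")
  if (dim(volumes)[3] != length(offsets))
    stop("one volume per offset required")
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  if (!all(dim(reference) == dim(volumes)[1:2]))
    stop("reference must match the image grid")
  stopifnot(all(geometry$fov_mm > 0), all(geometry$matrix > 0),
            geometry$slice_thickness_mm > 0)
  structure(list(volumes = volumes, offsets = as.numeric(offsets),
                 reference = reference, geometry = geometry,
                 normalized = FALSE),
            class = "cest_stack")
}

#' Default acquisition geometry
#'
#' 20 x 20 mm field of view on a 128 x 128 matrix (0.15625 mm/pixel)
#' with a 2 mm slice, the single-slice CEST readout geometry the
#' pipeline emulates.
#' @param matrix_size Image matrix, length-2 integer.
#' @param fov_mm Field of view, mm, length 2.
#' @param slice_thickness_mm Slice thickness, mm.
#' @export
default_geometry <- function(matrix_size = c(128, 128),
                             fov_mm = c(20, 20),
                             slice_thickness_mm = 2) {
  list(fov_mm = fov_mm, matrix = matrix_size,
       slice_thickness_mm = slice_thickness_mm,
       mm_per_px = fov_mm / matrix_size)
}

#' @export
print.cest_stack <- function(x, ...) {
  cat(sprintf("<cest_stack> %dx%d, %d offsets in [%.3g, %.3g] ppm%s\n",
              dim(x$volumes)[1], dim(x$volumes)[2], length(x$offsets),
              min(x$offsets), max(x$offsets),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Normalize a CEST stack by its reference image
#'
#' Divides every per-offset volume voxelwise by the unsaturated
#' reference M_0 and masks out voxels whose reference intensity falls
#' below the threshold (or is non-positive, which triggers a warning).
#'
#' @param stack A [cest_stack()].
#' @param intensity_threshold Minimum reference intensity for a voxel to
#'   be kept.
#' @return List with `stack` (normalized `cest_stack`) and `mask`
#'   (logical matrix of retained voxels).
#' @export
normalize_stack <- function(stack, intensity_threshold = 0) {
  stopifnot(inherits(stack, "cest_stack"))
  ref <- stack$reference
  mask <- is.finite(ref) & ref >= intensity_threshold
  bad <- mask & ref <= 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-positive reference masked out")
    mask[bad] <- FALSE
  }
  vols <- stack$volumes
  safe_ref <- ifelse(mask, ref, NA_real_)
  for (k in seq_along(stack$offsets)) vols[, , k] <- vols[, , k] / safe_ref
  out <- stack
  out$volumes <- vols
  out$reference <- ifelse(mask, 1, NA_real_)
  out$normalized <- TRUE
  list(stack = out, mask = mask)
}

#' Spline-interpolate a z-spectrum to a dense uniform grid
#'
#' Natural cubic spline through the measured points (no smoothing),
#' evaluated on a uniform grid with the requested step. The
#' interpolant passes exactly through the input points.
#'
#' @param z A [zspectrum()] with at least 4 offsets and no duplicates.
#' @param grid_step Grid step, ppm.
#' @return Dense [zspectrum()].
#' @export
interpolate_spectrum <- function(z, grid_step = 0.01) {
  stopifnot(inherits(z, "zspectrum"))
  if (length(z$offsets) < 4) stop("need at least 4 offsets")
  if (anyDuplicated(z$offsets)) stop("duplicate offsets")
  f <- stats::splinefun(z$offsets, z$values, method = "natural")
  grid <- seq(min(z$offsets), max(z$offsets), by = grid_step)
  zspectrum(grid, f(grid), tol = 0.2)
}

#' Re-center a z-spectrum on the true water frequency
#'
#' Translates the frequency axis by `-shift` (so the direct-saturation
#' dip of a voxel whose water resonates at `shift` ppm is moved back to
#' 0) and resamples on the original offset grid with a natural cubic
#' spline. Offsets that fall outside the measured support after
#' translation are spline-extrapolated; `shift` beyond `max_shift` is
#' rejected so that extrapolation never reaches the analysis range.
#'
#' @param z A [zspectrum()].
#' @param shift Water frequency offset of this voxel, ppm (from WASSR).
#' @param max_shift Largest correctable |shift|, ppm.
#' @return Corrected [zspectrum()] on the original offsets.
#' @export
b0_correct <- function(z, shift, max_shift = 0.3) {
  stopifnot(inherits(z, "zspectrum"))
  if (!is.finite(shift) || abs(shift) > max_shift)
    stop(sprintf("shift %.3g ppm exceeds correctable range (%.3g ppm)",
                 shift, max_shift))
  f <- stats::splinefun(z$offsets, z$values, method = "natural")
  zspectrum(z$offsets, f(z$offsets + shift), tol = 0.2)
}

#' MTR asymmetry at one offset
#'
#' `100 * (M_sat(-delta) - M_sat(+delta)) / M_0` evaluated on a
#' (B0-corrected) normalized z-spectrum, in percent. Values at exactly
#' +/- delta are taken from the natural-spline interpolant, which
#' coincides with the measured values when +/- delta are sampled
#' offsets.
#'
#' @param z A corrected, normalized [zspectrum()].
#' @param delta Offset of interest, ppm (> 0, within support).
#' @return Asymmetry in percent.
#' @export
mtr_asym <- function(z, delta = 0.6) {
  stopifnot(inherits(z, "zspectrum"), delta > 0)
  if (delta > max(z$offsets) || -delta < min(z$offsets))
    stop("delta outside spectrum support")
  f <- stats::splinefun(z$offsets, z$values, method = "natural")
  100 * (f(-delta) - f(delta))
}

#' Full MTR asymmetry spectrum
#'
#' [mtr_asym()] evaluated over a vector of positive offsets.
#'
#' @param z A corrected, normalized [zspectrum()].
#' @param deltas Positive offsets, ppm; defaults to every positive
#'   sampled offset within support.
#' @return `data.frame(offset_ppm, mtr_asym_pct)`.
#' @export
asymmetry_spectrum <- function(z, deltas = NULL) {
  if (is.null(deltas))
    deltas <- z$offsets[z$offsets > 0 & -z$offsets >= min(z$offsets)]
  f <- stats::splinefun(z$offsets, z$values, method = "natural")
  data.frame(offset_ppm = deltas,
             mtr_asym_pct = 100 * (f(-deltas) - f(deltas)))
}

#' Voxelwise B0-corrected MTR asymmetry map
#'
#' For every voxel that is valid in the B0 map (and in the optional
#' mask), interpolates the voxel z-spectrum, re-centers it on the
#' WASSR-estimated water frequency and evaluates [mtr_asym()] at
#' `delta`. Voxels with an invalid B0 estimate, an uncorrectable shift
#' or a failed spectrum are NA in the output and FALSE in the validity
#' mask.
#'
#' @param stack Normalized [cest_stack()] (see [normalize_stack()]).
#' @param b0 A `b0_map` from [build_b0_map()].
#' @param delta Offset of interest, ppm.
#' @param mask Optional logical matrix restricting the computation.
#' @param max_shift Passed to [b0_correct()].
#' @return List with `map` (matrix, percent, NA where invalid) and
#'   `valid` (logical matrix).
#' @export
mtr_asym_map <- function(stack, b0, delta = 0.6, mask = NULL,
                         max_shift = 0.3) {
  stopifnot(inherits(stack, "cest_stack"), isTRUE(stack$normalized))
  if (!any(b0$valid)) stop("B0 map has no valid voxels")
  dims <- dim(stack$volumes)[1:2]
  stopifnot(all(dim(b0$shift) == dims))
  use <- b0$valid
  if (!is.null(mask)) use <- use & mask
  out <- matrix(NA_real_, dims[1], dims[2])
  valid <- matrix(FALSE, dims[1], dims[2])
  offs <- stack$offsets
  idx <- which(use, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    v <- stack$volumes[i, j, ]
    s <- b0$shift[i, j]
    if (!all(is.finite(v)) || !is.finite(s) || abs(s) > max_shift) next
    # natural-spline evaluation at shift -/+ delta == interpolate ->
    # translate axis by -shift -> read off +/- delta
    f <- stats::splinefun(offs, v, method = "natural")
    out[i, j] <- 100 * (f(s - delta) - f(s + delta))
    valid[i, j] <- TRUE
  }
  list(map = out, valid = valid, delta = delta)
}
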