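# Synthetic ground-truth generators: CEST/WASSR phantom stacks,
# histology slides with known soma areas, and LCModel-style metabolite
# tables. All generators are pure functions of (spec, seed).

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's state afterwards, so generators are pure and do not
# perturb the global RNG stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default CEST saturation offsets
#'
#' Uniform 0.2 ppm spacing across +/- 4 ppm (41 offsets including 0).
#' The spacing and range follow the emulated acquisition; whether 0 ppm
#' is part of the schedule is a convention, so every generator takes the
#' offset list explicitly and this helper is only a default.
#' @export
default_cest_offsets <- function() seq(-4, 4, by = 0.2)

#' Default WASSR saturation offsets
#'
#' 35 uniformly spaced offsets across +/- 1 ppm (the emulated count and
#' range; the exact spacing is a convention).
#' @export
default_wassr_offsets <- function() seq(-1, 1, length.out = 35)

#' Specification of a synthetic CEST/WASSR phantom
#'
#' Describes a two-compartment "lesion vs contralateral control" slice:
#' a solute-fraction multiplier map (lesion and control ROI values on a
#' background), a smooth polynomial B0 shift field with an optional
#' localized Gaussian susceptibility artifact, and additive Gaussian
#' noise.
#'
#' @param grid Image matrix size (length 2).
#' @param fov_mm Field of view, mm (length 2).
#' @param lesion_roi,control_roi [roi_spec()]s inside the FOV, non-
#'   overlapping.
#' @param lesion_multiplier,control_multiplier Solute-fraction
#'   multipliers inside the two ROIs (background uses
#'   `control_multiplier`).
#' @param b0_coef Coefficients `(c0, cx, cy, cxx, cyy, cxy)` of the B0
#'   polynomial in centered, FOV-normalized coordinates, ppm.
#' @param b0_artifact Optional `list(center_mm, sd_mm, amplitude_ppm)`
#'   Gaussian bump emulating a tissue-air susceptibility artifact.
#' @param b0_lesion_offset_ppm Constant B0 offset added inside the
#'   lesion ROI (a QC-gate fixture knob; default 0).
#' @param noise_sd Additive Gaussian noise, as a fraction of M_0.
#' @param m0 Reference image intensity (arbitrary units).
#' @param seed RNG seed; the phantom is a pure function of (spec, seed).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128, 128), fov_mm = c(20, 20),
                         lesion_roi = roi_spec(c(7, 10), side = "LPS"),
                         control_roi = roi_spec(c(13, 10), side = "PBS"),
                         lesion_multiplier = 2,
                         control_multiplier = 1,
                         b0_coef = c(0, 0.04, 0.03, 0.02, -0.02, 0.01),
                         b0_artifact = NULL,
                         b0_lesion_offset_ppm = 0,
                         noise_sd = 0.01, m0 = 1000, seed = 1) {
  stopifnot(noise_sd >= 0, m0 > 0)
  geometry <- default_geometry(grid, fov_mm)
  ma <- roi_mask(lesion_roi, geometry)
  mb <- roi_mask(control_roi, geometry)
  if (any(ma & mb)) stop("lesion and control ROIs overlap")
  structure(list(grid = grid, fov_mm = fov_mm, geometry = geometry,
                 lesion_roi = lesion_roi, control_roi = control_roi,
                 lesion_multiplier = lesion_multiplier,
                 control_multiplier = control_multiplier,
                 b0_coef = b0_coef, b0_artifact = b0_artifact,
                 b0_lesion_offset_ppm = b0_lesion_offset_ppm,
                 noise_sd = noise_sd, m0 = m0, seed = seed),
            class = "phantom_spec")
}

# Per-voxel B0 field (ppm) on the phantom grid.
.phantom_b0_field <- function(spec) {
  g <- spec$grid
  px <- spec$geometry$mm_per_px
  x <- ((seq_len(g[1]) - 0.5) * px[1]) / spec$fov_mm[1] - 0.5
  y <- ((seq_len(g[2]) - 0.5) * px[2]) / spec$fov_mm[2] - 0.5
  X <- matrix(x, g[1], g[2])
  Y <- matrix(y, g[1], g[2], byrow = TRUE)
  cf <- spec$b0_coef
  b0 <- cf[1] + cf[2] * X + cf[3] * Y + cf[4] * X^2 + cf[5] * Y^2 +
    cf[6] * X * Y
  if (!is.null(spec$b0_artifact)) {
    a <- spec$b0_artifact
    xm <- (seq_len(g[1]) - 0.5) * px[1]
    ym <- (seq_len(g[2]) - 0.5) * px[2]
    D2 <- outer((xm - a$center_mm[1])^2, (ym - a$center_mm[2])^2, "+")
    b0 <- b0 + a$amplitude_ppm * exp(-D2 / (2 * a$sd_mm^2))
  }
  if (spec$b0_lesion_offset_ppm != 0)
    b0[roi_mask(spec$lesion_roi, spec$geometry)] <-
      b0[roi_mask(spec$lesion_roi, spec$geometry)] +
      spec$b0_lesion_offset_ppm
  b0
}

# Per-voxel solute-fraction multiplier map.
.phantom_fraction_map <- function(spec) {
  m <- matrix(spec$control_multiplier, spec$grid[1], spec$grid[2])
  m[roi_mask(spec$lesion_roi, spec$geometry)] <- spec$lesion_multiplier
  m[roi_mask(spec$control_roi, spec$geometry)] <- spec$control_multiplier
  m
}

# Scale the first non-water pool's fraction by `mult` (drop it at 0).
.modulate_pools <- function(pools, mult) {
  if (length(pools) < 2 || mult == 1) return(pools)
  if (mult == 0) return(pools[-2])
  p <- pools[[2]]
  pools[[2]] <- pool(p$name, p$t1, p$t2, p$shift, p$fraction * mult,
                     p$k_exchange)
  pools
}

# One stack: per voxel, the dense simulated spectrum of its fraction
# multiplier evaluated at (offset - b0), scaled by M0, plus noise.
.render_stack <- function(spec, pools, pulse, offsets, context, mode,
                          dense_step, b0, fmap) {
  pad <- max(abs(b0)) + 5 * dense_step
  dense <- seq(min(offsets) - pad, max(offsets) + pad, by = dense_step)
  g <- spec$grid
  vols <- array(NA_real_, c(g, length(offsets)))
  for (u in unique(as.vector(fmap))) {
    zs <- simulate_zspectrum(.modulate_pools(pools, u), pulse, dense,
                             context, mode)
    f <- stats::splinefun(zs$offsets, zs$values, method = "natural")
    sel <- fmap == u
    for (k in seq_along(offsets))
      vols[, , k][sel] <- f(offsets[k] - b0[sel])
  }
  vols <- vols * spec$m0
  ref <- matrix(spec$m0, g[1], g[2])
  if (spec$noise_sd > 0) {
    sd_abs <- spec$noise_sd * spec$m0
    vols <- vols + array(stats::rnorm(length(vols), 0, sd_abs), dim(vols))
    ref <- ref + matrix(stats::rnorm(length(ref), 0, sd_abs), g[1], g[2])
  }
  cest_stack(vols, offsets, ref, spec$geometry)
}

#' Generate a synthetic CEST + WASSR phantom with known ground truth
#'
#' Renders the CEST and WASSR image stacks of a two-compartment phantom:
#' every voxel's z-values are Bloch-McConnell simulations with that
#' voxel's solute-fraction multiplier, evaluated at offsets shifted by
#' the voxel's B0 field, scaled by the reference intensity, with
#' additive Gaussian noise. The returned ground truth is sufficient to
#' score every downstream stage.
#'
#' @param spec A [phantom_spec()].
#' @param pools Pool system, water first; the second pool is the
#'   modulated solute.
#' @param pulse CEST presaturation pulse.
#' @param wassr_pulse WASSR prepulse.
#' @param context A [scanner_context()].
#' @param cest_offsets,wassr_offsets Offset schedules, ppm.
#' @param mode Simulation mode (see [simulate_zspectrum()]).
#' @param delta Offset (ppm) at which the ground-truth asymmetry
#'   difference is recorded.
#' @return List with `cest` and `wassr` (raw [cest_stack()]s) and
#'   `truth`: fraction map, B0 field, ROIs, noiseless per-compartment
#'   z-values and the true lesion-control asymmetry difference at
#'   `delta`.
#' @export
make_cest_phantom <- function(spec, pools = default_pools(),
                              pulse = saturation_pulse(0.9, 1.6),
                              wassr_pulse = saturation_pulse(0.1, 0.5),
                              context = scanner_context(),
                              cest_offsets = default_cest_offsets(),
                              wassr_offsets = default_wassr_offsets(),
                              mode = "time_evolved", delta = 0.6) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(pools) < 2) stop("pools must include a solute pool")
  b0 <- .phantom_b0_field(spec)
  fmap <- .phantom_fraction_map(spec)
  out <- .with_seed(spec$seed, {
    cest <- .render_stack(spec, pools, pulse, cest_offsets, context,
                          mode, 0.01, b0, fmap)
    wassr <- .render_stack(spec, pools, wassr_pulse, wassr_offsets,
                           context, mode, 0.005, b0, fmap)
    list(cest = cest, wassr = wassr)
  })
  # noiseless, on-resonance truth per compartment
  asym_of <- function(mult) {
    z <- simulate_zspectrum(.modulate_pools(pools, mult), pulse,
                            c(-delta, delta), context, mode)
    100 * (z$values[1] - z$values[2])
  }
  lesion_asym <- asym_of(spec$lesion_multiplier)
  control_asym <- asym_of(spec$control_multiplier)
  out$truth <- list(
    fraction_map = fmap, b0_field = b0,
    lesion_roi = spec$lesion_roi, control_roi = spec$control_roi,
    delta = delta, lesion_asym_pct = lesion_asym,
    control_asym_pct = control_asym,
    roi_asym_difference_pct = lesion_asym - control_asym,
    seed = spec$seed)
  out
}

#' Specification of a synthetic Iba-1 histology slide
#'
#' Dark elliptical somata with thin processes on a smoothly varying
#' bright background. All geometry is drawn in micrometer units before
#' rasterization, so the same seed yields the same physical slide at any
#' pixel size.
#'
#' @param size_px Image size, pixels (length 2).
#' @param pixel_size_um Pixel edge, micrometers (0.46 emulates a 20x
#'   slide scan).
#' @param n_somata Number of somata.
#' @param soma_area_mean,soma_area_sd Soma area distribution, um^2.
#' @param process_density Processes per soma (thin distractor lines the
#'   segmenter must reject).
#' @param background Background intensity (0-1 scale).
#' @param gradient_amplitude Amplitude of the uneven-staining background
#'   gradient.
#' @param soma_contrast,process_contrast Fractional darkening of soma /
#'   process pixels relative to the local background.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param seed RNG seed.
#' @return Object of class `slide_spec`.
#' @export
slide_spec <- function(size_px = c(512, 512), pixel_size_um = 0.46,
                       n_somata = 50, soma_area_mean = 40,
                       soma_area_sd = 8, process_density = 2,
                       background = 0.75, gradient_amplitude = 0.15,
                       soma_contrast = 0.55, process_contrast = 0.35,
                       noise_sd = 0.01, seed = 1) {
  stopifnot(pixel_size_um > 0, n_somata >= 0, soma_area_mean > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "slide_spec")
}

#' Render a synthetic histology slide with known soma areas
#'
#' @param spec A [slide_spec()].
#' @return List with `image` (matrix in [0, 1], dark = stained),
#'   `truth` (`data.frame(id, cx_um, cy_um, area_um2)` with rasterized
#'   areas) and `spec`.
#' @export
make_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  .with_seed(spec$seed, .render_slide(spec))
}

.render_slide <- function(spec) {
  npx <- spec$size_px
  psz <- spec$pixel_size_um
  W <- npx[1] * psz
  H <- npx[2] * psz
  xs <- (seq_len(npx[1]) - 0.5) * psz
  ys <- (seq_len(npx[2]) - 0.5) * psz
  # uneven staining background
  gx <- matrix((xs / W) - 0.5, npx[1], npx[2])
  gy <- matrix((ys / H) - 0.5, npx[1], npx[2], byrow = TRUE)
  bg <- spec$background * (1 + spec$gradient_amplitude *
                             (2 * gx + 0.8 * gy^2 - 0.4 * gy))
  img <- bg
  n <- spec$n_somata
  truth <- data.frame(id = integer(0), cx_um = numeric(0),
                      cy_um = numeric(0), area_um2 = numeric(0))
  if (n > 0) {
    areas <- stats::rnorm(n, spec$soma_area_mean, spec$soma_area_sd)
    areas <- pmax(areas, 0.3 * spec$soma_area_mean)
    ratio <- stats::runif(n, 0.6, 1)        # minor/major axis
    amaj <- sqrt(areas / (pi * ratio))      # um
    theta <- stats::runif(n, 0, pi)
    rmax <- max(amaj)
    margin <- rmax + 2
    # non-overlapping centers by rejection sampling
    cx <- numeric(0); cy <- numeric(0)
    tries <- 0
    while (length(cx) < n && tries < 20000) {
      tries <- tries + 1
      px <- stats::runif(1, margin, W - margin)
      py <- stats::runif(1, margin, H - margin)
      if (!length(cx) || all((px - cx)^2 + (py - cy)^2 >
                             (2 * rmax + 3)^2)) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
    }
    if (length(cx) < n)
      stop("could not place all somata; reduce n_somata or areas")
    raster_area <- numeric(n)
    for (i in seq_len(n)) {
      bmin <- amaj[i] * ratio[i]
      # bounding box in pixel indices
      r <- amaj[i] + psz
      i0 <- max(1L, floor((cx[i] - r) / psz)); i1 <- min(npx[1], ceiling((cx[i] + r) / psz))
      j0 <- max(1L, floor((cy[i] - r) / psz)); j1 <- min(npx[2], ceiling((cy[i] + r) / psz))
      bx <- xs[i0:i1] - cx[i]
      by <- ys[j0:j1] - cy[i]
      XR <- outer(bx, by, function(x, y) x * cos(theta[i]) + y * sin(theta[i]))
      YR <- outer(bx, by, function(x, y) -x * sin(theta[i]) + y * cos(theta[i]))
      inside <- (XR / amaj[i])^2 + (YR / bmin)^2 <= 1
      sub <- img[i0:i1, j0:j1]
      sub[inside] <- bg[i0:i1, j0:j1][inside] * (1 - spec$soma_contrast)
      img[i0:i1, j0:j1] <- sub
      raster_area[i] <- sum(inside) * psz^2
      # processes: thin radial lines starting at the soma edge
      for (q in seq_len(spec$process_density)) {
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 8, 18)
        r0 <- amaj[i] + 0.5
        tpts <- seq(0, len, by = psz / 2)
        pxs <- cx[i] + (r0 + tpts) * cos(ang)
        pys <- cy[i] + (r0 + tpts) * sin(ang)
        ii <- round(pxs / psz + 0.5); jj <- round(pys / psz + 0.5)
        ok <- ii >= 1 & ii <= npx[1] & jj >= 1 & jj <= npx[2]
        idx <- cbind(ii[ok], jj[ok])
        img[idx] <- bg[idx] * (1 - spec$process_contrast)
      }
    }
    truth <- data.frame(id = seq_len(n), cx_um = cx, cy_um = cy,
                        area_um2 = raster_area)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                        npx[1], npx[2])
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, truth = truth, spec = spec)
}

#' Generate an LCModel-style metabolite concentration table
#'
#' Two spectra (LPS side, vehicle/PBS side) per subject, one row per
#' metabolite per spectrum: fitted concentration, Cramer-Rao %SD and the
#' spectrum linewidth. Baselines are chosen so that the vehicle-side
#' mI/tCr ratio is about 0.70 and the default LPS-side myoinositol
#' effect of +17% raises it to about 0.82. Rows violating the quality
#' gates can be injected to exercise the filters.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param effect Relative myoinositol increase on the LPS side.
#' @param crlb_sd Multiplicative (log-normal) concentration noise, the
#'   fitted-concentration uncertainty the %SD column reports.
#' @param seed RNG seed.
#' @param n_bad_linewidth Number of spectra given linewidth > 25 Hz.
#' @param n_bad_crlb Number of non-creatine metabolite rows given
#'   %SD in 12-15.
#' @param subject_sd Between-subject log-normal scale spread.
#' @return `data.frame(subject, side, metabolite, concentration,
#'   sd_percent, linewidth_hz)`.
#' @export
make_metabolite_table <- function(n_subjects = 6, effect = 0.17,
                                  crlb_sd = 0.05, seed = 1,
                                  n_bad_linewidth = 0, n_bad_crlb = 0,
                                  subject_sd = 0.08) {
  stopifnot(n_subjects >= 1)
  base <- c(mI = 5.6, Cr = 4.8, PCr = 3.2, Glu = 8.0, Gln = 3.0,
            NAA = 8.2, Tau = 9.0)
  .with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      subj_scale <- exp(stats::rnorm(1, 0, subject_sd))
      for (side in c("LPS", "PBS")) {
        conc <- base * subj_scale
        if (side == "LPS") conc["mI"] <- conc["mI"] * (1 + effect)
        conc <- conc * exp(stats::rnorm(length(conc), 0, crlb_sd))
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, side = side, metabolite = names(base),
          concentration = unname(conc),
          sd_percent = pmax(1, stats::rnorm(length(base), 5, 1.5)),
          linewidth_hz = stats::rnorm(1, 12.9, 0.8))
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (n_bad_linewidth > 0) {
      spectra <- unique(tab[, c("subject", "side")])
      pick <- spectra[sample.int(nrow(spectra),
                                 min(n_bad_linewidth, nrow(spectra))), ]
      for (r in seq_len(nrow(pick))) {
        sel <- tab$subject == pick$subject[r] & tab$side == pick$side[r]
        tab$linewidth_hz[sel] <- stats::runif(1, 26, 30)
      }
    }
    if (n_bad_crlb > 0) {
      cand <- which(!tab$metabolite %in% c("Cr", "PCr"))
      pick <- sample(cand, min(n_bad_crlb, length(cand)))
      tab$sd_percent[pick] <- stats::runif(length(pick), 12, 15)
    }
    tab
  })
}
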