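# Thin readers/writers for the pipeline's on-disk formats: NIfTI image
# stacks with a CSV offsets sidecar, TIFF slides, CSV metabolite tables,
# YAML configuration and JSON QC reports.

#' Write a CEST/WASSR stack as NIfTI plus an offsets sidecar
#'
#' Writes `<prefix>.nii.gz` (4D: x, y, 1 slice, offset),
#' `<prefix>_ref.nii.gz` (the reference image) and `<prefix>_offsets.csv`
#' (columns `index`, `offset_ppm`).
#'
#' @param stack A [cest_stack()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cest_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "cest_stack"))
  d <- dim(stack$volumes)
  vol4 <- array(stack$volumes, c(d[1], d[2], 1, d[3]))
  pix <- c(stack$geometry$mm_per_px, stack$geometry$slice_thickness_mm)
  RNifti::writeNifti(RNifti::asNifti(vol4, pixdim = pix),
                     paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(stack$reference, pixdim = pix[1:2]),
                     paste0(prefix, "_ref.nii.gz"))
  utils::write.csv(data.frame(index = seq_along(stack$offsets),
                              offset_ppm = stack$offsets),
                   paste0(prefix, "_offsets.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a CEST/WASSR stack written by [write_cest_stack()]
#'
#' @param prefix Path prefix used when writing.
#' @param geometry Acquisition geometry; defaults to the grid found on
#'   disk with the default FOV.
#' @return A [cest_stack()].
#' @export
read_cest_stack <- function(prefix, geometry = NULL) {
  vol4 <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  ref <- as.array(RNifti::readNifti(paste0(prefix, "_ref.nii.gz")))
  offs <- utils::read.csv(paste0(prefix, "_offsets.csv"))$offset_ppm
  d <- dim(vol4)
  vols <- array(vol4, c(d[1], d[2], d[length(d)]))
  if (is.null(geometry)) geometry <- default_geometry(d[1:2])
  cest_stack(vols, offs, matrix(ref, d[1], d[2]), geometry)
}

#' Write a B0 map (shift + validity mask) as NIfTI
#'
#' @param b0 A `b0_map`.
#' @param prefix Output path prefix; writes `<prefix>_b0ppm.nii.gz` and
#'   `<prefix>_valid.nii.gz`.
#' @export
write_b0_map <- function(b0, prefix) {
  RNifti::writeNifti(RNifti::asNifti(ifelse(b0$valid, b0$shift, NA_real_)),
                     paste0(prefix, "_b0ppm.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(b0$valid * 1),
                     paste0(prefix, "_valid.nii.gz"))
  invisible(prefix)
}

#' Write / read a slide image as 16-bit grayscale TIFF
#'
#' @param image Matrix with values in [0, 1].
#' @param path Output file.
#' @export
write_slide_tiff <- function(image, path) {
  tiff::writeTIFF(t(image), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_slide_tiff
#' @export
read_slide_tiff <- function(path) {
  t(tiff::readTIFF(path))
}

#' Read an LCModel-style metabolite table from CSV
#'
#' Validates the column contract expected by [mrs_qc_and_ratio()].
#'
#' @param path CSV with columns subject, side, metabolite,
#'   concentration, sd_percent, linewidth_hz.
#' @export
read_metabolite_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "side", "metabolite", "concentration",
            "sd_percent", "linewidth_hz")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metabolite table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' Read a YAML study configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_study_config <- function(path) yaml::read_yaml(path)

#' Read pools, pulses and scanner from a YAML configuration
#'
#' Parses a configuration of the shape shipped in
#' `system.file("extdata", "example_pools.yaml", package = "cestpipe")`:
#' a `pools` list (water first), optional `pulses` (each with `b1`, µT,
#' and `duration`, s) and optional `scanner` (`field_strength`,
#' `gamma_bar`).
#'
#' @param path YAML file.
#' @return List with `pools`, `pulses` (named list of
#'   [saturation_pulse()]) and `context` ([scanner_context()]).
#' @export
read_pools_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pools)) stop("configuration has no 'pools' section")
  pools <- lapply(cfg$pools, function(p)
    pool(p$name, p$t1, p$t2, shift = p$shift %||% 0,
         fraction = p$fraction %||% 1,
         k_exchange = p$k_exchange %||% 0))
  pulses <- lapply(cfg$pulses, function(p)
    saturation_pulse(p$b1, p$duration))
  context <- if (is.null(cfg$scanner)) scanner_context() else
    scanner_context(cfg$scanner$field_strength %||% 9.4,
                    cfg$scanner$gamma_bar %||% 42.577)
  list(pools = pools, pulses = pulses, context = context)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QC report (or any result list) as JSON
#'
#' @param x List to serialize.
#' @param path Output file.
#' @export
write_qc_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
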