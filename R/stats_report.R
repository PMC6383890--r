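# ROI outcome extraction, MRS QC, paired statistics and the study
# driver.

#' Mean map value over an ROI
#'
#' Average of the valid (non-NA) voxels of a parameter map inside the
#' ROI's pixel window; the study's ROI outcome ("average contrast").
#'
#' @param map Numeric matrix (NA = invalid voxel).
#' @param roi An [roi_spec()].
#' @param geometry See [default_geometry()].
#' @param stat `"mean"` (default) or `"median"`.
#' @return List with `value` (NA when no valid voxel), `n_valid` and
#'   `reason`.
#' @export
roi_mean <- function(map, roi, geometry = default_geometry(),
                     stat = c("mean", "median")) {
  stat <- match.arg(stat)
  w <- roi_pixels(roi, geometry)
  v <- map[w$ix, w$iy]
  v <- v[is.finite(v)]
  if (!length(v))
    return(list(value = NA_real_, n_valid = 0L, reason = "no_valid_voxels"))
  list(value = if (stat == "mean") mean(v) else stats::median(v),
       n_valid = length(v), reason = "ok")
}

#' Apply MRS quality gates and creatine normalization
#'
#' Spectra whose linewidth exceeds `linewidth_max` are excluded whole;
#' metabolites whose Cramer-Rao %SD is not below `crlb_max` are excluded
#' individually. For surviving spectra, concentrations are expressed as
#' the ratio to total creatine (creatine + phosphocreatine); if either
#' creatine row failed QC the spectrum's ratios are unavailable.
#'
#' @param table `data.frame(subject, side, metabolite, concentration,
#'   sd_percent, linewidth_hz)`, e.g. from [make_metabolite_table()].
#' @param crlb_max Cramer-Rao %SD bound (metabolites kept when
#'   `sd_percent < crlb_max`).
#' @param linewidth_max Maximum spectrum linewidth, Hz.
#' @return List with `ratios` (`data.frame(subject, side, metabolite,
#'   ratio)`) and `exclusions` (`data.frame(subject, side, metabolite,
#'   reason)`; `metabolite` NA when the whole spectrum was dropped).
#' @export
mrs_qc_and_ratio <- function(table, crlb_max = 10, linewidth_max = 25) {
  need <- c("subject", "side", "metabolite", "concentration",
            "sd_percent", "linewidth_hz")
  if (!all(need %in% names(table)))
    stop("table lacks required columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (!all(c("Cr", "PCr") %in% table$metabolite))
    stop("creatine rows (Cr, PCr) missing: total creatine undefined")
  ratios <- list()
  excl <- list()
  note <- function(subj, side, met, reason)
    data.frame(subject = subj, side = side, metabolite = met,
               reason = reason)
  for (key in split(table, ~ subject + side, drop = TRUE)) {
    subj <- key$subject[1]; side <- key$side[1]
    if (key$linewidth_hz[1] > linewidth_max) {
      excl[[length(excl) + 1]] <-
        note(subj, side, NA_character_, "linewidth")
      next
    }
    pass <- key$sd_percent < crlb_max
    for (m in key$metabolite[!pass])
      excl[[length(excl) + 1]] <- note(subj, side, m, "crlb")
    ok <- key[pass, ]
    if (!all(c("Cr", "PCr") %in% ok$metabolite)) {
      excl[[length(excl) + 1]] <-
        note(subj, side, NA_character_, "tcr_unavailable")
      next
    }
    tcr <- sum(ok$concentration[ok$metabolite %in% c("Cr", "PCr")])
    rest <- ok[!ok$metabolite %in% c("Cr", "PCr"), ]
    if (nrow(rest))
      ratios[[length(ratios) + 1]] <-
        data.frame(subject = subj, side = side,
                   metabolite = rest$metabolite,
                   ratio = rest$concentration / tcr)
  }
  empty_r <- data.frame(subject = integer(0), side = character(0),
                        metabolite = character(0), ratio = numeric(0))
  empty_e <- data.frame(subject = integer(0), side = character(0),
                        metabolite = character(0), reason = character(0))
  r <- if (length(ratios)) do.call(rbind, ratios) else empty_r
  e <- if (length(excl)) do.call(rbind, excl) else empty_e
  rownames(r) <- rownames(e) <- NULL
  list(ratios = r, exclusions = e)
}

#' Paired LPS-vs-PBS outcome table
#'
#' @param subject Subject identifiers.
#' @param lps,pbs Outcome values per subject (complete pairs).
#' @param measure Label, e.g. `"MTR_asym %"`.
#' @return `data.frame` of class `paired_outcome`.
#' @export
paired_outcome <- function(subject, lps, pbs, measure = "outcome") {
  stopifnot(length(subject) == length(lps), length(lps) == length(pbs))
  keep <- is.finite(lps) & is.finite(pbs)
  out <- data.frame(subject = subject[keep], lps = lps[keep],
                    pbs = pbs[keep])
  attr(out, "measure") <- measure
  class(out) <- c("paired_outcome", "data.frame")
  out
}

.iqr2 <- function(x) unname(stats::quantile(x, c(0.25, 0.75), type = 7))

#' Paired group comparison (t-test and Wilcoxon)
#'
#' Reports per-side medians and interquartile ranges (25th-75th
#' percentile, linear interpolation) and compares the sides with a
#' paired t-test and the Wilcoxon signed-rank test on the paired
#' differences (the paired-design nonparametric analogue); the two-
#' sample Wilcoxon rank-sum statistic on the sides is also reported as a
#' secondary output. With fewer than 3 pairs only descriptives are
#' returned. Degenerate inputs (all differences equal) leave the
#' affected p-value NA.
#'
#' @param outcome A [paired_outcome()].
#' @return List with `measure`, `n`, `median_lps`, `iqr_lps`,
#'   `median_pbs`, `iqr_pbs`, `median_diff`, `iqr_diff`, `t_p`,
#'   `wilcoxon_signed_p`, `wilcoxon_ranksum_p`, `tests_computed`.
#' @export
paired_compare <- function(outcome) {
  stopifnot(inherits(outcome, "paired_outcome"))
  n <- nrow(outcome)
  d <- outcome$lps - outcome$pbs
  res <- list(measure = attr(outcome, "measure"), n = n,
              median_lps = stats::median(outcome$lps),
              iqr_lps = .iqr2(outcome$lps),
              median_pbs = stats::median(outcome$pbs),
              iqr_pbs = .iqr2(outcome$pbs),
              median_diff = stats::median(d),
              iqr_diff = .iqr2(d),
              t_p = NA_real_, wilcoxon_signed_p = NA_real_,
              wilcoxon_ranksum_p = NA_real_,
              tests_computed = FALSE)
  if (n < 3) return(res)
  res$t_p <- tryCatch(
    stats::t.test(outcome$lps, outcome$pbs, paired = TRUE)$p.value,
    error = function(e) NA_real_)
  res$wilcoxon_signed_p <- tryCatch(
    suppressWarnings(stats::wilcox.test(outcome$lps, outcome$pbs,
                                        paired = TRUE)$p.value),
    error = function(e) NA_real_)
  res$wilcoxon_ranksum_p <- tryCatch(
    suppressWarnings(stats::wilcox.test(outcome$lps,
                                        outcome$pbs)$p.value),
    error = function(e) NA_real_)
  res$tests_computed <- TRUE
  res
}

#' Convenience Fisher exact test of classification vs genotype
#'
#' Thin wrapper around [stats::fisher.test()] on the 2x2 table of
#' responder class against genotype; provided as a utility only.
#'
#' @param class_labels,genotype Character vectors of equal length.
#' @return The `htest` object.
#' @export
genotype_association_test <- function(class_labels, genotype) {
  stats::fisher.test(table(class_labels, genotype))
}

#' Specification of a synthetic study cohort
#'
#' A cohort of `n_effect` responder subjects (elevated 0.6 ppm solute in
#' the lesion ROI, LPS-side soma enlargement, LPS-side myoinositol
#' increase) and `n_null` non-responders (no injected effect anywhere).
#' Per-subject seeds are derived from the study seed, so the cohort is a
#' pure function of (spec, seed).
#'
#' @param n_effect,n_null Group sizes.
#' @param grid Phantom matrix size.
#' @param noise_sd Phantom noise (fraction of M_0).
#' @param lesion_multiplier_effect Solute-fraction multiplier in the
#'   lesion ROI of effect subjects (null subjects use 1).
#' @param subject_jitter_sd Log-normal between-subject spread of the
#'   compartment multipliers.
#' @param mi_effect Relative LPS-side myoinositol increase in effect
#'   subjects.
#' @param soma_shift_um2 LPS-side soma area increase in effect subjects,
#'   um^2.
#' @param n_slices Histology slices per subject.
#' @param slide_size_px,n_somata,soma_area_mean,soma_area_sd,slide_noise_sd
#'   Slide generator settings (see [slide_spec()]).
#' @param b0_roi_offset Per-subject constant B0 offset added inside the
#'   lesion ROI, ppm (recycled); use e.g. 0.06 over a flat `b0_coef` to
#'   trip the QC gate.
#' @param b0_coef Polynomial B0-field coefficients passed to
#'   [phantom_spec()].
#' @param paired_slides If TRUE (default) the LPS and PBS sides of a
#'   slice share the same soma layout (same seed), emulating the strong
#'   within-slice correlation of the two hemispheres; the effect group's
#'   LPS-side areas are shifted on top of the shared layout. FALSE draws
#'   the sides independently.
#' @param qc_threshold_ppm B0 ROI-difference gate.
#' @param delta Analysis offset, ppm.
#' @param pools,pulse,wassr_pulse,context Simulation settings.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_effect = 6, n_null = 6, grid = c(128, 128),
                        noise_sd = 0.01,
                        lesion_multiplier_effect = 2,
                        subject_jitter_sd = 0.05,
                        mi_effect = 0.17, soma_shift_um2 = 10,
                        n_slices = 3, slide_size_px = c(384, 384),
                        n_somata = 50, soma_area_mean = 40,
                        soma_area_sd = 8, slide_noise_sd = 0.01,
                        b0_roi_offset = 0,
                        b0_coef = c(0, 0.04, 0.03, 0.02, -0.02, 0.01),
                        paired_slides = TRUE, qc_threshold_ppm = 0.05,
                        delta = 0.6, pools = default_pools(),
                        pulse = saturation_pulse(0.9, 1.6),
                        wassr_pulse = saturation_pulse(0.1, 0.5),
                        context = scanner_context()) {
  structure(as.list(environment()), class = "cohort_spec")
}

#' Run the full synthetic study
#'
#' End-to-end driver mirroring the per-animal flow: generate (or, in a
#' real study, load) CEST + WASSR stacks, build the B0 map over the two
#' analysis ROIs, apply the B0 QC gate, compute the B0-corrected MTR
#' asymmetry ROI means, apply MRS QC and creatine normalization, segment
#' the histology slides and compute the soma-size difference, then
#' assemble paired outcome tables and group statistics. Subjects failing
#' a gate are logged and excluded from the affected outcome; the run
#' continues.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Study seed (all per-subject seeds derive from it).
#' @return List of class `study_report`: `status`, `subjects`
#'   (per-subject table), `tests` (per group x measure
#'   [paired_compare()] results), `outcomes` (paired outcome tables),
#'   `exclusions`, `classification` and `boxplot_data` (long-format
#'   `data.frame` ready for plotting).
#' @export
run_study <- function(cohort = cohort_spec(), seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n_tot <- cohort$n_effect + cohort$n_null
  if (n_tot == 0) {
    return(structure(list(status = "no-data",
                          subjects = data.frame(), tests = list(),
                          outcomes = list(),
                          exclusions = data.frame(),
                          classification = data.frame(),
                          boxplot_data = data.frame()),
                     class = "study_report"))
  }
  groups <- rep(c("effect", "null"), c(cohort$n_effect, cohort$n_null))
  b0_off <- rep_len(cohort$b0_roi_offset, n_tot)
  geometry <- default_geometry(cohort$grid)
  lesion <- roi_spec(c(7, 10), side = "LPS")
  control <- roi_spec(c(13, 10), side = "PBS")
  mask <- roi_mask(lesion, geometry) | roi_mask(control, geometry)
  # all component seeds come from one master stream so that no two
  # generator calls share or overlap a seed
  ns <- cohort$n_slices
  draws <- .with_seed(seed, list(
    jit = matrix(exp(stats::rnorm(2 * n_tot, 0, cohort$subject_jitter_sd)),
                 n_tot, 2),
    phantom = sample.int(.Machine$integer.max, n_tot),
    slide_lps = matrix(sample.int(.Machine$integer.max, n_tot * ns),
                       n_tot, ns),
    slide_pbs_indep = matrix(sample.int(.Machine$integer.max, n_tot * ns),
                             n_tot, ns),
    metab = sample.int(.Machine$integer.max, 2)))
  draws$slide_pbs <- if (isTRUE(cohort$paired_slides)) draws$slide_lps
                     else draws$slide_pbs_indep
  # one metabolite table per group (a single RNG stream each)
  mrs <- list()
  for (g in c("effect", "null")) {
    n_g <- sum(groups == g)
    if (n_g == 0) next
    tab <- make_metabolite_table(
      n_subjects = n_g,
      effect = if (g == "effect") cohort$mi_effect else 0,
      seed = draws$metab[if (g == "effect") 1 else 2])
    tab$subject <- which(groups == g)[tab$subject]  # cohort numbering
    mrs[[g]] <- mrs_qc_and_ratio(tab)
  }
  rows <- list()
  excl <- list()
  for (i in seq_len(n_tot)) {
    grp <- groups[i]
    jit <- draws$jit[i, ]
    lm <- jit[1] * if (grp == "effect") cohort$lesion_multiplier_effect else 1
    cm <- jit[2]
    spec <- phantom_spec(grid = cohort$grid, lesion_roi = lesion,
                         control_roi = control,
                         lesion_multiplier = lm, control_multiplier = cm,
                         b0_coef = cohort$b0_coef,
                         b0_lesion_offset_ppm = b0_off[i],
                         noise_sd = cohort$noise_sd,
                         seed = draws$phantom[i])
    ph <- make_cest_phantom(spec, pools = cohort$pools,
                            pulse = cohort$pulse,
                            wassr_pulse = cohort$wassr_pulse,
                            context = cohort$context,
                            delta = cohort$delta)
    wn <- normalize_stack(ph$wassr, intensity_threshold = 0.5 * spec$m0)
    b0 <- build_b0_map(wn$stack, mask & wn$mask)
    qc <- qc_roi_pair(b0, roi_mask(lesion, geometry),
                      roi_mask(control, geometry),
                      threshold = cohort$qc_threshold_ppm)
    lps_asym <- pbs_asym <- NA_real_
    if (qc$pass) {
      cn <- normalize_stack(ph$cest, intensity_threshold = 0.5 * spec$m0)
      am <- mtr_asym_map(cn$stack, b0, delta = cohort$delta,
                         mask = mask & cn$mask)
      lps_asym <- roi_mean(am$map, lesion, geometry)$value
      pbs_asym <- roi_mean(am$map, control, geometry)$value
    } else {
      excl[[length(excl) + 1]] <-
        data.frame(subject = i, stage = "cest",
                   reason = if (qc$reason == "unmeasurable")
                     "b0_unmeasurable" else "b0_gate",
                   detail = sprintf("B0 ROI difference %.3f ppm",
                                    qc$difference))
    }
    # MRS (ratios precomputed per group)
    mi <- mrs[[grp]]$ratios
    mi <- mi[mi$metabolite == "mI" & mi$subject == i, ]
    mi_lps <- if (any(mi$side == "LPS")) mi$ratio[mi$side == "LPS"] else NA_real_
    mi_pbs <- if (any(mi$side == "PBS")) mi$ratio[mi$side == "PBS"] else NA_real_
    me <- mrs[[grp]]$exclusions
    me <- me[me$subject == i, , drop = FALSE]
    if (nrow(me))
      excl[[length(excl) + 1]] <-
        data.frame(subject = i, stage = "mrs", reason = me$reason,
                   detail = ifelse(is.na(me$metabolite), me$side,
                                   paste(me$side, me$metabolite)))
    # histology
    shift <- if (grp == "effect") cohort$soma_shift_um2 else 0
    med_of_slide <- function(mean_area, sl_seed) {
      sl <- make_slide(slide_spec(size_px = cohort$slide_size_px,
                                  n_somata = cohort$n_somata,
                                  soma_area_mean = mean_area,
                                  soma_area_sd = cohort$soma_area_sd,
                                  noise_sd = cohort$slide_noise_sd,
                                  seed = sl_seed))
      seg <- segment_somata(sl$image, sl$spec$pixel_size_um)
      roi_soma_stats(seg)$median_area_um2
    }
    sl_ids <- seq_len(cohort$n_slices)
    lps_med <- vapply(sl_ids, function(s)
      med_of_slide(cohort$soma_area_mean + shift,
                   draws$slide_lps[i, s]), numeric(1))
    pbs_med <- vapply(sl_ids, function(s)
      med_of_slide(cohort$soma_area_mean,
                   draws$slide_pbs[i, s]), numeric(1))
    sd_res <- soma_size_difference(
      data.frame(slice = sl_ids, median_area_um2 = lps_med),
      data.frame(slice = sl_ids, median_area_um2 = pbs_med))
    rows[[i]] <- data.frame(
      subject = i, group = grp, qc_pass = qc$pass,
      b0_roi_diff_ppm = qc$difference,
      lps_asym_pct = lps_asym, pbs_asym_pct = pbs_asym,
      mi_tcr_lps = mi_lps, mi_tcr_pbs = mi_pbs,
      soma_diff_um2 = sd_res$median_diff_um2,
      iba1_class = classify_iba1(sd_res$per_slice$diff_um2))
  }
  subjects <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject = integer(0), stage = character(0),
               reason = character(0), detail = character(0))
  rownames(subjects) <- rownames(exclusions) <- NULL
  measures <- list(
    mtr_asym = c("lps_asym_pct", "pbs_asym_pct", "MTR_asym %"),
    mi_tcr = c("mi_tcr_lps", "mi_tcr_pbs", "mI/tCr"))
  outcomes <- list(); tests <- list()
  for (grp in unique(subjects$group)) {
    gs <- subjects[subjects$group == grp, ]
    for (m in names(measures)) {
      po <- paired_outcome(gs$subject, gs[[measures[[m]][1]]],
                           gs[[measures[[m]][2]]],
                           measure = measures[[m]][3])
      key <- paste(grp, m, sep = ".")
      outcomes[[key]] <- po
      tests[[key]] <- paired_compare(po)
    }
    dpo <- paired_outcome(gs$subject, gs$soma_diff_um2,
                          rep(0, nrow(gs)), measure = "soma diff um^2")
    tests[[paste(grp, "soma_diff", sep = ".")]] <- paired_compare(dpo)
  }
  long <- do.call(rbind, lapply(names(outcomes), function(k) {
    po <- outcomes[[k]]
    if (!nrow(po)) return(NULL)
    data.frame(group = sub("\\..*", "", k),
               measure = attr(po, "measure"),
               subject = rep(po$subject, 2),
               side = rep(c("LPS", "PBS"), each = nrow(po)),
               value = c(po$lps, po$pbs))
  }))
  structure(list(status = "ok", subjects = subjects, tests = tests,
                 outcomes = outcomes, exclusions = exclusions,
                 classification = subjects[, c("subject", "group",
                                               "iba1_class")],
                 boxplot_data = long),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> status=%s, %d subjects, %d exclusions\n",
              x$status, nrow(x$subjects), nrow(x$exclusions)))
  for (k in names(x$tests)) {
    t <- x$tests[[k]]
    cat(sprintf("  %-18s n=%d median LPS %.3g PBS %.3g  t p=%.3g  W p=%.3g\n",
                k, t$n, t$median_lps, t$median_pbs, t$t_p,
                t$wilcoxon_signed_p))
  }
  invisible(x)
}
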