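test_that("ROI mean aggregates valid voxels only", {
  g <- default_geometry()   # 20 mm / 128 px
  m <- matrix(5, 128, 128)
  roi <- roi_spec(c(7, 10))
  w <- roi_pixels(roi, g)
  # a 1.25 mm ROI is exactly 8 x 8 pixels at this geometry
  expect_equal(c(length(w$ix), length(w$iy)), c(8L, 8L))
  expect_equal(roi_mean(m, roi, g)$value, 5)
  # half the window invalid: mean over the valid half
  m2 <- m
  m2[w$ix[1:4], w$iy] <- NA
  m2[w$ix[5:8], w$iy] <- 3
  r <- roi_mean(m2, roi, g)
  expect_equal(r$value, 3)
  expect_equal(r$n_valid, 32L)
  m3 <- m; m3[w$ix, w$iy] <- NA
  r3 <- roi_mean(m3, roi, g)
  expect_true(is.na(r3$value))
  expect_identical(r3$reason, "no_valid_voxels")
})

test_that("MRS QC removes failing rows and normalizes to total creatine", {
  tab <- data.frame(
    subject = 1, side = rep(c("LPS", "PBS"), each = 4),
    metabolite = rep(c("mI", "Cr", "PCr", "Glu"), 2),
    concentration = c(8.2, 6.0, 4.0, 9.0, 7.0, 6.0, 4.0, 9.0),
    sd_percent = c(5, 5, 5, 5, 12, 5, 5, 5),
    linewidth_hz = rep(c(13, 13), each = 4))
  q <- mrs_qc_and_ratio(tab)
  lps <- q$ratios[q$ratios$side == "LPS", ]
  expect_equal(lps$ratio[lps$metabolite == "mI"], 0.82)
  # PBS mI fails CRLB at 12%: mI missing, Glu kept
  pbs <- q$ratios[q$ratios$side == "PBS", ]
  expect_false("mI" %in% pbs$metabolite)
  expect_true("Glu" %in% pbs$metabolite)
  expect_true(any(q$exclusions$reason == "crlb"))
  # linewidth 26 Hz drops the whole spectrum
  tab2 <- tab
  tab2$linewidth_hz[tab2$side == "LPS"] <- 26
  q2 <- mrs_qc_and_ratio(tab2)
  expect_false("LPS" %in% q2$ratios$side)
  expect_true(any(q2$exclusions$reason == "linewidth"))
  # boundary: exactly 25 Hz is acceptable, %SD exactly 10 is not
  tab3 <- tab
  tab3$linewidth_hz <- 25
  tab3$sd_percent[1] <- 10
  q3 <- mrs_qc_and_ratio(tab3)
  expect_true("PBS" %in% q3$ratios$side)
  expect_false("mI" %in% q3$ratios$metabolite[q3$ratios$side == "LPS"])
  # losing a creatine row makes the spectrum's ratios unavailable
  tab4 <- tab
  tab4$sd_percent[tab4$metabolite == "Cr" & tab4$side == "LPS"] <- 15
  q4 <- mrs_qc_and_ratio(tab4)
  expect_false("LPS" %in% q4$ratios$side)
  expect_true(any(q4$exclusions$reason == "tcr_unavailable"))
  expect_error(mrs_qc_and_ratio(tab[tab$metabolite != "Cr", ]), "creatine")
})

test_that("paired comparison reports the study's statistics", {
  po <- paired_outcome(1:6, c(10.8, 10.6, 9.9, 11.4, 10.0, 9.6),
                       c(5.3, 5.5, 5.1, 5.4, 4.7, 5.6), "MTR_asym %")
  r <- paired_compare(po)
  expect_equal(r$n, 6)
  expect_equal(r$median_lps, median(po$lps))
  expect_equal(r$iqr_lps, unname(quantile(po$lps, c(0.25, 0.75))))
  expect_lt(r$t_p, 0.001)
  expect_equal(r$wilcoxon_signed_p, 0.03125, tolerance = 1e-6)
  # sign flip: identical p-values, opposite effect
  flip <- paired_outcome(1:6, po$pbs, po$lps, "flipped")
  rf <- paired_compare(flip)
  expect_equal(rf$t_p, r$t_p)
  expect_equal(rf$wilcoxon_signed_p, r$wilcoxon_signed_p)
  expect_equal(rf$median_diff, -r$median_diff)
  # permutation invariance in subject order
  perm <- paired_outcome(6:1, rev(po$lps), rev(po$pbs), "perm")
  rp <- paired_compare(perm)
  expect_equal(rp$t_p, r$t_p)
  expect_equal(rp$median_lps, r$median_lps)
  # degenerate and small inputs
  zero <- paired_outcome(1:4, rep(1, 4), rep(1, 4))
  rz <- paired_compare(zero)
  expect_equal(rz$median_diff, 0)
  expect_true(is.na(rz$t_p) || rz$t_p > 0.99)
  small <- paired_compare(paired_outcome(1:2, c(1, 2), c(0, 1)))
  expect_false(small$tests_computed)
  expect_true(is.na(small$t_p))
})

test_that("paired t power on the design effect matches the analytic value", {
  n <- 6; delta <- 2.5; sdd <- 1.0
  set.seed(21)
  rej <- mean(replicate(500, {
    d <- rnorm(n, delta, sdd)
    po <- paired_outcome(1:n, d, rep(0, n))
    paired_compare(po)$t_p < 0.05
  }))
  analytic <- stats::power.t.test(n = n, delta = delta, sd = sdd,
                                  type = "paired")$power
  expect_gte(rej, 0.6)
  expect_lt(abs(rej - analytic), 0.1)
})

test_that("study driver assembles outcomes, gates and classification", {
  rep <- run_study(cohort_spec(n_effect = 2, n_null = 2, grid = c(32, 32),
                               n_slices = 2, slide_size_px = c(256, 256),
                               n_somata = 25), seed = 4)
  expect_identical(rep$status, "ok")
  expect_equal(nrow(rep$subjects), 4)
  eff <- rep$subjects[rep$subjects$group == "effect", ]
  nul <- rep$subjects[rep$subjects$group == "null", ]
  expect_true(all(eff$lps_asym_pct > eff$pbs_asym_pct))
  expect_true(all(eff$soma_diff_um2 > 5))
  expect_true(all(abs(nul$soma_diff_um2) < 2))
  expect_identical(eff$iba1_class, rep("Iba1+", 2))
  expect_true(all(c("effect.mtr_asym", "null.mi_tcr") %in% names(rep$tests)))
  expect_gt(nrow(rep$boxplot_data), 0)
  # B0 gate: the offending subject is excluded from CEST, run continues
  rep2 <- run_study(cohort_spec(n_effect = 2, n_null = 0, grid = c(32, 32),
                                n_slices = 1, slide_size_px = c(256, 256),
                                n_somata = 25, b0_coef = rep(0, 6),
                                b0_roi_offset = c(0.06, 0)), seed = 4)
  expect_true(any(rep2$exclusions$reason == "b0_gate" &
                    rep2$exclusions$subject == 1))
  expect_true(is.na(rep2$subjects$lps_asym_pct[1]))
  expect_false(is.na(rep2$subjects$lps_asym_pct[2]))
  # empty cohort: a no-data report, not an error
  expect_identical(run_study(cohort_spec(n_effect = 0, n_null = 0))$status,
                   "no-data")
})

test_that("genotype association wrapper returns a Fisher test", {
  cls <- rep(c("Iba1+", "Iba1-"), each = 6)
  gt <- rep(c("WT", "APP/PS1"), 6)
  r <- genotype_association_test(cls, gt)
  expect_s3_class(r, "htest")
  expect_gt(r$p.value, 0.05)
})
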