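ctx <- scanner_context()
water <- list(pool("water", 1.8, 0.04))

test_that("closed-form CW oracle obeys its algebraic identities", {
  offs <- c(-400, -10, 0, 10, 400)
  expect_equal(sapply(offs, function(o) single_pool_cw_oracle(1.8, 0.04, 0, o)),
               rep(1, 5))
  # far off resonance saturation vanishes
  expect_gt(single_pool_cw_oracle(1.8, 0.04, 0.9, 1e6), 0.999999)
  # omega1^2 T1 T2 = 1 at resonance halves the signal
  b1_unit <- 1 / (2 * pi * 42.577)
  expect_equal(single_pool_cw_oracle(1, 1, b1_unit, 0), 0.5)
  expect_error(single_pool_cw_oracle(-1, 0.04, 0.9, 0), "t1")
})

test_that("unsaturated and zero-solute systems reduce to known limits", {
  offs <- seq(-4, 4, 0.2)
  z0 <- simulate_zspectrum(water, saturation_pulse(0, 1.6), offs, ctx)
  expect_equal(z0$values, rep(1, length(offs)), tolerance = 1e-12)
  # two-pool with vanishing solute fraction == single-pool oracle
  pools2 <- list(pool("water", 1.8, 0.04),
                 pool("hydroxyl", 1.0, 0.015, 0.6, 1e-15, 600))
  zss <- simulate_zspectrum(pools2, saturation_pulse(0.9, 1.6), offs, ctx,
                            mode = "steady_state")
  oracle <- sapply(offs, function(o)
    single_pool_cw_oracle(1.8, 0.04, 0.9, o * ctx$hz_per_ppm))
  expect_lt(max(abs(zss$values - oracle) / oracle), 1e-6)
})

test_that("time-evolved propagator matches brute-force RK4 integration", {
  pools <- list(pool("water", 1.8, 0.04),
                pool("hydroxyl", 1.0, 0.015, 0.6, 0.002, 600))
  pulse <- saturation_pulse(0.9, 1.6)
  z <- simulate_zspectrum(pools, pulse, c(-0.6, 0.6), ctx)
  for (i in 1:2) {
    ref <- rk4_zvalue(pools, 0.9, 1.6, c(-0.6, 0.6)[i])
    expect_equal(z$values[i], ref, tolerance = 1e-6)
  }
  # exchange from a +0.6 ppm pool depresses the label side
  expect_lt(z$values[2], z$values[1])
})

test_that("steady-state and time-evolved modes agree for long pulses", {
  pools <- default_pools()
  offs <- seq(-2, 2, 0.5)
  zt <- simulate_zspectrum(pools, saturation_pulse(0.9, 5 * 1.8), offs, ctx)
  zs <- simulate_zspectrum(pools, saturation_pulse(0.9, 1), offs, ctx,
                           mode = "steady_state")
  expect_lt(max(abs(zt$values - zs$values)), 1e-3)
})

test_that("mirror-symmetric pool systems give an even z-spectrum", {
  offs <- seq(-4, 4, 0.2)
  for (mode in c("time_evolved", "steady_state")) {
    z <- simulate_zspectrum(mirror_pools(), saturation_pulse(0.9, 1.6),
                            offs, ctx, mode = mode)
    asym <- abs(rev(z$values[offs < 0]) - z$values[offs > 0])
    expect_lt(max(asym), 1e-6)
  }
})

test_that("output is invariant under permutation of non-water pools", {
  p <- list(pool("water", 1.8, 0.04),
            pool("a", 1.0, 0.015, 0.6, 0.002, 600),
            pool("b", 1.0, 5e-4, -2.4, 0.005, 30))
  offs <- seq(-3, 3, 0.6)
  z1 <- simulate_zspectrum(p, saturation_pulse(0.9, 1.6), offs, ctx)
  z2 <- simulate_zspectrum(p[c(1, 3, 2)], saturation_pulse(0.9, 1.6),
                           offs, ctx)
  expect_equal(z1$values, z2$values, tolerance = 1e-12)
})

test_that("thermal equilibrium is a fixed point without RF (detailed balance)", {
  pools <- default_pools()
  sys <- cestpipe:::.bm_system(pools, omega1 = 0, offset_ppm = 1.3,
                               hz_per_ppm = ctx$hz_per_ppm)
  resid <- sys$A %*% sys$M0 + sys$b
  # transverse rows are trivially 0 at equilibrium; the z rows encode
  # the exchange flux balance
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("pool and input validation is enforced", {
  expect_error(pool("w", 1.8, 0.04, fraction = 0), "fraction")
  expect_error(pool("w", 1.8, 0.04, k_exchange = -1), "k_exchange")
  bad <- list(pool("solute", 1, 0.015, 0.6, 0.5, 100))
  expect_error(simulate_zspectrum(bad, saturation_pulse(0.9, 1.6), 0, ctx),
               "water")
  expect_error(simulate_zspectrum(water, saturation_pulse(0.9, 1.6),
                                  numeric(0), ctx), "non-empty")
})

test_that("parameter sweep reproduces expected monotonicity and spillover", {
  mk <- function(f) list(pool("water", 1.8, 0.04),
                         pool("hydroxyl", 1.0, 0.015, 0.6, f, 600))
  # doubling the solute fraction raises the asymmetry
  sw <- sweep_parameters(list(mk(0.001), mk(0.002)),
                         list(saturation_pulse(0.9, 1.6)), 0.6, ctx)
  expect_true(all(is.na(sw$error)))
  expect_gt(sw$asym_pct[2], sw$asym_pct[1])
  # asymmetry rises from 0 with b1, then spillover brings it back down
  b1s <- c(0, 0.3, 0.9, 3, 10)
  swb <- sweep_parameters(list(mk(0.002)),
                          lapply(b1s, saturation_pulse, duration = 1.6),
                          0.6, ctx)
  a <- swb$asym_pct
  expect_equal(a[1], 0, tolerance = 1e-9)
  imax <- which.max(a)
  expect_true(imax > 1 && imax < length(a))
  # vanishing solute: no asymmetry at any b1
  sw0 <- sweep_parameters(list(mk(1e-15)),
                          list(saturation_pulse(0.9, 1.6)), 0.6, ctx)
  expect_lt(abs(sw0$asym_pct), 1e-6)
  # failing rows carry the message, sweep continues
  swe <- sweep_parameters(list(bad = list(pool("s", 1, 0.01, 0.6, 0.5, 1)),
                               ok = mk(0.001)),
                          list(saturation_pulse(0.9, 1.6)), 0.6, ctx)
  expect_false(is.na(swe$error[1]))
  expect_true(is.na(swe$error[2]))
})
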