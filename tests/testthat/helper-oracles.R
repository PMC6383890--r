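# Independent test oracles and small fixtures.

# Brute-force fixed-step RK4 integrator for the coupled multi-pool
# saturation equations, written from the physics with no shared code
# with the package's propagator. State per pool: (Mx, My, Mz).
rk4_zvalue <- function(pools, b1_ut, duration_s, offset_ppm,
                       hz_per_ppm = 9.4 * 42.577, h = 2e-5) {
  n <- length(pools)
  f <- vapply(pools, function(p) p$fraction, numeric(1))
  k <- vapply(pools, function(p) p$k_exchange, numeric(1))
  w1 <- 2 * pi * 42.577 * b1_ut
  A <- matrix(0, 3 * n, 3 * n)
  bb <- numeric(3 * n)
  for (i in seq_len(n)) {
    p <- pools[[i]]
    ix <- 3 * (i - 1) + 1
    dw <- 2 * pi * hz_per_ppm * (p$shift - offset_ppm)
    kout <- if (i == 1) sum(f[-1] * k[-1]) else k[i]
    A[ix, ix] <- -(1 / p$t2 + kout);      A[ix, ix + 1] <- dw
    A[ix + 1, ix] <- -dw;                 A[ix + 1, ix + 1] <- -(1 / p$t2 + kout)
    A[ix + 1, ix + 2] <- w1;              A[ix + 2, ix + 1] <- -w1
    A[ix + 2, ix + 2] <- -(1 / p$t1 + kout)
    bb[ix + 2] <- f[i] / p$t1
    if (i > 1) {
      for (d in 0:2) {
        A[1 + d, ix + d] <- A[1 + d, ix + d] + k[i]
        A[ix + d, 1 + d] <- A[ix + d, 1 + d] + f[i] * k[i]
      }
    }
  }
  y <- as.vector(rbind(0, 0, f))
  deriv <- function(y) A %*% y + bb
  nstep <- round(duration_s / h)
  for (s in seq_len(nstep)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y[3]
}

# Mirror-symmetric pool system: water plus two identical solutes at
# opposite shifts (an even z-spectrum by construction).
mirror_pools <- function(shift = 1, fraction = 0.003, k = 400) {
  list(pool("water", 1.8, 0.04),
       pool("plus", 1.0, 0.015, shift, fraction, k),
       pool("minus", 1.0, 0.015, -shift, fraction, k))
}

# Fraction of ground-truth somata matched by a segmented centroid
# within `tol_um`.
soma_detection_rate <- function(truth, regions, tol_um = 3) {
  if (!nrow(regions)) return(0)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    min((truth$cx_um[i] - regions$cx_um)^2 +
          (truth$cy_um[i] - regions$cy_um)^2) < tol_um^2
  }, logical(1))
  mean(hits)
}

# A measured WASSR spectrum whose water resonates at `shift` ppm:
# the on-resonance spectrum evaluated at (offset - shift).
shifted_wassr_spectrum <- function(shift, pools = list(pool("water", 1.8, 0.04)),
                                   offsets = default_wassr_offsets(),
                                   pulse = saturation_pulse(0.1, 0.5)) {
  z <- simulate_zspectrum(pools, pulse, offsets - shift, scanner_context())
  zspectrum(offsets, z$values)
}
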