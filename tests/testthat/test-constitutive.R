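# constitutive module: tension, cortical/adhesion/protrusion stresses,
# thermal relations, Young-Dupre equilibrium

p0 <- default_params()
A0 <- pi * 8.5^2
V0 <- pi * 8.5^3 / 6

test_that("biphasic tension law reproduces the printed branches", {
  expect_equal(cortical_tension(A0, A0, p0, smooth = FALSE), 0.01)
  expect_equal(cortical_tension(1.26 * A0, A0, p0, smooth = FALSE), 0.0516)
  expect_equal(cortical_tension(1.5 * A0, A0, p0, smooth = FALSE),
               0.0516 + 0.545 * 0.24, tolerance = 1e-12)
  # below-rest input clamps to the resting branch
  expect_equal(cortical_tension(0.9 * A0, A0, p0, smooth = FALSE), 0.01)
  expect_error(cortical_tension(-1, A0, p0), "positive")
})

test_that("smoothed tension is C1 and close to the piecewise law", {
  x <- seq(1, 1.6, by = 1e-4)
  raw <- cortical_tension(x * A0, A0, p0, smooth = FALSE)
  sm <- cortical_tension(x * A0, A0, p0, smooth = TRUE)
  w <- p0$smoothing_width
  expect_true(all(abs(sm - raw) <= p0$k2 * w + 1e-12))
  # C1: difference quotient of the smoothed law has no jumps larger than
  # a fraction of the slope change across one grid interval
  dsl <- diff(sm) / diff(x)
  expect_lt(max(abs(diff(dsl))), (p0$k2 - p0$k1) * 1e-4 / w * 2)
  # branches agree at the knee to round-off
  expect_equal(p0$tau_a + p0$k1 * (p0$ratio_trans - 1), p0$tau_b,
               tolerance = 1e-12)
})

test_that("cortical stress follows Laplace's law on a sphere", {
  c0 <- init_spherical_cap(8.5, 1e-3, n_free = 150)
  st <- cortical_stress(c0, tau = 0.01)
  mag <- sqrt(st$sr^2 + st$sz^2)
  # one-sided fits at the last nodes before the contact cusp are less
  # accurate; check everywhere else
  expect_true(all(abs(mag[2:(c0$contact_index - 4)] - 10 * 2 / 4.25) <
                  0.02 * 10 * 2 / 4.25))
  # inward: stress opposes the outward normal on a convex surface
  expect_true(all(st$sn[2:(c0$contact_index - 1)] < 0))
  # linearity in tau
  st2 <- cortical_stress(c0, tau = 0.02)
  expect_equal(st2$sr, 2 * st$sr, tolerance = 1e-12)
})

test_that("adhesion stress matches closed form and brute-force oracle", {
  p <- p0
  zoff <- 2^(-1 / 3) * p$D0
  # plane-integrated closed form: zero exactly at the equilibrium standoff
  expect_lt(abs(phagospread:::adhesion_plane_stress(zoff, p)), 1e-9)
  # a node far above the substrate feels a vanishing stress
  h_far <- 50 * p$D0
  h_near <- 1.077 * p$D0    # peak attraction height
  far <- phagospread:::adhesion_plane_stress(h_far, p)
  near <- phagospread:::adhesion_plane_stress(h_near, p)
  expect_lt(abs(far / near), 1e-3)

  # quadrature vs the independent 2-D brute-force oracle, node near the
  # contact line of a cap (1% agreement)
  c0 <- init_spherical_cap(8.5, 0.5, n_free = 80)
  st <- adhesion_stress(c0, p)
  a <- c0$r[c0$contact_index]
  for (i in c(74, 78)) {
    b <- brute_adhesion_stress(c0$r[i], c0$z[i], a, p)
    expect_lt(abs(st$sz[i] - b["sz"]) / abs(b["sz"]), 0.02)
  }
  # bare-plane configuration against the closed form
  r <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.2, 3.4, 3.41)
  z <- c(3, 2.5, 2, 1.5, 1, 0.5, 0.2, 0.1, 2 * p$D0 - zoff, 0.01)
  cc <- cell_contour(c(r, 1e-6, 0), c(z, 0, 0), contact_index = 11,
                     validate = FALSE)
  stp <- adhesion_stress(cc, p)
  expect_lt(abs(stp$sz[9] /
                phagospread:::adhesion_plane_stress(2 * p$D0, p) - 1),
            0.01)
  expect_lt(stp$sz[9], 0)   # net attraction toward the substrate

  # linear in the ligand density
  st30 <- adhesion_stress(c0, p, rho_rel = 30)
  expect_equal(st30$sz, 0.3 * st$sz, tolerance = 1e-12)
})

test_that("protrusion magnitude law reproduces the printed branches", {
  At <- contact_area_trans(p0)
  smax <- p0$sigma_prot_max
  expect_equal(protrusion_magnitude(0, At, 1, p0, smooth = FALSE),
               0.05 * smax)
  expect_equal(protrusion_magnitude(At, At, 1.3, p0, smooth = FALSE),
               0.35 * smax)
  expect_equal(protrusion_magnitude(At + 120, At, 1.4, p0, smooth = FALSE),
               smax)
  expect_equal(protrusion_magnitude(At + 500, At, 1.5, p0, smooth = FALSE),
               smax)
  expect_error(protrusion_magnitude(-1, At, 1, p0), "non-negative")
})

test_that("protrusion law is monotone and bounded (smoothed and raw)", {
  At <- contact_area_trans(p0)
  A_c <- seq(0, At + 200, length.out = 2000)
  # area ratio grows with contact area in a run; emulate with the cap map
  ratio <- 1 + 0.4 * (A_c / max(A_c))
  for (sm in c(TRUE, FALSE)) {
    v <- protrusion_magnitude(A_c, At, ratio, p0, smooth = sm)
    expect_true(all(diff(v) > -1e-9))
    expect_true(all(v >= 0.05 * p0$sigma_prot_max - 1e-9))
    expect_true(all(v <= p0$sigma_prot_max + 1e-9))
  }
})

test_that("protrusion profile decays exponentially from the contact line", {
  c0 <- init_spherical_cap(8.5, 2, n_free = 100)
  pr <- protrusion_profile(c0, 1000, p0)
  ci <- c0$contact_index
  expect_equal(pr$sn[ci], 1000, tolerance = 1e-12)
  s <- c0$s
  k1 <- which.min(abs((s[ci] - s) - p0$s0))
  expect_equal(pr$sn[k1], 1000 * exp(-(s[ci] - s[k1]) / p0$s0),
               tolerance = 1e-12)
  k2 <- which.min(abs((s[ci] - s) - 2 * p0$s0))
  expect_lt(abs(pr$sn[k2] / (1000 * exp(-2)) - 1), 0.3)
})

test_that("temporal protrusion decay", {
  expect_equal(protrusion_decay(100, 5, 5, p0), 100)
  expect_equal(protrusion_decay(100, 5 + p0$t0, 5, p0), 100 / exp(1))
  expect_equal(protrusion_decay(100, 66, 0, p0), 100 / exp(1))
  expect_error(protrusion_decay(100, 1, 5, p0), "t_bind")
})

test_that("membrane-fluctuation threshold hits the printed anchors", {
  d_rest <- fluctuation_threshold(0.01, A0, p0)
  expect_lt(abs(d_rest - 18) / 18, 0.05)      # ~18 nm at resting tension
  d_high <- fluctuation_threshold(1, 300, p0)
  expect_lt(abs(d_high - 2) / 2, 0.25)        # ~2 nm at very high tension
  # monotone decreasing in tau over the simulated range
  taus <- 10^seq(log10(0.01), log10(2), length.out = 50)
  d <- fluctuation_threshold(taus, 300, p0)
  expect_true(all(diff(d) < 0))
  # doubling kB T (via T) scales the threshold by exactly sqrt(2):
  # temperature enters the prefactor only
  p2 <- physical_params(temperature = 2 * p0$temperature)
  expect_equal(fluctuation_threshold(0.05, 300, p2) /
               fluctuation_threshold(0.05, 300, p0), sqrt(2),
               tolerance = 1e-12)
  expect_error(fluctuation_threshold(0, A0, p0), "positive")
})

test_that("adhesion energy density reproduces the printed estimates", {
  expect_equal(-log(p0$K_d), 13.8155, tolerance = 1e-4)
  expect_lt(abs(adhesion_energy_density(25000, p0) - 1500) / 1500, 0.05)
  expect_lt(abs(adhesion_energy_density(44, p0) - 2.6) / 2.6, 0.05)
  expect_identical(adhesion_energy_density(0, p0), 0)
  expect_error(adhesion_energy_density(-1, p0), "non-negative")
})

test_that("Young-Dupre equilibrium against the independent cap oracle", {
  yd <- young_dupre_equilibrium(100, V0, p0)
  orc <- oracle_cap_geometry(100, V0)
  expect_lt(abs((pi - yd$theta_c) - orc$theta) / orc$theta, 1e-5)
  expect_lt(abs(yd$A_cell - orc$A_cell) / orc$A_cell, 1e-5)
  # gamma from the oracle's geometry and the tension law
  tau_o <- cortical_tension(orc$A_cell, A0, p0, smooth = FALSE)
  g_o <- 1000 * tau_o * (1 - cos(pi - orc$theta))
  expect_lt(abs(yd$gamma - g_o) / g_o, 1e-4)

  # contact angle of 90 degrees: gamma = tau (hemispherical cap)
  R_hemi <- (3 * V0 / (2 * pi))^(1 / 3)
  yd90 <- young_dupre_equilibrium(pi * R_hemi^2, V0, p0)
  expect_equal(yd90$theta_c, pi / 2, tolerance = 1e-6)
  expect_equal(yd90$gamma, 1000 * yd90$tau, tolerance = 1e-6)

  # vanishing contact: gamma -> 0
  expect_lt(young_dupre_equilibrium(1e-3, V0, p0)$gamma, 0.5)
  expect_error(young_dupre_equilibrium(-5, V0, p0), "positive")
})

test_that("Young-Dupre forward and inverse maps are mutual inverses", {
  for (A_c in c(20, 60, 100, 140)) {
    g <- young_dupre_equilibrium(A_c, V0, p0)$gamma
    expect_lt(abs(young_dupre_area(g, V0, p0) - A_c) / A_c, 1e-7)
  }
})

test_that("transitional contact area is consistent with the cap map", {
  At <- contact_area_trans(p0)
  yd <- young_dupre_equilibrium(At, V0, p0)
  expect_equal(yd$A_cell, 1.26 * A0, tolerance = 1e-6)
})

test_that("parameter validation catches inconsistencies", {
  expect_error(physical_params(tau_b = 0.06), "discontinuous")
  expect_error(physical_params(mu = -1), "positive")
  expect_error(physical_params(ratio_trans = 0.9), "exceed 1")
})
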