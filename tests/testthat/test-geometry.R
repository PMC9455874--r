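# geometry module: contour construction, measurement, curvature,
# smoothing, volume correction, meshing

test_that("spherical-cap initialisation matches closed forms", {
  d <- 8.5
  V_exact <- pi * d^3 / 6            # 321.555 um^3
  c0 <- init_spherical_cap(d, 0.05)
  m <- measure_contour(c0)
  expect_lt(abs(m$volume - V_exact) / V_exact, 1e-3)
  expect_equal(c0$r[c0$contact_index], sqrt(0.05 / pi), tolerance = 1e-10)

  # vanishing footprint converges to the full sphere surface
  c1 <- init_spherical_cap(d, 1e-4)
  m1 <- measure_contour(c1)
  expect_lt(abs(m1$surface_area - pi * d^2) / (pi * d^2), 0.01)

  expect_error(init_spherical_cap(d, -1), "positive")
  expect_error(init_spherical_cap(d, 60), "smaller than")
  expect_error(init_spherical_cap(-1, 0.05), "positive")
})

test_that("contour invariants are enforced", {
  c0 <- init_spherical_cap(8.5, 0.05, n_free = 40)
  expect_identical(c0$r[1], 0)
  expect_true(all(diff(c0$s) > 0))
  expect_identical(c0$s_contact, c0$s[c0$contact_index])
  expect_true(all(c0$z[c0$contact_index:length(c0$z)] == 0))
  # self-intersecting polyline is rejected (segments 1-2 and 3-4 cross)
  r <- c(0, 2, 1.8, 0.2, 1.5, 0.75, 0)
  z <- c(3, 1, 2, 1.2, 0, 0, 0)
  expect_error(cell_contour(r, z, 5), "self-intersect")
})

test_that("measure_contour matches sphere closed forms and scaling", {
  # a nearly-detached sphere, 200 nodes
  c0 <- init_spherical_cap(8.5, 1e-3, n_free = 200)
  m <- measure_contour(c0)
  R <- 4.25
  expect_lt(abs(m$surface_area - 4 * pi * R^2) / (4 * pi * R^2), 0.01)
  expect_lt(abs(m$volume - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.01)

  # scaling law: x2 in size -> x4 area, x8 volume
  c2 <- cell_contour(2 * c0$r, 2 * c0$z, c0$contact_index)
  m2 <- measure_contour(c2)
  expect_equal(m2$surface_area / m$surface_area, 4, tolerance = 1e-12)
  expect_equal(m2$volume / m$volume, 8, tolerance = 1e-12)

  expect_error(measure_contour(list(r = c(0, 1), z = c(1, 0))),
               "degenerate")
})

test_that("curvature matches the sphere and the axis limit", {
  c0 <- init_spherical_cap(8.5, 3, n_free = 200, grade = 1)
  H <- compute_curvature(c0)
  expect_true(all(abs(H / (2 / 4.25) - 1) < 0.01))
  # apex value equals the symmetric limit (finite, = 2 dphi/ds)
  expect_true(is.finite(H[1]))
  # strongly graded nodes keep accuracy (analytic cap fixture)
  V <- 4 / 3 * pi * 4.25^3
  c1 <- make_cap_contour(pi - 0.05, V, n_free = 120, grade = 8)
  R1 <- phagospread:::cap_radius(pi - 0.05, V)
  H1 <- compute_curvature(c1)
  expect_true(all(abs(H1 / (2 / R1) - 1) < 0.01))
  expect_error(compute_curvature(cell_contour(c(0, 1, 1.5, 1),
                                              c(2, 1.5, 0.7, 0),
                                              4, validate = FALSE)),
               "free-surface nodes")
})

test_that("second-order convergence of sphere measures", {
  V_exact <- pi * 8.5^3 / 6
  A_exact <- pi * 8.5^2
  err <- sapply(c(50, 100, 200), function(n) {
    cc <- make_cap_contour(pi - 0.05, V_exact, n_free = n, grade = 1)
    m <- measure_contour(cc)
    abs(m$surface_area - cap_area_ref(pi - 0.05, V_exact)) /
      cap_area_ref(pi - 0.05, V_exact)
  })
  rate1 <- log2(err[1] / err[2])
  rate2 <- log2(err[2] / err[3])
  expect_gt(rate1, 1.6)
  expect_gt(rate2, 1.6)
})

test_that("smoothing damps zigzag noise and fixes the adherent set", {
  c0 <- init_spherical_cap(8.5, 0.5, n_free = 80, grade = 1)
  # a smooth contour is (nearly) a fixed point
  cs <- smooth_contour(c0)
  expect_lt(attr(cs, "max_displacement"), 5e-4)

  # single-node zigzag of amplitude delta
  delta <- 0.05
  cz <- c0
  k <- 40
  nrm <- phagospread:::contour_normals(c0)
  cz$r[k] <- cz$r[k] + delta * nrm$nr[k]
  cz$z[k] <- cz$z[k] + delta * nrm$nz[k]
  cz <- cell_contour(cz$r, cz$z, c0$contact_index, validate = FALSE)
  csm <- smooth_contour(cz)
  resid <- sqrt((csm$r[k] - c0$r[k])^2 + (csm$z[k] - c0$z[k])^2)
  expect_lt(resid, 0.5 * delta)
  other <- setdiff(2:(c0$contact_index - 1), (k - 3):(k + 3))
  dd <- sqrt((csm$r[other] - c0$r[other])^2 + (csm$z[other] - c0$z[other])^2)
  expect_true(all(dd < delta))

  ci <- c0$contact_index
  expect_identical(csm$r[ci:length(csm$r)], c0$r[ci:length(c0$r)])
  expect_identical(csm$z[ci:length(csm$z)], c0$z[ci:length(c0$z)])
})

test_that("volume correction restores the target volume", {
  c0 <- init_spherical_cap(8.5, 0.5, n_free = 80)
  V0 <- measure_contour(c0)$volume
  # +1% volume perturbation
  c1 <- cell_contour(c0$r * 1.0033, c0$z * 1.0033, c0$contact_index,
                     validate = FALSE)
  c1$r[1] <- 0
  c1 <- cell_contour(c1$r, pmax(c1$z, 0), c0$contact_index,
                     validate = FALSE)
  c2 <- correct_volume(c1, V0)
  expect_lt(abs(measure_contour(c2)$volume - V0) / V0, 1e-6)
  # contact nodes untouched
  ci <- c0$contact_index
  expect_identical(c2$r[ci:length(c2$r)], c1$r[ci:length(c1$r)])
  # zero drift is an identity
  expect_identical(correct_volume(c0, V0), c0)
  # 10% drift raises
  c3 <- cell_contour(c0$r * 1.05, c0$z * 1.05, c0$contact_index,
                     validate = FALSE)
  c3$r[1] <- 0
  expect_error(correct_volume(c3, V0), "drift")
})

test_that("mesh generation is valid, tagged, graded and deterministic", {
  c0 <- init_spherical_cap(8.5, 0.05, n_free = 60)
  msh <- generate_mesh(c0, layers = 10)
  expect_true(all(phagospread:::quad_jacobian_positive(msh$coords,
                                                       msh$elems)))
  # boundary roundtrip: free boundary nodes reproduce the contour free
  # nodes to round-off; adherent/axis nodes lie exactly on their surfaces
  fi <- msh$contour_index
  expect_equal(msh$coords[msh$free_nodes, 1], c0$r[fi], tolerance = 1e-14)
  expect_equal(msh$coords[msh$free_nodes, 2], c0$z[fi], tolerance = 1e-14)
  expect_true(all(msh$coords[msh$adherent_nodes, 2] == 0))
  expect_true(all(msh$coords[msh$axis_nodes, 1] == 0))
  # every boundary edge of the element graph carries exactly one tag
  tagged <- sort(unique(c(msh$free_nodes, msh$adherent_nodes,
                          msh$axis_nodes)))
  expect_true(all(boundary_nodes_of(msh) %in% tagged))

  # tighter element packing near the flat surface
  cz <- matrix(msh$coords[msh$elems, 2], ncol = 4)
  zc <- rowMeans(cz)
  low <- msh$elem_size[zc < 0.5]
  high <- msh$elem_size[zc > 2]
  expect_lt(mean(low), mean(high))

  # refinement in both directions halves h_mesh (within 20%)
  c1 <- init_spherical_cap(8.5, 0.05, n_free = 120)
  m2 <- generate_mesh(c1, layers = 20)
  expect_lt(abs(msh$h_mesh / m2$h_mesh - 2), 0.4)

  # bit-reproducible
  expect_identical(msh, generate_mesh(c0, layers = 10))
})

test_that("meshing works across the spread-shape family", {
  V <- pi * 8.5^3 / 6
  for (th in c(150, 120, 90, 60) * pi / 180) {
    cc <- make_cap_contour(th, V, n_free = 60)
    msh <- generate_mesh(cc, layers = 10)
    expect_true(all(phagospread:::quad_jacobian_positive(msh$coords,
                                                         msh$elems)))
  }
})

test_that("contour resampling preserves shape and contact line", {
  c0 <- init_spherical_cap(8.5, 2, n_free = 90)
  c1 <- resample_contour(c0, n_free = 60, n_adherent = 8)
  expect_identical(c1$contact_index, 60L)
  expect_equal(c1$r[60], c0$r[c0$contact_index], tolerance = 1e-12)
  m0 <- measure_contour(c0); m1 <- measure_contour(c1)
  expect_lt(abs(m1$volume - m0$volume) / m0$volume, 1e-3)
})
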