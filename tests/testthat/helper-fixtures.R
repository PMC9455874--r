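# Fixtures built in code: analytic contours and independent oracles.

# spherical-cap contour at a given polar half-angle (pi = detached sphere),
# volume V, built directly from the circle parameterisation
make_cap_contour <- function(theta, V, n_free = 80, n_adherent = 10,
                             grade = 4) {
  R <- (3 * V / (pi * (1 - cos(theta))^2 * (2 + cos(theta))))^(1 / 3)
  zc <- -R * cos(theta)
  ang <- theta * phagospread:::graded_seq(n_free, grade)
  r <- R * sin(ang)
  z <- zc + R * cos(ang)
  r[1] <- 0
  z[n_free] <- 0
  a <- R * sin(theta)
  r[n_free] <- a
  v <- phagospread:::graded_seq(n_adherent + 1, 1 / 4)[-1]
  cell_contour(c(r, a * (1 - v)), c(pmax(z, 0), rep(0, n_adherent)),
               contact_index = n_free, validate = FALSE)
}

# independent brute-force oracle for the continuum adhesion stress:
# direct 2-D polar quadrature over the substrate plane outside the disc
brute_adhesion_stress <- function(ri, zi, a, p, rho_rel = 100,
                                  plane_offset = 2^(-1 / 3) * p$D0,
                                  n_rho = 4000, n_th = 1600, rho_max = 8) {
  h <- zi + plane_offset
  W <- p$W_adh * rho_rel / 100
  D0 <- p$D0
  C <- W / D0^2
  rho <- seq(1e-5, rho_max, length.out = n_rho)
  th <- seq(0, pi, length.out = n_th)
  dr <- rho[2] - rho[1]; dth <- th[2] - th[1]
  RR <- matrix(rho, n_rho, n_th)
  CT <- matrix(cos(th), n_rho, n_th, byrow = TRUE)
  D <- sqrt(h^2 + ri^2 + RR^2 - 2 * ri * RR * CT)
  K <- (D0 / D)^4 - (D0 / D)^7
  outside <- RR > a
  sz <- 2 * C * sum(-h / D * K * RR * outside) * dr * dth
  sr <- 2 * C * sum((RR * CT - ri) / D * K * RR * outside) * dr * dth
  c(sr = sr, sz = sz)
}

# independent cap-geometry oracle: given contact area and volume, find the
# cap by bisection on the centre height using numeric volume quadrature
# (no closed-form cap formulas)
oracle_cap_geometry <- function(A_c, V) {
  a <- sqrt(A_c / pi)
  vol_num <- function(R, zc) {
    zt <- zc + R
    z <- seq(0, zt, length.out = 20001)
    r2 <- pmax(R^2 - (z - zc)^2, 0)
    pi * sum((r2[-1] + r2[-length(r2)]) / 2 * diff(z))
  }
  f <- function(zc) {
    R <- sqrt(zc^2 + a^2)
    vol_num(R, zc) - V
  }
  zc <- stats::uniroot(f, c(-9.9, 10), tol = 1e-12)$root
  R <- sqrt(zc^2 + a^2)
  theta <- acos(-zc / R)           # polar half-angle of the cap
  A_free <- 2 * pi * R^2 * (1 - cos(theta))
  list(theta = theta, R = R, A_cell = A_free + A_c)
}

default_params <- function(...) physical_params(...)

# closed-form total cap area used as the measurement reference
cap_area_ref <- function(theta, V) phagospread:::cap_total_area(theta, V)

# nodes on the topological boundary of the quad mesh (edges used once)
boundary_nodes_of <- function(msh) {
  el <- msh$elems
  ed <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 4)], el[, c(4, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  once <- names(which(table(key) == 1))
  unique(as.integer(unlist(strsplit(once, " "))))
}
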