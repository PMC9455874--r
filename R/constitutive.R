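#' Biphasic cortical tension law
#'
#' Tension of the actin cortex as a function of relative cell surface-area
#' expansion x = A_cell / A_cell0: a shallow linear regime
#' `tau_a + k1 (x - 1)` up to the knee at `ratio_trans`, then a steep regime
#' `tau_b + k2 (x - ratio_trans)`.  With `smooth = TRUE` the knee is replaced
#' by a C1 quadratic blend over `ratio_trans +- smoothing_width`; with
#' `smooth = FALSE` the raw branches are evaluated.  Area ratios below 1
#' (cell below its resting area) clamp to the resting branch value.
#'
#' @param A_cell current total cell surface area (um^2).
#' @param A_cell0 resting surface area (um^2).
#' @param p a [physical_params()] object.
#' @param smooth apply the C1 knee blend (default TRUE when
#'   `p$smoothing_width > 0`).
#' @return cortical tension (mN/m).
#' @export
cortical_tension <- function(A_cell, A_cell0, p = physical_params(),
                             smooth = p$smoothing_width > 0) {
  if (any(A_cell <= 0) || any(A_cell0 <= 0))
    stop("areas must be positive", call. = FALSE)
  x <- pmax(A_cell / A_cell0, 1)
  x0 <- p$ratio_trans
  b1 <- p$tau_a + p$k1 * (x - 1)
  b2 <- p$tau_b + p$k2 * (x - x0)
  w <- p$smoothing_width
  if (!smooth || w <= 0) return(ifelse(x <= x0, b1, b2))
  # C1 quadratic junction between slopes k1 and k2 over [x0 - w, x0 + w]
  lo <- x0 - w
  q <- p$tau_a + p$k1 * (lo - 1) + p$k1 * (x - lo) +
    (p$k2 - p$k1) / (4 * w) * (x - lo)^2
  ifelse(x <= lo, b1, ifelse(x >= x0 + w, b2, q))
}

#' Cortical stress from tension and curvature
#'
#' Laplace's law on the free surface: the cortical stress is
#' `-tau H n`, with H the mean curvature and n the outward normal; convex
#' regions (H > 0) feel an inward pull.
#'
#' @param c0 a [cell_contour()].
#' @param tau cortical tension (mN/m).
#' @param curvature optional precomputed curvature vector from
#'   [compute_curvature()].
#' @return list with per-free-node components `sr`, `sz` (Pa), the scalar
#'   normal magnitude `sn` (Pa, signed along the outward normal) and the
#'   normals used.
#' @export
cortical_stress <- function(c0, tau, curvature = NULL) {
  H <- if (is.null(curvature)) compute_curvature(c0) else curvature
  nrm <- contour_normals(c0)
  tau_int <- tension_to_internal(tau)   # Pa um
  sn <- -tau_int * H                    # Pa, along outward normal
  list(sr = sn * nrm$nr, sz = sn * nrm$nz, sn = sn,
       nr = nrm$nr, nz = nrm$nz)
}

# equilibrium standoff of the 7-4 adhesion potential integrated over a
# plane: net normal stress on a flat membrane vanishes at h = 2^(-1/3) D0
eq_standoff <- function(p) 2^(-1 / 3) * p$D0

# peak attractive stress (Pa) on a flat membrane over a bare substrate at
# relative density 100%; used to motivate the W_adh calibration
adhesion_peak_stress <- function(p) {
  xs <- (4 / 5)^(1 / 3)
  2 * pi * (xs^2 / 3 - xs^5 / 6) * p$W_adh
}

# closed-form normal stress (Pa, signed; negative = toward substrate) on a
# point at height h (um) above an infinite bare adhesive plane
adhesion_plane_stress <- function(h, p, rho_rel = 100) {
  W <- p$W_adh * rho_rel / 100
  x <- p$D0 / h
  -2 * pi * W * (x^2 / 3 - x^5 / 6)
}

#' Work of adhesion of the continuum potential
#'
#' Adhesion energy density gamma (uJ/m^2) released when unit membrane area
#' moves from infinity to the equilibrium standoff of the 7-4 potential,
#' obtained by integrating the plane-integrated normal stress in closed
#' form: gamma = (pi/2) 2^(1/3) W D0.
#'
#' @param p a [physical_params()].
#' @param rho_rel relative ligand density (%).
#' @return adhesion energy density (uJ/m^2).
#' @export
adhesion_work <- function(p, rho_rel = p$rho_rel) {
  (pi / 2) * 2^(1 / 3) * (p$W_adh * rho_rel / 100) * p$D0
}

#' Continuum adhesion stress on the free contour
#'
#' For every free node, integrates the short-range 7-4 pair potential over
#' the substrate plane outside the current contact disc.  The azimuthal part
#' of the integral is available in closed form (the excluded disc subtends
#' an angle interval at each lateral distance), leaving a 1-D radial
#' integral evaluated by Gauss quadrature in log distance.  The interaction
#' plane is offset below the substrate by the equilibrium standoff, so the
#' net normal stress on resting membrane at z = 0 vanishes; membrane above
#' the standoff is attracted, membrane below it is pushed back.
#'
#' @param c0 a [cell_contour()].
#' @param p a [physical_params()].
#' @param rho_rel relative ligand density (%); the stress is linear in it.
#' @param plane_offset depth of the interaction plane below z = 0 (um).
#' @param nq quadrature points of the radial rule.
#' @return list with per-free-node stress components `sr`, `sz` (Pa).
#' @export
adhesion_stress <- function(c0, p, rho_rel = p$rho_rel,
                            plane_offset = eq_standoff(p), nq = 48L) {
  ci <- c0$contact_index
  idx <- seq_len(ci)
  r_i <- c0$r[idx]
  h <- pmax(c0$z[idx], 0) + plane_offset
  h <- pmax(h, 1e-3)  # 1 nm singularity floor
  a <- c0$r[ci]       # contact radius
  W <- p$W_adh * rho_rel / 100
  D0 <- p$D0
  if (W == 0) return(list(sr = numeric(ci), sz = numeric(ci)))
  gl <- gauss_legendre(nq)
  m <- length(r_i)
  Dmax <- pmax(10 * h, 40 * D0)   # truncation tail ~ (h/Dmax)^3 = 0.1%
  # log-distance nodes per contour node: D in [h, Dmax]
  lo <- log(h); hi <- log(Dmax)
  Dm <- exp(outer(lo, gl$x, function(l, x) l) +
            outer(hi - lo, (gl$x + 1) / 2))  # m x nq
  wts <- outer((hi - lo) / 2, gl$w) * Dm     # includes dD = D dlogD
  l2 <- pmax(Dm^2 - h^2, 0)
  l <- sqrt(l2)
  # included azimuthal interval: outside the contact disc
  denom <- 2 * r_i * l
  cstar <- (a^2 - r_i^2 - l2) / ifelse(denom > 0, denom, 1)
  cstar[denom <= 0] <- ifelse((a^2 - r_i^2 - l2)[denom <= 0] > 0, 2, -2)
  cstar <- pmin(pmax(cstar, -1), 1)
  psi <- acos(cstar)          # included half-angle
  K <- (D0 / Dm)^4 - (D0 / Dm)^7   # attraction positive for D > D0
  C <- W / D0^2
  sz <- -C * h * rowSums(2 * psi * K * wts)
  sr <- C * rowSums(2 * sin(psi) * l * K * wts)
  # adherent contact-line node carries no pre-contact stress
  sz[ci] <- 0; sr[ci] <- 0
  list(sr = sr, sz = sz)
}

# Gauss-Legendre rule on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

# C1 soft helpers used by the smoothed protrusion law
.ssqrt <- function(x, delta) sqrt(0.5 * (x + sqrt(x^2 + delta^2)))
.smin1 <- function(b, delta) {
  y <- 1 - b
  1 - 0.5 * (y + sqrt(y^2 + delta^2))
}

#' Protrusion stress magnitude law
#'
#' Strength of the active protrusion stress as a function of the contact
#' area A_c, mirroring the biphasic tension response: linear growth
#' `c1 + c2 (A_c / A_c_trans)` while the cell is in the low-tension regime,
#' square-root growth `c3 + c4 sqrt((A_c - A_c_trans)/dA_sat)` once the
#' tension rises steeply, and saturation at `sigma_prot_max`.  `A_c_trans`
#' is the contact area at which the total cell area reaches the tension
#' knee.  With `smooth = TRUE` the branch joins are C1-blended.
#'
#' @param A_c cell-substrate contact area (um^2).
#' @param A_c_trans transitional contact area (um^2); see
#'   [contact_area_trans()].
#' @param area_ratio current A_cell / A_cell0 (selects the first branch).
#' @param p a [physical_params()].
#' @param smooth apply C1 blending (default follows `p$smoothing_width`).
#' @return protrusion stress magnitude (Pa).
#' @export
protrusion_magnitude <- function(A_c, A_c_trans, area_ratio,
                                 p = physical_params(),
                                 smooth = p$smoothing_width > 0) {
  if (any(A_c < 0)) stop("A_c must be non-negative", call. = FALSE)
  x0 <- p$ratio_trans
  b1 <- p$prot_c1 + p$prot_c2 * (A_c / A_c_trans)
  if (!smooth || p$smoothing_width <= 0) {
    b2 <- p$prot_c3 + p$prot_c4 * sqrt(pmax(A_c - A_c_trans, 0) / p$dA_sat)
    f <- ifelse(area_ratio <= x0, b1,
                ifelse(A_c > A_c_trans + p$dA_sat, 1, pmin(b2, 1)))
    return(p$sigma_prot_max * f)
  }
  dA <- p$dA_sat * (p$smoothing_width / 0.02) * 0.04   # um^2 scale of blends
  b2 <- p$prot_c3 + p$prot_c4 * .ssqrt((A_c - A_c_trans) / p$dA_sat,
                                       dA / p$dA_sat)
  b2 <- .smin1(b2, 0.02)
  t <- (area_ratio - (x0 - p$smoothing_width)) / (2 * p$smoothing_width)
  t <- pmin(pmax(t, 0), 1)
  wgt <- t^2 * (3 - 2 * t)
  p$sigma_prot_max * ((1 - wgt) * b1 + wgt * b2)
}

#' Spatial profile of the protrusion stress
#'
#' Distributes a protrusion magnitude along the free contour with
#' exponential decay in arc-length distance from the contact line:
#' `sigma_prot exp(-(s_contact - s)/s0)`, acting along the outward normal.
#'
#' @param c0 a [cell_contour()].
#' @param sigma_prot protrusion stress magnitude at the contact line (Pa).
#' @param p a [physical_params()].
#' @return list with per-free-node components `sr`, `sz` (Pa) and scalar
#'   magnitudes `sn`.
#' @export
protrusion_profile <- function(c0, sigma_prot, p = physical_params()) {
  ci <- c0$contact_index
  s <- c0$s[1:ci]
  sn <- sigma_prot * exp(-(c0$s_contact - s) / p$s0)
  nrm <- contour_normals(c0)
  list(sr = sn * nrm$nr, sz = sn * nrm$nz, sn = sn)
}

#' Temporal decay of the protrusion stress
#'
#' After the most recent bond formation at `t_bind`, the protrusion stress
#' decays exponentially with time constant `t0` (discrete-adhesion model).
#'
#' @param sigma_prot stress before decay (Pa).
#' @param t current time (s); must be `>= t_bind`.
#' @param t_bind time of the most recent bond formation (s).
#' @param p a [physical_params()].
#' @return decayed stress (Pa).
#' @export
protrusion_decay <- function(sigma_prot, t, t_bind, p = physical_params()) {
  if (any(t < t_bind)) stop("t must be >= t_bind", call. = FALSE)
  sigma_prot * exp(-(t - t_bind) / p$t0)
}

#' Membrane-fluctuation capture distance
#'
#' RMS height of thermal membrane fluctuations at tension tau:
#' `sqrt(kB T / (4 pi tau) * log(1 + tau A_cell / (pi^2 kappa_b)))`.
#' Used as the threshold distance at which a free ligand site captures the
#' approaching membrane in the discrete-adhesion model; rising tension
#' suppresses fluctuations and shrinks the capture range.
#'
#' @param tau cortical tension (mN/m), positive.
#' @param A_cell cell surface area (um^2).
#' @param p a [physical_params()].
#' @return RMS fluctuation height (nm).
#' @export
fluctuation_threshold <- function(tau, A_cell, p = physical_params()) {
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  tau_int <- tension_to_internal(tau)        # Pa um
  kBT <- .kB_int * p$temperature             # Pa um^3
  kb <- p$kappa_b * 1e18                     # Pa um^3
  h2 <- kBT / (4 * pi * tau_int) * log(1 + tau_int * A_cell / (pi^2 * kb))
  1000 * sqrt(h2)                            # um -> nm
}

#' Adhesion energy density from ligand density
#'
#' Upper-limit estimate assuming every ligand in the contact region is
#' bonded: `gamma = rho E_bind kB T`, with the per-bond energy
#' `E_bind = -ln(K_d)` in kB T units (about 14 for K_d = 1e-6 M).
#'
#' @param rho_IgG ligand surface density (um^-2).
#' @param p a [physical_params()].
#' @return energy density (uJ/m^2).
#' @export
adhesion_energy_density <- function(rho_IgG, p = physical_params()) {
  if (any(rho_IgG < 0)) stop("density must be non-negative", call. = FALSE)
  E_bind <- -log(p$K_d)
  rho_IgG * E_bind * .kB_int * p$temperature
}

# spherical-cap geometry at fixed volume: radius for contact angle theta
cap_radius <- function(theta, V) {
  (3 * V / (pi * (1 - cos(theta))^2 * (2 + cos(theta))))^(1 / 3)
}

# contact area of the constant-volume cap at contact angle theta
cap_contact_area <- function(theta, V) {
  R <- cap_radius(theta, V)
  pi * R^2 * sin(theta)^2
}

# total surface area (free cap + contact disc) at contact angle theta
cap_total_area <- function(theta, V) {
  R <- cap_radius(theta, V)
  2 * pi * R^2 * (1 - cos(theta)) + pi * R^2 * sin(theta)^2
}

#' Young-Dupre equilibrium of the adhesive droplet model
#'
#' For a spherical cap of volume V with contact area A_c, solves the cap
#' geometry for the contact angle theta_c and total surface area A_cell,
#' evaluates the cortical tension at that area, and returns the adhesion
#' energy density required at equilibrium, `gamma = tau (1 - cos theta_c)`.
#'
#' @param A_c contact area (um^2), positive.
#' @param V cell volume (um^3).
#' @param p a [physical_params()].
#' @param smooth passed to [cortical_tension()].
#' @return list with `theta_c` (rad), `A_cell` (um^2), `tau` (mN/m),
#'   `gamma` (uJ/m^2).
#' @export
young_dupre_equilibrium <- function(A_c, V, p = physical_params(),
                                    smooth = FALSE) {
  if (A_c <= 0 || !is.finite(A_c)) stop("A_c must be positive", call. = FALSE)
  f <- function(th) cap_contact_area(th, V) - A_c
  eps <- 1e-8
  if (f(pi - eps) > 0) stop("A_c below the attainable cap range",
                            call. = FALSE)
  theta <- stats::uniroot(f, c(eps, pi - eps), tol = 1e-12)$root
  A_cell <- cap_total_area(theta, V)
  tau <- cortical_tension(A_cell, rest_area(p), p, smooth = smooth)
  # theta is the polar half-angle of the cap (pi = detached sphere); the
  # contact angle of the wetting relation gamma = tau (1 - cos theta_c) is
  # its supplement, so gamma -> 0 for a barely-touching cell
  theta_c <- pi - theta
  gamma <- tension_to_internal(tau) * (1 - cos(theta_c))  # Pa um = uJ/m^2
  list(theta_c = theta_c, A_cell = A_cell, tau = tau, gamma = gamma)
}

#' Inverse Young-Dupre map: contact area from adhesion energy
#'
#' Root-finds the equilibrium contact area whose Young-Dupre energy equals
#' `gamma`; the forward map is monotone increasing in A_c.
#'
#' @param gamma adhesion energy density (uJ/m^2), positive.
#' @param V cell volume (um^3).
#' @param p a [physical_params()].
#' @param smooth passed to [cortical_tension()].
#' @return equilibrium contact area (um^2).
#' @export
young_dupre_area <- function(gamma, V, p = physical_params(),
                             smooth = FALSE) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  g <- function(A_c) young_dupre_equilibrium(A_c, V, p, smooth)$gamma - gamma
  lo <- 1e-4; hi <- 500
  while (g(hi) < 0 && hi < 5e4) hi <- hi * 2
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Transitional contact area of the protrusion law
#'
#' Contact area of the constant-volume spherical cap whose total surface
#' area equals `ratio_trans` times the resting area -- the moment the
#' cortical tension enters its steep regime.  Used as `A_c_trans` in
#' [protrusion_magnitude()].
#'
#' @param p a [physical_params()].
#' @return transitional contact area (um^2).
#' @export
contact_area_trans <- function(p = physical_params()) {
  V <- rest_volume(p)
  target <- p$ratio_trans * rest_area(p)
  f <- function(th) cap_total_area(th, V) - target
  stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root |>
    cap_contact_area(V)
}
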