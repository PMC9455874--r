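#' Physical and model parameters for cell-spreading simulations
#'
#' Bundles every material constant and constitutive coefficient used by the
#' spreading models.  The internal unit system is micrometre-second-Pascal
#' (1 Pa um^2 = 1e-12 N); tensions are exposed in mN/m (1 mN/m = 1000 Pa um),
#' energies per area in uJ/m^2 (numerically equal to Pa um).
#'
#' @param mu cytoplasmic viscosity (Pa s).  200 for the passive (Brownian
#'   zipper) cell, 1660 for the active (protrusive zipper) cell.
#' @param cell_diameter resting cell diameter (um).
#' @param p_out external hydrostatic pressure (Pa), the pressure reference.
#' @param tau_a,k1,tau_b,k2 coefficients of the biphasic cortical tension law
#'   (mN/m): tau = tau_a + k1 (x - 1) below the knee and
#'   tau_b + k2 (x - ratio_trans) above it, with x = A_cell / A_cell0.
#' @param ratio_trans area ratio at the tension knee (dimensionless).
#' @param smoothing_width half-width (in area ratio) of the C1 quadratic blend
#'   applied at the tension knee; also scales the protrusion-law blends.
#'   Set to 0 to evaluate the raw piecewise branches.
#' @param sigma_prot_max maximum protrusion stress (Pa).
#' @param prot_c1,prot_c2,prot_c3,prot_c4 coefficients of the three-branch
#'   protrusion-magnitude law (fractions of `sigma_prot_max`).
#' @param dA_sat contact-area scale (um^2) over which the protrusion stress
#'   saturates above the transitional contact area.
#' @param s0 spatial decay length of the protrusion stress along the free
#'   contour arc (um).
#' @param t0 temporal decay constant of the protrusion stress after the most
#'   recent bond formation (s); used by the discrete-adhesion model.
#' @param D0 range of the cell-substrate adhesion potential (um; 50 nm).
#' @param W_adh adhesion strength at 100% relative ligand density (Pa).  This
#'   is the single calibrated product sigma_0 rho_l D0^2 of the pairwise
#'   interaction scale and ligand density; the continuum adhesion stress is
#'   linear in it.  The default is chosen so that the peak attractive stress
#'   on a flat membrane over a bare substrate at full coverage is 2 kPa,
#'   comparable to the maximum protrusion stress.
#' @param rho_rel relative ligand density for continuum runs (%, 0-100).
#' @param rho_l absolute ligand site density for discrete runs (um^-2).
#' @param temperature absolute temperature (K).
#' @param kappa_b membrane bending modulus (J).
#' @param K_d equilibrium dissociation constant of the receptor-ligand bond
#'   (mol/L); sets the per-bond energy E_bind = -ln(K_d) in kB T units.
#' @param contact_threshold height (um) below which advected free membrane is
#'   considered in contact with the substrate and joins the adherent set.
#'   `NULL` (default) uses the equilibrium standoff of the adhesion
#'   potential, `2^(-1/3) D0`: membrane that has reached the potential
#'   minimum is adhered.
#'
#' @return An object of class `phago_params` (a validated list).
#' @export
physical_params <- function(mu = 1660,
                            cell_diameter = 8.5,
                            p_out = 0,
                            tau_a = 0.01, k1 = 0.16,
                            tau_b = 0.0516, k2 = 0.545,
                            ratio_trans = 1.26,
                            smoothing_width = 0.02,
                            sigma_prot_max = 3500,
                            prot_c1 = 0.05, prot_c2 = 0.3,
                            prot_c3 = 0.35, prot_c4 = 0.65,
                            dA_sat = 120,
                            s0 = 0.8,
                            t0 = 66,
                            D0 = 0.05,
                            W_adh = 1846.77,
                            rho_rel = 100,
                            rho_l = 1000,
                            temperature = 310,
                            kappa_b = 2e-20,
                            K_d = 1e-6,
                            contact_threshold = NULL) {
  p <- list(mu = mu, cell_diameter = cell_diameter, p_out = p_out,
            tau_a = tau_a, k1 = k1, tau_b = tau_b, k2 = k2,
            ratio_trans = ratio_trans, smoothing_width = smoothing_width,
            sigma_prot_max = sigma_prot_max,
            prot_c1 = prot_c1, prot_c2 = prot_c2,
            prot_c3 = prot_c3, prot_c4 = prot_c4,
            dA_sat = dA_sat, s0 = s0, t0 = t0,
            D0 = D0, W_adh = W_adh, rho_rel = rho_rel, rho_l = rho_l,
            temperature = temperature, kappa_b = kappa_b, K_d = K_d,
            contact_threshold = if (is.null(contact_threshold))
              2^(-1 / 3) * D0 else contact_threshold)
  validate_params(p)
  class(p) <- "phago_params"
  p
}

validate_params <- function(p) {
  pos <- c("mu", "cell_diameter", "tau_a", "k1", "tau_b", "k2",
           "sigma_prot_max", "dA_sat", "s0", "t0", "D0",
           "temperature", "kappa_b", "K_d", "contact_threshold")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$ratio_trans <= 1) stop("ratio_trans must exceed 1", call. = FALSE)
  knee <- p$tau_a + p$k1 * (p$ratio_trans - 1)
  if (abs(knee - p$tau_b) > 1e-10) {
    stop("tension law discontinuous at the knee: tau_a + k1 (ratio_trans - 1) = ",
         format(knee), " but tau_b = ", format(p$tau_b), call. = FALSE)
  }
  if (p$smoothing_width < 0) stop("smoothing_width must be >= 0", call. = FALSE)
  if (p$W_adh < 0) stop("W_adh must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.phago_params <- function(x, ...) {
  cat("Cell-spreading model parameters (um-s-Pa units)\n")
  cat(sprintf("  viscosity mu        : %g Pa s\n", x$mu))
  cat(sprintf("  cell diameter       : %g um\n", x$cell_diameter))
  cat(sprintf("  tension law         : %g + %g (x-1) | %g + %g (x-%g) mN/m\n",
              x$tau_a, x$k1, x$tau_b, x$k2, x$ratio_trans))
  cat(sprintf("  protrusion          : sigma_max %g Pa, s0 %g um, t0 %g s\n",
              x$sigma_prot_max, x$s0, x$t0))
  cat(sprintf("  adhesion            : D0 %g um, W(100%%) %g Pa\n",
              x$D0, x$W_adh))
  cat(sprintf("  thermal             : T %g K, kappa_b %g J\n",
              x$temperature, x$kappa_b))
  invisible(x)
}

# Boltzmann constant in J/K and in internal Pa um^3 units
.kB_J <- 1.380649e-23
.kB_int <- 1.380649e-23 * 1e18  # 1 J = 1e18 Pa um^3

# tension conversion: mN/m -> Pa um
tension_to_internal <- function(tau_mN_m) tau_mN_m * 1000
tension_to_mN_m <- function(tau_int) tau_int / 1000

# resting-sphere reference areas/volumes
rest_area <- function(p) pi * p$cell_diameter^2
rest_volume <- function(p) pi * p$cell_diameter^3 / 6
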