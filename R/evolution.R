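#' Adaptive time step from the Courant rule
#'
#' Largest step such that fluid moves at most `courant_fraction` of any
#' individual element (per-element size over local speed), capped at
#' `dt_max` when velocities are tiny.
#'
#' @param mesh a `phago_mesh`.
#' @param flow a `flow_field` on that mesh.
#' @param courant_fraction allowed fraction of an element per step.
#' @param dt_max cap (s) for quiescent phases.
#' @return time step (s).
#' @export
compute_timestep <- function(mesh, flow, courant_fraction = 0.1,
                             dt_max = 0.5) {
  sp <- sqrt(flow$vr^2 + flow$vz^2)
  spe <- matrix(sp[mesh$elems], ncol = 4)
  spe <- pmax(spe[, 1], spe[, 2], spe[, 3], spe[, 4])
  ok <- spe > 1e-12
  if (!any(ok)) return(dt_max)
  min(courant_fraction * min(mesh$elem_size[ok] / spe[ok]), dt_max)
}

#' Advect the contour with the boundary velocity
#'
#' Forward-Euler displacement of the free-surface nodes by the flow field
#' (adherent nodes are no-slip and do not move; the apex keeps r = 0).
#' The returned contour may dip below z = 0; the contact-line update is
#' responsible for converting such nodes to adherent contact.
#'
#' @param c0 a [cell_contour()].
#' @param flow a `flow_field`.
#' @param mesh the `phago_mesh` the flow was solved on (provides the
#'   contour-to-mesh node map).
#' @param dt time step (s).
#' @return the advected contour (not validated for z >= 0).
#' @export
advect <- function(c0, flow, mesh, dt) {
  ci <- c0$contact_index
  r <- c0$r; z <- c0$z
  # mesh free boundary nodes in contour order
  ord <- order(mesh$contour_index)          # -> contour nodes 1..ci
  mid <- mesh$free_nodes[ord]
  idx <- seq_len(ci - 1L)                   # contact-line node is no-slip
  r[idx] <- r[idx] + flow$vr[mid[idx]] * dt
  z[idx] <- z[idx] + flow$vz[mid[idx]] * dt
  r[1] <- 0
  cell_contour(r, z, ci, validate = FALSE)
}

# rebuild a contour from a free polyline, a new contact radius and an
# adherent node count (tail graded toward the contact line)
rebuild_contour <- function(r_free, z_free, r_contact, n_adherent) {
  v <- graded_seq(n_adherent + 1L, ratio = 1 / 4)[-1L]
  r_adh <- r_contact * (1 - v)
  cell_contour(c(r_free, r_contact, r_adh),
               c(pmax(z_free, 0), 0, rep(0, length(r_adh))),
               contact_index = length(r_free) + 1L, validate = FALSE)
}

#' Continuum contact-line update
#'
#' Free nodes advected to `z <= threshold` join the adherent set: the
#' contour is zipped onto the substrate from the innermost such node
#' through the contact line, the contact radius becomes the largest
#' adherent radius, and the adherent disc is re-gridded.  Contact is
#' irreversible; with no crossing nodes the contour is returned unchanged.
#'
#' @param c0 the advected contour.
#' @param threshold capture height (um).
#' @return the updated `cell_contour`.
#' @export
update_contact_continuum <- function(c0, threshold = 0) {
  ci <- c0$contact_index
  n <- length(c0$r)
  hit <- which(c0$z[seq_len(ci - 1L)] <= threshold)
  if (!length(hit)) {
    # still clamp stray negative coordinates from round-off
    if (any(c0$z < 0)) {
      z <- pmax(c0$z, 0)
      return(cell_contour(c0$r, z, ci, validate = FALSE))
    }
    return(c0)
  }
  k <- min(hit)
  if (k < 5L) stop("contact zip would consume the whole free surface",
                   call. = FALSE)
  zipped_r <- c0$r[k:(ci - 1L)]
  r_contact <- max(zipped_r, c0$r[ci])
  rebuild_contour(c0$r[seq_len(k - 1L)], c0$z[seq_len(k - 1L)],
                  r_contact, n_adherent = n - ci)
}

#' Discrete adhesion-site lattice
#'
#' Concentric rings of substrate binding sites with radial spacing
#' `rho_l^(-1/2)` (the in-plane ligand spacing), laterally shifted by
#' `offset`.  Sites within the initial footprint start bound at t = 0.
#'
#' @param rho_l ligand density (um^-2).
#' @param offset lateral lattice shift (um), in `[0, spacing)`.
#' @param r_max outermost ring radius (um).
#' @param r_bound0 initial contact radius; rings inside start bound.
#' @return object of class `adhesion_sites`.
#' @export
adhesion_sites <- function(rho_l, offset = 0, r_max = 8, r_bound0 = 0) {
  stopifnot(rho_l > 0)
  spacing <- 1 / sqrt(rho_l)
  radii <- seq(offset, r_max, by = spacing)
  bound <- radii <= r_bound0
  structure(list(radii = radii, bound = bound,
                 t_bind = ifelse(bound, 0, NA_real_),
                 spacing = spacing, offset = offset),
            class = "adhesion_sites")
}

#' @export
print.adhesion_sites <- function(x, ...) {
  cat(sprintf(
    "adhesion_sites: %d rings, spacing %.4f um (offset %.4f), %d bound\n",
    length(x$radii), x$spacing, x$offset, sum(x$bound)))
  invisible(x)
}

# minimum distance from a point (rp, 0) to the free part of a contour
# (vectorised point-to-segment distances)
contour_point_distance <- function(c0, rp) {
  ci <- c0$contact_index
  x <- c0$r[1:ci]; y <- pmax(c0$z[1:ci], 0)
  ax <- x[-ci]; ay <- y[-ci]
  bx <- x[-1]; by <- y[-1]
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- ((rp - ax) * dx + (0 - ay) * dy) / pmax(L2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  px <- ax + t * dx; py <- ay + t * dy
  min(sqrt((px - rp)^2 + py^2))
}

#' Discrete contact-line update
#'
#' Scans the free rings outward from the contact line; whenever the free
#' contour approaches a ring to within the membrane-fluctuation capture
#' distance (Eq.-of-state via [fluctuation_threshold()] at the current
#' tension), the ring binds irreversibly: its binding time is recorded and
#' the membrane is zipped onto the substrate out to the ring radius.
#' Repeats until no further ring is captured this step.
#'
#' @param c0 the advected contour.
#' @param sites an [adhesion_sites()] lattice.
#' @param tau current cortical tension (mN/m).
#' @param A_cell current cell surface area (um^2).
#' @param t current time (s).
#' @param p a [physical_params()].
#' @return list with the updated `contour`, `sites`, and `n_new` bonds.
#' @export
update_contact_discrete <- function(c0, sites, tau, A_cell, t, p) {
  d_thr <- fluctuation_threshold(tau, A_cell, p) / 1000   # nm -> um
  n_adh <- length(c0$r) - c0$contact_index
  n_free0 <- c0$contact_index
  # free membrane may rest on (but not cross) the substrate
  if (any(c0$z < 0)) {
    c0 <- cell_contour(c0$r, pmax(c0$z, 0), c0$contact_index,
                       validate = FALSE)
  }
  n_new <- 0L
  repeat {
    free_sites <- which(!sites$bound)
    if (!length(free_sites)) break
    k <- free_sites[which.min(sites$radii[free_sites])]  # next ring outward
    rp <- sites$radii[k]
    if (rp <= c0$r[c0$contact_index]) {          # overrun by the zipper
      sites$bound[k] <- TRUE; sites$t_bind[k] <- t
      n_new <- n_new + 1L
      next
    }
    if (contour_point_distance(c0, rp) > d_thr) break
    sites$bound[k] <- TRUE
    sites$t_bind[k] <- t
    n_new <- n_new + 1L
    ci <- c0$contact_index
    # zip the membrane between the ring and the old contact line: cut at
    # the free node nearest the ring, keep everything apex-side of it
    d2 <- (c0$r[seq_len(ci - 1L)] - rp)^2 + c0$z[seq_len(ci - 1L)]^2
    kstar <- which.min(d2)
    if (kstar < 6L) stop("discrete zip would consume the whole free surface",
                         call. = FALSE)
    c0 <- rebuild_contour(c0$r[seq_len(kstar - 1L)],
                          c0$z[seq_len(kstar - 1L)], rp, n_adherent = n_adh)
    # keep the free-surface resolution: successive ring captures in one
    # step would otherwise eat the contour node by node
    c0 <- resample_contour(c0, n_free = n_free0, n_adherent = n_adh)
  }
  list(contour = c0, sites = sites, n_new = n_new)
}
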