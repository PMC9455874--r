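#' Axisymmetric cell contour
#'
#' The generating curve of the axisymmetric cell surface, ordered from the
#' apex (on the symmetry axis, top of the cell) down the free surface to the
#' contact line (z = 0) and then inward along the substrate back to the axis.
#' Node `contact_index` is the contact-line node, the first node of the
#' adherent set; all nodes from it onward lie exactly on z = 0.
#'
#' @param r,z node coordinates (um), apex first.
#' @param contact_index index of the contact-line node.
#' @param validate check the class invariants (default TRUE).
#' @return An object of class `cell_contour`: a list with fields `r`, `z`,
#'   `contact_index`, cumulative arc length `s` and `s_contact`.
#' @export
cell_contour <- function(r, z, contact_index, validate = TRUE) {
  stopifnot(length(r) == length(z), length(r) >= 3)
  s <- c(0, cumsum(sqrt(diff(r)^2 + diff(z)^2)))
  c0 <- structure(
    list(r = as.numeric(r), z = as.numeric(z),
         contact_index = as.integer(contact_index),
         s = s, s_contact = s[contact_index]),
    class = "cell_contour")
  if (validate) validate_contour(c0)
  c0
}

validate_contour <- function(c0, tol = 1e-9) {
  n <- length(c0$r)
  ci <- c0$contact_index
  if (ci < 2L || ci > n) stop("contact_index out of range", call. = FALSE)
  if (abs(c0$r[1]) > tol) stop("first node must lie on the axis (r = 0)",
                               call. = FALSE)
  if (any(c0$r < -tol)) stop("negative r coordinate", call. = FALSE)
  if (any(c0$z < -tol)) stop("node below the substrate (z < 0)", call. = FALSE)
  if (any(c0$z[ci:n] != 0)) stop("adherent nodes must have z = 0 exactly",
                                 call. = FALSE)
  if (any(diff(c0$s) <= 0)) stop("arc length not strictly increasing ",
                                 "(coincident nodes)", call. = FALSE)
  if (!is_simple_contour(c0)) stop("contour is self-intersecting",
                                   call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cell_contour <- function(x, ...) {
  m <- measure_contour(x)
  cat(sprintf(
    "cell_contour: %d nodes (%d free), contact radius %.3f um,\n  surface area %.2f um^2, volume %.2f um^3\n",
    length(x$r), x$contact_index - 1L, x$r[x$contact_index],
    m$surface_area, m$volume))
  invisible(x)
}

#' Test a contour polyline for self-intersection
#'
#' Exact segment-pair test, vectorised over all non-adjacent pairs.
#' @param c0 a `cell_contour` (or list with `r`, `z`).
#' @return TRUE if the polyline is simple.
#' @export
is_simple_contour <- function(c0) {
  x <- c0$r; y <- c0$z
  ns <- length(x) - 1L
  if (ns < 3L) return(TRUE)
  ij <- which(outer(seq_len(ns), seq_len(ns), function(i, j) j > i + 1L),
              arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  # segment i: p1->p2, segment j: q1->q2
  p1x <- x[i]; p1y <- y[i]; p2x <- x[i + 1L]; p2y <- y[i + 1L]
  q1x <- x[j]; q1y <- y[j]; q2x <- x[j + 1L]; q2y <- y[j + 1L]
  d1 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d2 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  d3 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d4 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  cross <- (d1 * d2 < 0) & (d3 * d4 < 0)
  !any(cross)
}

#' Graded sequence on [0, 1]
#'
#' `n` points from 0 to 1 with geometrically decreasing spacing toward 1;
#' `ratio` is the first-to-last spacing ratio.
#' @keywords internal
graded_seq <- function(n, ratio = 6) {
  stopifnot(n >= 2)
  if (n == 2) return(c(0, 1))
  g <- ratio^(1 / (n - 2))        # per-interval shrink factor
  sp <- g^(-(0:(n - 2)))          # decreasing spacings toward u = 1
  u <- c(0, cumsum(sp) / sum(sp))
  u[length(u)] <- 1
  u
}

#' Initial spherical-cap contour
#'
#' Builds the starting shape of a simulation: a sphere of the given diameter
#' truncated by the substrate so that it has a small flat contact footprint,
#' with the enclosed volume equal to the volume of the full sphere (volume is
#' conserved for the rest of the run).
#'
#' @param diameter resting cell diameter (um).
#' @param footprint_area initial contact footprint (um^2); must be positive
#'   and smaller than the sphere cross-section.
#' @param n_free number of nodes on the free surface (apex to contact line).
#' @param n_adherent number of nodes on the adherent disc (contact line to
#'   axis), contact-line node excluded.
#' @param grade free-surface node-spacing ratio, apex-to-contact (spacing is
#'   finer near the contact line).
#' @return A `cell_contour`.
#' @export
init_spherical_cap <- function(diameter, footprint_area,
                               n_free = 120, n_adherent = 12, grade = 8) {
  if (!is.finite(diameter) || diameter <= 0)
    stop("diameter must be positive", call. = FALSE)
  if (!is.finite(footprint_area) || footprint_area <= 0)
    stop("footprint_area must be positive", call. = FALSE)
  if (footprint_area >= pi * (diameter / 2)^2)
    stop("footprint_area must be smaller than the sphere cross-section",
         call. = FALSE)
  a <- sqrt(footprint_area / pi)
  V_target <- pi * diameter^3 / 6
  # cap volume above z = 0 for sphere radius R resting with contact radius a
  vol_cap <- function(R) {
    zc <- sqrt(R^2 - a^2)
    pi * (2 / 3 * R^3 + R^2 * zc - zc^3 / 3)
  }
  R0 <- diameter / 2
  f <- function(R) vol_cap(R) - V_target
  # vol_cap(R0) < V_full? vol_cap(R0) = V_full - missing sliver < V_target
  up <- R0 * 1.5
  while (f(up) < 0) up <- up * 1.5
  R_geom <- stats::uniroot(f, c(max(a * (1 + 1e-12), R0 * 0.5), up),
                           tol = 1e-12 * R0)$root
  build <- function(R) {
    zc <- sqrt(R^2 - a^2)
    th_end <- acos(-zc / R)
    u <- graded_seq(n_free, ratio = grade)
    th <- th_end * u
    r <- R * sin(th)
    z <- zc + R * cos(th)
    r[1] <- 0
    z[length(z)] <- 0
    r[length(r)] <- a
    # adherent disc: fine near the contact line, coarser toward the axis
    v <- graded_seq(n_adherent + 1L, ratio = 1 / 4)[-1L]
    r_adh <- a * (1 - v)
    cell_contour(c(r, r_adh), c(z, rep(0, length(r_adh))),
                 contact_index = n_free)
  }
  # the polygonal contour encloses slightly less than the smooth cap;
  # inflate the radius so the discrete volume is exact (nodes stay on a
  # sphere, keeping curvature clean at any resolution)
  g <- function(R) measure_contour(build(R))$volume - V_target
  R <- stats::uniroot(g, c(R_geom, R_geom * 1.05), tol = 1e-12 * R_geom,
                      extendInt = "upX")$root
  build(R)
}

#' Surface area and enclosed volume of a contour
#'
#' Area is the full surface of revolution `2 pi int r ds` over the whole
#' contour -- free surface plus adherent disc, the total-cortex convention
#' used by the tension law.  Volume is the axisymmetric volume of revolution
#' `-pi int r^2 dz`.
#'
#' @param c0 a `cell_contour`.
#' @return list with `surface_area` (um^2), `volume` (um^3) and
#'   `free_area` (um^2, free surface only).
#' @export
measure_contour <- function(c0) {
  n <- length(c0$r)
  if (n < 3) stop("degenerate contour (need >= 3 nodes)", call. = FALSE)
  if (!is_simple_contour(c0)) stop("contour is self-intersecting",
                                   call. = FALSE)
  r <- c0$r; z <- c0$z
  ds <- sqrt(diff(r)^2 + diff(z)^2)
  rmid <- (r[-1] + r[-n]) / 2
  seg_area <- 2 * pi * rmid * ds
  area <- sum(seg_area)
  ci <- c0$contact_index
  free_area <- sum(seg_area[seq_len(ci - 1L)])
  vol <- -pi * sum((r[-1]^2 + r[-n]^2) / 2 * diff(z))
  list(surface_area = area, volume = vol, free_area = free_area)
}

# raw unit tangents/normals on the free part (1..contact_index) from local
# quadratic fits of r(s), z(s); outward normal is the tangent rotated -90 deg
contour_normals <- function(c0) {
  ci <- c0$contact_index
  r <- c0$r[1:ci]; z <- c0$z[1:ci]; s <- c0$s[1:ci]
  tr <- local_polyfit(s, r, w = 5L, degree = 2L)$dy
  tz <- local_polyfit(s, z, w = 5L, degree = 2L)$dy
  nrm <- sqrt(tr^2 + tz^2)
  tr <- tr / nrm; tz <- tz / nrm
  nr <- -tz; nz <- tr
  # apex: the outward normal is exactly vertical by symmetry
  nr[1] <- 0; nz[1] <- 1
  list(nr = nr, nz = nz, tr = tr, tz = tz)
}

# normal angle phi (from the +z axis) on the free part, unwrapped to be
# continuous along the contour
contour_phi <- function(c0) {
  nrm <- contour_normals(c0)
  phi <- atan2(nrm$nr, nrm$nz)
  dphi <- diff(phi)
  jump <- round(dphi / (2 * pi))
  phi - c(0, cumsum(jump)) * 2 * pi
}

# local least-squares polynomial fit of y(s): returns fitted values and first
# derivative at each node, window w nodes (clamped at the ends), degree 3
local_polyfit <- function(s, y, w = 7L, degree = 3L) {
  m <- length(s)
  yf <- numeric(m); dyf <- numeric(m)
  h <- w %/% 2L
  for (i in seq_len(m)) {
    lo <- max(1L, i - h); hi <- min(m, i + h)
    if (hi - lo + 1L < w) {
      if (lo == 1L) hi <- min(m, w) else lo <- max(1L, m - w + 1L)
    }
    ss <- s[lo:hi] - s[i]
    deg <- min(degree, length(ss) - 1L)
    X <- outer(ss, 0:deg, `^`)
    cf <- tryCatch(qr.coef(qr(X), y[lo:hi]), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) {
      yf[i] <- y[i]; dyf[i] <- NA_real_
    } else {
      yf[i] <- cf[1]; dyf[i] <- cf[2]
    }
  }
  list(y = yf, dy = dyf)
}

#' Mean curvature along the free contour
#'
#' Returns the mean curvature `dphi/ds + sin(phi)/r` at every node of the
#' free surface (apex through contact line), with `phi` the angle of the
#' outward normal obtained from local cubic polynomial fits in arc length.
#' On the axis the `sin(phi)/r` term is replaced by its symmetric limit
#' `dphi/ds`, so the apex curvature is `2 dphi/ds`.
#'
#' @param c0 a `cell_contour` with at least 5 free-surface nodes.
#' @param window fitting window (nodes) for the cubic fits.
#' @return numeric vector of curvatures (um^-1), length `contact_index`.
#' @export
compute_curvature <- function(c0, window = 7L) {
  ci <- c0$contact_index
  if (ci < 5L) stop("need at least 5 free-surface nodes", call. = FALSE)
  r <- c0$r[1:ci]; s <- c0$s[1:ci]
  if (any(r[-1] <= 0)) stop("free node on the axis off-apex (r = 0)",
                            call. = FALSE)
  phi <- contour_phi(c0)
  fit <- local_polyfit(s, phi, w = window)
  phi_f <- fit$y; dphi <- fit$dy
  H <- numeric(ci)
  H[1] <- 2 * dphi[1]
  H[-1] <- dphi[-1] + sin(phi_f[-1]) / r[-1]
  H
}

#' Smooth the free part of a contour
#'
#' Local least-squares cubic (Savitzky-Golay style, 5-node window in arc
#' length) applied to r(s) and z(s) on the interior free nodes.  The apex,
#' the contact-line node and all adherent nodes are left unchanged.
#'
#' @param c0 a `cell_contour`.
#' @param window smoothing window (nodes).
#' @return the smoothed `cell_contour`, with attribute `max_displacement`.
#' @export
smooth_contour <- function(c0, window = 5L) {
  ci <- c0$contact_index
  if (ci <= window) return(structure(c0, max_displacement = 0))
  s <- c0$s[1:ci]
  rs <- local_polyfit(s, c0$r[1:ci], w = window)$y
  zs <- local_polyfit(s, c0$z[1:ci], w = window)$y
  r <- c0$r; z <- c0$z
  idx <- 2:(ci - 1L)
  disp <- sqrt((rs[idx] - r[idx])^2 + (zs[idx] - z[idx])^2)
  r[idx] <- pmax(rs[idx], 0)
  z[idx] <- pmax(zs[idx], 0)
  out <- cell_contour(r, z, ci, validate = FALSE)
  attr(out, "max_displacement") <- if (length(disp)) max(disp) else 0
  out
}

#' Correct the enclosed volume of a contour
#'
#' Displaces all free-surface nodes by a single distance along their local
#' outward normals, chosen by 1-D root finding so that the enclosed volume
#' matches `V_target` to 1e-6 relative.  Contact-line and adherent nodes are
#' unchanged.  Drift larger than 5% signals a solver bug and raises an error.
#'
#' @param c0 a `cell_contour`.
#' @param V_target target volume (um^3).
#' @return the corrected `cell_contour`.
#' @export
correct_volume <- function(c0, V_target) {
  V <- measure_contour(c0)$volume
  rel <- (V - V_target) / V_target
  if (abs(rel) > 0.05)
    stop(sprintf("volume drift %.2f%% exceeds the 5%% correction limit",
                 100 * rel), call. = FALSE)
  if (abs(rel) < 1e-12) return(c0)
  ci <- c0$contact_index
  nrm <- contour_normals(c0)
  idx <- seq_len(ci - 1L)
  shape <- function(d) {
    r <- c0$r; z <- c0$z
    r[idx] <- pmax(r[idx] + d * nrm$nr[idx], 0)
    z[idx] <- pmax(z[idx] + d * nrm$nz[idx], 0)
    r[1] <- 0
    cell_contour(r, z, ci, validate = FALSE)
  }
  A_free <- measure_contour(c0)$free_area
  d0 <- -(V - V_target) / A_free       # first-order estimate
  lo <- min(2.5 * d0, -abs(d0)); hi <- max(2.5 * d0, abs(d0))
  g <- function(d) measure_contour(shape(d))$volume - V_target
  while (g(lo) > 0) lo <- lo * 2
  while (g(hi) < 0) hi <- hi * 2
  d <- stats::uniroot(g, c(lo, hi), tol = 1e-9 * abs(d0) + 1e-15)$root
  out <- shape(d)
  validate_contour(out)
  out
}

#' Redistribute contour nodes along arc length
#'
#' Resamples the free surface to `n_free` nodes with spacing graded finer
#' toward the contact line (cubic-spline interpolation of r(s), z(s)) and the
#' adherent disc to `n_adherent` nodes graded finer near the contact line.
#' Apex, contact-line position and contact radius are preserved.
#'
#' @param c0 a `cell_contour`.
#' @param n_free,n_adherent node counts after resampling.
#' @param grade free-surface spacing ratio (apex to contact line).
#' @return the resampled `cell_contour`.
#' @export
resample_contour <- function(c0, n_free = NULL, n_adherent = NULL, grade = 8) {
  ci <- c0$contact_index
  n <- length(c0$r)
  if (is.null(n_free)) n_free <- ci
  if (is.null(n_adherent)) n_adherent <- n - ci
  s <- c0$s[1:ci]
  fr <- stats::splinefun(s, c0$r[1:ci], method = "natural")
  fz <- stats::splinefun(s, c0$z[1:ci], method = "natural")
  s_new <- c0$s_contact * graded_seq(n_free, ratio = grade)
  r <- pmax(fr(s_new), 0)
  z <- pmax(fz(s_new), 0)
  r[1] <- 0
  a <- c0$r[ci]
  r[n_free] <- a; z[n_free] <- 0
  v <- graded_seq(n_adherent + 1L, ratio = 1 / 4)[-1L]
  r_adh <- a * (1 - v)
  cell_contour(c(r, r_adh), c(z, rep(0, length(r_adh))),
               contact_index = n_free, validate = FALSE)
}
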