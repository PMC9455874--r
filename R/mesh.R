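#' Body-fitted quadrilateral mesh of the cell cross-section
#'
#' Builds a logically rectangular quad mesh of the half cross-section
#' (r >= 0).  One grid family follows the free contour from the contact
#' line to the apex; the transversal family connects each free-surface node
#' to a point on the symmetry axis at matched arc fraction, so the first
#' transversal is exactly the adherent disc and the last degenerates onto
#' the axis below the apex.  Layer thicknesses are geometrically graded
#' toward the cell surface, which packs elements toward the flat substrate
#' in the contact region where the transversals are short.  The
#' construction is deterministic: identical contour and settings give a
#' bit-identical mesh.
#'
#' @param c0 a [cell_contour()].
#' @param layers number of element layers between the surface and the axis.
#' @param grade geometric grading factor of consecutive layer thicknesses
#'   toward the cell surface.
#' @return An object of class `phago_mesh`: list with `coords` (N x 2, um),
#'   `elems` (E x 4, counterclockwise), boundary node sets
#'   (`free_nodes` ordered contact-to-apex, `adherent_nodes`, `axis_nodes`),
#'   `free_edges`, the free-node-to-contour index map `contour_index`,
#'   `h_mesh` (mean sqrt element area, um), per-element `elem_size`, and
#'   grid dims.
#' @export
generate_mesh <- function(c0, layers = 12L, grade = 1.15) {
  ci <- c0$contact_index
  m <- ci                       # transversal count = free-surface nodes
  q <- as.integer(layers)
  if (q < 2L) stop("need at least 2 layers", call. = FALSE)

  # heads: free surface reversed (j = 1 at the contact line)
  Or <- rev(c0$r[1:ci]); Oz <- rev(c0$z[1:ci])
  s_out <- c(0, cumsum(sqrt(diff(Or)^2 + diff(Oz)^2)))
  u_out <- s_out / s_out[m]

  # feet: on the axis, height proportional to the head's arc fraction;
  # the j = 1 transversal is the adherent disc, the j = m one a short
  # axis segment below the apex
  z_apex <- c0$z[1]
  delta_top <- c0$s[2] - c0$s[1]
  Fz <- u_out * max(z_apex - delta_top, 0.5 * z_apex)

  # layer positions: eta = 0 on the surface, graded coarser inward
  u <- graded_seq(q + 1L, ratio = grade^(q - 1L))
  eta <- rev(1 - u)

  np <- q + 1L
  J <- rep(seq_len(m), each = np)
  I <- rep(seq_len(np), times = m)
  e <- eta[I]
  X <- Or[J] * (1 - e)                   # foot r = 0
  Z <- Oz[J] + e * (Fz[J] - Oz[J])
  coords <- cbind(r = X, z = Z)
  idx <- function(j, i) (j - 1L) * np + i

  jj <- rep(seq_len(m - 1L), each = q)
  ii <- rep(seq_len(q), times = m - 1L)
  elems <- cbind(idx(jj, ii), idx(jj, ii + 1L),
                 idx(jj + 1L, ii + 1L), idx(jj + 1L, ii))
  ar <- quad_signed_area(coords, elems)
  if (mean(ar < 0) > 0.5) {              # consistent CCW orientation
    elems <- elems[, 4:1]
    ar <- -ar
  }
  jac_ok <- quad_jacobian_positive(coords, elems)
  if (!all(jac_ok)) {
    # local folds can appear when the free surface hugs the substrate;
    # a few Laplacian sweeps on the interior nodes usually untangle them
    interior <- J > 1L & J < m & I > 1L & I < np
    nb <- cbind(idx(pmax(J - 1L, 1L), I), idx(pmin(J + 1L, m), I),
                idx(J, pmax(I - 1L, 1L)), idx(J, pmin(I + 1L, np)))
    for (sweep in 1:30) {
      Xn <- (coords[nb[, 1], ] + coords[nb[, 2], ] +
             coords[nb[, 3], ] + coords[nb[, 4], ]) / 4
      coords[interior, ] <- Xn[interior, ]
      jac_ok <- quad_jacobian_positive(coords, elems)
      if (all(jac_ok)) break
    }
  }
  if (!all(jac_ok)) {
    b <- which(!jac_ok)[1]
    stop(sprintf("mesh generation failed: %d inverted element(s), first near r = %.3f, z = %.3f (tangled contour?)",
                 sum(!jac_ok), mean(coords[elems[b, ], 1]),
                 mean(coords[elems[b, ], 2])), call. = FALSE)
  }

  free_nodes <- idx(seq_len(m), 1L)                 # contact -> apex
  adherent_nodes <- idx(1L, seq_len(np))            # the contact disc
  axis_nodes <- unique(c(idx(seq_len(m), np),       # feet
                         idx(m, seq_len(np))))      # apex transversal
  free_edges <- cbind(free_nodes[-m], free_nodes[-1L])

  esize <- sqrt(abs(ar))
  structure(list(
    coords = coords, elems = elems,
    free_nodes = free_nodes, adherent_nodes = adherent_nodes,
    axis_nodes = axis_nodes, free_edges = free_edges,
    contour_index = ci:1,        # contour node of free_nodes[j]
    h_mesh = mean(esize), elem_size = esize,
    dims = c(m = m, layers = q)), class = "phago_mesh")
}

# signed areas of bilinear quads (shoelace on corners)
quad_signed_area <- function(coords, elems) {
  x <- matrix(coords[elems, 1], ncol = 4)
  y <- matrix(coords[elems, 2], ncol = 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
         (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
         (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

# Jacobians of each bilinear quad at the 2x2 Gauss points must be positive
# (this is where the FEM evaluates them; near-apex quads legitimately have
# a zero corner Jacobian where the grid collapses onto the symmetry axis)
quad_jacobian_positive <- function(coords, elems, tol = 0) {
  x <- matrix(coords[elems, 1], ncol = 4)
  y <- matrix(coords[elems, 2], ncol = 4)
  g <- 1 / sqrt(3)
  ok <- rep(TRUE, nrow(elems))
  for (gp in list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))) {
    d <- quad_dshape(gp[1], gp[2])
    jrr <- x %*% d$dxi; jrz <- x %*% d$deta
    jzr <- y %*% d$dxi; jze <- y %*% d$deta
    detJ <- jrr * jze - jrz * jzr
    ok <- ok & (as.numeric(detJ) > tol)
  }
  ok
}

# bilinear shape functions and reference derivatives on [-1,1]^2,
# corner order (-1,-1), (1,-1), (1,1), (-1,1)
quad_shape <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}
quad_dshape <- function(xi, eta) {
  list(dxi  = c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
       deta = c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

#' @export
print.phago_mesh <- function(x, ...) {
  cat(sprintf(
    "phago_mesh: %d nodes, %d quad elements (%d x %d), h_mesh = %.3f um\n",
    nrow(x$coords), nrow(x$elems), x$dims[1] - 1L, x$dims[2], x$h_mesh))
  invisible(x)
}
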