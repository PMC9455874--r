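#' Stabilisation bound for the perturbed Stokes system
#'
#' The incompressibility constraint is relaxed to
#' `div(v - epsilon grad p) = 0`; accuracy requires
#' `epsilon <= h_mesh^2 / (2 mu)`, which is also the solver default.
#'
#' @param h_mesh characteristic element radius (um).
#' @param mu viscosity (Pa s).
#' @return the bound (um^2 / (Pa s)).
#' @export
epsilon_bound <- function(h_mesh, mu) h_mesh^2 / (2 * mu)

#' Solver settings for the Uzawa iteration
#'
#' @param epsilon perturbation parameter; `NULL` means use
#'   [epsilon_bound()] of the mesh at hand.
#' @param uzawa_tol relative pressure-convergence criterion
#'   `max|p - p_est| / max|p - p_out|`.
#' @param max_iterations iteration cap before a non-convergence error.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(epsilon = NULL, uzawa_tol = 1e-6,
                            max_iterations = 500L) {
  stopifnot(uzawa_tol > 0, max_iterations >= 1)
  structure(list(epsilon = epsilon, uzawa_tol = uzawa_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "solver_settings")
}

#' Assemble the axisymmetric perturbed-Stokes finite element system
#'
#' Bilinear (Q1) quadrilateral elements for velocity and pressure with 2x2
#' Gauss quadrature and the axisymmetric volume weight r.  Produces the
#' viscous stiffness A (including the hoop strain term), the
#' pressure-divergence coupling G, pressure mass and stiffness matrices,
#' and the boundary traction load on the free surface.  Velocity boundary
#' conditions: no-slip on the adherent disc, `v_r = 0` on the symmetry
#' axis, or an explicit Dirichlet table (used by verification problems).
#' The pressure carries the natural zero-normal-gradient condition.
#'
#' @param mesh a `phago_mesh` (or compatible list with `coords`, `elems`,
#'   `free_edges`, `adherent_nodes`, `axis_nodes`).
#' @param mu viscosity (Pa s).
#' @param epsilon perturbation parameter; `NULL` uses [epsilon_bound()].
#' @param traction list with per-contour-free-node stress components
#'   `sr`, `sz` (Pa, apex-to-contact order as produced by the constitutive
#'   layer), applied as the Neumann load on the free boundary; `NULL` for
#'   zero traction.
#' @param dirichlet optional data frame with columns `node`, `vr`, `vz`
#'   (NA = unconstrained) replacing the default boundary conditions.
#' @return A list of operators used by [uzawa_solve()] and
#'   [direct_stokes_solve()].
#' @export
assemble_stokes <- function(mesh, mu, epsilon = NULL, traction = NULL,
                            dirichlet = NULL) {
  coords <- mesh$coords
  elems <- mesh$elems
  N <- nrow(coords)
  E <- nrow(elems)
  if (is.null(epsilon)) epsilon <- epsilon_bound(mesh$h_mesh, mu)

  xs <- matrix(coords[elems, 1], ncol = 4)
  ys <- matrix(coords[elems, 2], ncol = 4)
  g <- 1 / sqrt(3)
  gps <- list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))

  n_pair <- 16L * E
  iA <- integer(0); jA <- integer(0)
  # accumulate per gauss point into dense E x 16 arrays, then flatten
  Arr <- matrix(0, E, 16); Azz <- matrix(0, E, 16)
  Arz <- matrix(0, E, 16); Azr <- matrix(0, E, 16)
  Gr <- matrix(0, E, 16); Gz <- matrix(0, E, 16)
  Mpv <- matrix(0, E, 16); Kpv <- matrix(0, E, 16)

  for (gp in gps) {
    sh <- quad_shape(gp[1], gp[2])
    d <- quad_dshape(gp[1], gp[2])
    jrr <- as.numeric(xs %*% d$dxi); jrz <- as.numeric(xs %*% d$deta)
    jzr <- as.numeric(ys %*% d$dxi); jze <- as.numeric(ys %*% d$deta)
    detJ <- jrr * jze - jrz * jzr
    if (any(detJ <= 0)) stop("non-positive Jacobian in assembly",
                             call. = FALSE)
    rg <- as.numeric(xs %*% sh)
    w <- detJ * rg
    dNr <- matrix(0, E, 4); dNz <- matrix(0, E, 4)
    for (a in 1:4) {
      dNr[, a] <- (d$dxi[a] * jze - d$deta[a] * jzr) / detJ
      dNz[, a] <- (-d$dxi[a] * jrz + d$deta[a] * jrr) / detJ
    }
    k <- 0L
    for (b in 1:4) for (a in 1:4) {
      k <- k + 1L
      Na <- sh[a]; Nb <- sh[b]
      Arr[, k] <- Arr[, k] + 2 * mu * w *
        (dNr[, a] * dNr[, b] + 0.5 * dNz[, a] * dNz[, b] +
         Na * Nb / rg^2)
      Azz[, k] <- Azz[, k] + 2 * mu * w *
        (dNz[, a] * dNz[, b] + 0.5 * dNr[, a] * dNr[, b])
      Arz[, k] <- Arz[, k] + mu * w * dNz[, a] * dNr[, b]
      Azr[, k] <- Azr[, k] + mu * w * dNr[, a] * dNz[, b]
      Gr[, k] <- Gr[, k] + w * (dNr[, a] + Na / rg) * Nb
      Gz[, k] <- Gz[, k] + w * dNz[, a] * Nb
      Mpv[, k] <- Mpv[, k] + w * Na * Nb
      Kpv[, k] <- Kpv[, k] + w * (dNr[, a] * dNr[, b] + dNz[, a] * dNz[, b])
    }
  }

  ia <- matrix(0L, E, 16); jb <- matrix(0L, E, 16)
  k <- 0L
  for (b in 1:4) for (a in 1:4) {
    k <- k + 1L
    ia[, k] <- elems[, a]
    jb[, k] <- elems[, b]
  }
  ii <- as.integer(ia); jj <- as.integer(jb)

  A <- Matrix::sparseMatrix(
    i = c(2 * ii - 1L, 2 * ii, 2 * ii - 1L, 2 * ii),
    j = c(2 * jj - 1L, 2 * jj, 2 * jj, 2 * jj - 1L),
    x = c(as.numeric(Arr), as.numeric(Azz),
          as.numeric(Arz), as.numeric(Azr)),
    dims = c(2 * N, 2 * N))
  G <- Matrix::sparseMatrix(
    i = c(2 * ii - 1L, 2 * ii), j = c(jj, jj),
    x = c(as.numeric(Gr), as.numeric(Gz)), dims = c(2 * N, N))
  Mp <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(Mpv),
                             dims = c(N, N))
  Kp <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(Kpv),
                             dims = c(N, N))

  # Neumann traction on the free boundary
  f <- numeric(2 * N)
  if (!is.null(traction) && !is.null(mesh$free_edges) &&
      nrow(mesh$free_edges) > 0) {
    ctr <- mesh$contour_index           # contour node of free_nodes[j]
    # per-free-boundary-node stresses in mesh free_nodes order
    sr <- traction$sr[ctr]; sz <- traction$sz[ctr]
    fe <- mesh$free_edges
    o <- match(fe, mesh$free_nodes)
    o1 <- o[seq_len(nrow(fe))]; o2 <- o[nrow(fe) + seq_len(nrow(fe))]
    p1r <- coords[fe[, 1], 1]; p1z <- coords[fe[, 1], 2]
    p2r <- coords[fe[, 2], 1]; p2z <- coords[fe[, 2], 2]
    L <- sqrt((p2r - p1r)^2 + (p2z - p1z)^2)
    for (t in (1 + c(-g, g)) / 2) {
      rq <- (1 - t) * p1r + t * p2r
      gr <- (1 - t) * sr[o1] + t * sr[o2]
      gz <- (1 - t) * sz[o1] + t * sz[o2]
      wq <- L / 2 * rq
      f[2 * fe[, 1] - 1L] <- f[2 * fe[, 1] - 1L] + (1 - t) * gr * wq
      f[2 * fe[, 1]] <- f[2 * fe[, 1]] + (1 - t) * gz * wq
      f[2 * fe[, 2] - 1L] <- f[2 * fe[, 2] - 1L] + t * gr * wq
      f[2 * fe[, 2]] <- f[2 * fe[, 2]] + t * gz * wq
    }
  }

  # Dirichlet dofs
  if (is.null(dirichlet)) {
    adn <- mesh$adherent_nodes
    axn <- setdiff(mesh$axis_nodes, adn)
    fixed <- c(2 * adn - 1L, 2 * adn, 2 * axn - 1L)
    vals <- numeric(length(fixed))
  } else {
    fixed <- integer(0); vals <- numeric(0)
    dr <- !is.na(dirichlet$vr)
    fixed <- c(fixed, 2 * dirichlet$node[dr] - 1L)
    vals <- c(vals, dirichlet$vr[dr])
    dz <- !is.na(dirichlet$vz)
    fixed <- c(fixed, 2 * dirichlet$node[dz])
    vals <- c(vals, dirichlet$vz[dz])
  }
  keep <- !duplicated(fixed)
  fixed <- fixed[keep]; vals <- vals[keep]
  free <- setdiff(seq_len(2 * N), fixed)

  list(A = A, G = G, Mp = Mp, Kp = Kp, f = f,
       free_dofs = free, fixed_dofs = fixed, fixed_vals = vals,
       mu = mu, epsilon = epsilon, N = N, mesh = mesh)
}

# solution container
new_flowfield <- function(vr, vz, p, iterations, residual, div_norm) {
  structure(list(vr = vr, vz = vz, p = p, iterations = iterations,
                 residual = residual, div_norm = div_norm),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "flow_field: max |v| = %.4g um/s, p in [%.4g, %.4g] Pa, %d iteration(s), residual %.2e\n",
    max(sqrt(x$vr^2 + x$vz^2)), min(x$p), max(x$p), x$iterations,
    x$residual))
  invisible(x)
}

# weak L2 norm of div(v) (used by the stabilisation-consistency checks)
divergence_norm <- function(sys, v_full) {
  d <- as.numeric(Matrix::crossprod(sys$G, v_full))
  sqrt(abs(sum(d * as.numeric(Matrix::solve(sys$Mp, d)))))
}

#' Weak divergence residual against a smooth test field
#'
#' Evaluates `| int q div(v) r dA |` for a smooth scalar field q(r, z)
#' (default q = z).  At the solver's fixed point this equals
#' `eps | int grad(q) . grad(p) r dA |`, so it shrinks linearly with the
#' stabilisation parameter; unlike the pointwise L2 divergence it is not
#' polluted by the stabilisation-limited small-scale pressure modes.
#'
#' @param sys operators from [assemble_stokes()].
#' @param flow a `flow_field` solved on them.
#' @param q per-node values of the test field; default the z coordinate.
#' @return the residual (um^3/s).
#' @export
divergence_residual <- function(sys, flow, q = sys$mesh$coords[, 2]) {
  v <- numeric(2 * sys$N)
  v[seq(1, 2 * sys$N, 2)] <- flow$vr
  v[seq(2, 2 * sys$N, 2)] <- flow$vz
  d <- as.numeric(Matrix::crossprod(sys$G, v))
  abs(sum(q * d))
}

#' Solve the perturbed Stokes system by Uzawa alternation
#'
#' Alternates a velocity solve at frozen pressure with a stabilised
#' pressure update at frozen velocity until the relative pressure change
#' `max|p - p_est| / max|p - p_out|` drops below the tolerance.  Both
#' subproblems are symmetric positive definite and are factorised once.
#'
#' @param sys operators from [assemble_stokes()].
#' @param p_init initial pressure estimate (per mesh node, Pa); `NULL`
#'   means uniform `p_out`.
#' @param settings a [solver_settings()].
#' @param p_out external pressure reference (Pa).
#' @return A `flow_field` with per-node `vr`, `vz` (um/s), `p` (Pa),
#'   iteration count, final residual and weak divergence norm.
#' @export
uzawa_solve <- function(sys, p_init = NULL, settings = solver_settings(),
                        p_out = 0) {
  N <- sys$N
  eps <- if (is.null(settings$epsilon)) sys$epsilon else settings$epsilon
  Fd <- sys$free_dofs; Dd <- sys$fixed_dofs
  A_ff <- Matrix::forceSymmetric(sys$A[Fd, Fd])
  chA <- Matrix::Cholesky(A_ff, LDL = FALSE)
  P <- Matrix::forceSymmetric(sys$Mp / sys$mu + eps * sys$Kp)
  chP <- Matrix::Cholesky(P, LDL = FALSE)
  G_f <- sys$G[Fd, , drop = FALSE]
  v_full <- numeric(2 * N)
  v_full[Dd] <- sys$fixed_vals
  rhs_fix <- if (length(Dd))
    as.numeric(sys$A[Fd, Dd, drop = FALSE] %*% sys$fixed_vals) else 0
  p <- if (is.null(p_init)) rep(p_out, N) else p_init

  res <- Inf; it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    rhs_v <- sys$f[Fd] + as.numeric(G_f %*% p) - rhs_fix
    v_full[Fd] <- as.numeric(Matrix::solve(chA, rhs_v, system = "A"))
    rhs_p <- as.numeric(sys$Mp %*% p) / sys$mu -
      as.numeric(Matrix::crossprod(sys$G, v_full))
    p_new <- as.numeric(Matrix::solve(chP, rhs_p, system = "A"))
    denom <- max(abs(p_new - p_out))
    res <- if (denom < .Machine$double.eps) 0 else
      max(abs(p_new - p)) / denom
    p <- p_new
    if (res <= settings$uzawa_tol) break
  }
  if (res > settings$uzawa_tol) {
    stop(sprintf("Uzawa iteration did not converge in %d iterations (residual %.3e)",
                 settings$max_iterations, res), call. = FALSE)
  }
  vr <- v_full[seq(1, 2 * N, by = 2)]
  vz <- v_full[seq(2, 2 * N, by = 2)]
  ff <- new_flowfield(vr, vz, p, it, res, divergence_norm(sys, v_full))
  ff
}

#' Direct monolithic solve of the same perturbed system
#'
#' Solves the coupled velocity-pressure saddle system
#' `[A, -G; G', eps Kp] [v; p] = [f; 0]` with one sparse LU factorisation.
#' This is the reference the Uzawa alternation is verified against.
#'
#' @param sys operators from [assemble_stokes()].
#' @param pin_pressure pin pressure node 1 to this value when the velocity
#'   space is fully constrained (pure-Dirichlet problems, where the
#'   pressure is otherwise determined only up to a constant); `NULL` for
#'   no pinning.
#' @return A `flow_field`.
#' @export
direct_stokes_solve <- function(sys, pin_pressure = NULL) {
  N <- sys$N
  eps <- sys$epsilon
  Fd <- sys$free_dofs; Dd <- sys$fixed_dofs
  A_ff <- sys$A[Fd, Fd]
  G_f <- sys$G[Fd, , drop = FALSE]
  Gt <- Matrix::t(sys$G)
  rhs_fix <- if (length(Dd))
    as.numeric(sys$A[Fd, Dd, drop = FALSE] %*% sys$fixed_vals) else 0
  rhs_top <- sys$f[Fd] - rhs_fix
  rhs_bot <- if (length(Dd))
    -as.numeric(Gt[, Dd, drop = FALSE] %*% sys$fixed_vals) else numeric(N)
  M <- rbind(cbind(A_ff, -G_f),
             cbind(Matrix::t(G_f), eps * sys$Kp))
  rhs <- c(rhs_top, rhs_bot)
  if (!is.null(pin_pressure)) {
    k <- length(Fd) + 1L
    M[k, ] <- 0; M[k, k] <- 1
    rhs[k] <- pin_pressure
  }
  sol <- as.numeric(Matrix::solve(M, rhs))
  v_full <- numeric(2 * N)
  v_full[Dd] <- sys$fixed_vals
  v_full[Fd] <- sol[seq_along(Fd)]
  p <- sol[length(Fd) + seq_len(N)]
  vr <- v_full[seq(1, 2 * N, by = 2)]
  vz <- v_full[seq(2, 2 * N, by = 2)]
  new_flowfield(vr, vz, p, 1L, 0, divergence_norm(sys, v_full))
}
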