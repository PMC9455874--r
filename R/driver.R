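#' Configuration of a spreading simulation
#'
#' @param variant one of `"brownian"` (passive, adhesion-driven),
#'   `"protrusive_continuum"` (active protrusion, optional continuum
#'   adhesion) or `"protrusive_discrete"` (active protrusion with discrete
#'   binding-site rings and time-decaying protrusion).
#' @param params a [physical_params()]; by default the passive viscosity
#'   (200 Pa s) is used for the Brownian variant and the active one
#'   (1660 Pa s) otherwise.
#' @param rho_rel relative ligand density (%) for continuum adhesion;
#'   the protrusion-only reference case uses 0.
#' @param rho_l absolute site density (um^-2) for the discrete variant.
#' @param t_end end time (s).
#' @param n_free,n_adherent,layers resolution: free-surface nodes,
#'   adherent-disc nodes, mesh layers.
#' @param contour_grade,mesh_grade node/layer grading factors.
#' @param footprint_area initial contact footprint (um^2).
#' @param courant_fraction,dt_max time-step control (see
#'   [compute_timestep()]).
#' @param solver a [solver_settings()].
#' @param plateau_stop stop early when the contact-area growth rate stays
#'   below `plateau_rate` (um^2/s) over `plateau_window` (s).
#' @param lattice_offset lateral shift of the discrete site lattice (um).
#' @param max_steps hard cap on step count.
#' @param verbose print progress every so many steps (0 = quiet).
#' @return object of class `run_config`.
#' @export
run_config <- function(variant = c("brownian", "protrusive_continuum",
                                   "protrusive_discrete"),
                       params = NULL,
                       rho_rel = if (variant == "protrusive_continuum") 0 else 100,
                       rho_l = 1000,
                       t_end = 300,
                       n_free = 60L, n_adherent = 10L, layers = 10L,
                       contour_grade = 8, mesh_grade = 1.15,
                       footprint_area = 0.05,
                       courant_fraction = 0.1, dt_max = 0.5,
                       solver = solver_settings(),
                       plateau_stop = TRUE, plateau_rate = 0.01,
                       plateau_window = 20,
                       lattice_offset = 0,
                       max_steps = 100000L,
                       verbose = 0L) {
  variant <- match.arg(variant)
  if (is.null(params)) {
    params <- physical_params(mu = if (variant == "brownian") 200 else 1660)
  }
  structure(list(variant = variant, params = params, rho_rel = rho_rel,
                 rho_l = rho_l, t_end = t_end,
                 n_free = as.integer(n_free),
                 n_adherent = as.integer(n_adherent),
                 layers = as.integer(layers),
                 contour_grade = contour_grade, mesh_grade = mesh_grade,
                 footprint_area = footprint_area,
                 courant_fraction = courant_fraction, dt_max = dt_max,
                 solver = solver, plateau_stop = plateau_stop,
                 plateau_rate = plateau_rate,
                 plateau_window = plateau_window,
                 lattice_offset = lattice_offset,
                 max_steps = as.integer(max_steps),
                 verbose = as.integer(verbose)),
            class = "run_config")
}

#' Initial simulation state
#'
#' Spherical-cap cell resting on the substrate with a small contact
#' footprint; reference areas, volume and the transitional contact area of
#' the protrusion law are fixed here for the whole run.
#'
#' @param cfg a [run_config()].
#' @return object of class `simulation_state`.
#' @export
simulation_state <- function(cfg) {
  p <- cfg$params
  c0 <- init_spherical_cap(p$cell_diameter, cfg$footprint_area,
                           n_free = cfg$n_free,
                           n_adherent = cfg$n_adherent,
                           grade = cfg$contour_grade)
  sites <- NULL
  if (cfg$variant == "protrusive_discrete") {
    sites <- adhesion_sites(cfg$rho_l, offset = cfg$lattice_offset,
                            r_max = 1.2 * p$cell_diameter,
                            r_bound0 = c0$r[c0$contact_index])
  }
  structure(list(
    time = 0, contour = c0, sites = sites, t_bind_latest = 0,
    p_prev = NULL,
    V0 = measure_contour(c0)$volume,
    A_cell0 = rest_area(p),
    A_c_trans = if (cfg$variant == "brownian") NA_real_
                else contact_area_trans(p),
    row = NULL), class = "simulation_state")
}

#' Advance the simulation by one full time step
#'
#' One cycle: curvature -> boundary stresses for the active variant ->
#' mesh -> Uzawa flow solve -> Courant time step -> contour advection
#' (with step rejection and halving on self-intersection) -> contact-line
#' update -> contour smoothing -> node redistribution -> volume
#' correction -> bookkeeping.
#'
#' @param state a `simulation_state`.
#' @param cfg the [run_config()].
#' @return the advanced `simulation_state`; the diagnostics of the step
#'   are in `$row` (one-row data frame).
#' @export
spread_step <- function(state, cfg) {
  p <- cfg$params
  c0 <- state$contour
  ci <- c0$contact_index
  meas <- measure_contour(c0)
  A_cell <- meas$surface_area
  a <- c0$r[ci]
  A_c <- pi * a^2
  ratio <- A_cell / state$A_cell0
  tau <- cortical_tension(A_cell, state$A_cell0, p)

  H <- compute_curvature(c0)
  ctx <- cortical_stress(c0, tau, H)
  tr <- list(sr = ctx$sr, sz = ctx$sz)
  sigma_prot <- 0
  if (cfg$variant != "protrusive_discrete" && cfg$rho_rel > 0) {
    ad <- adhesion_stress(c0, p, rho_rel = cfg$rho_rel)
    tr$sr <- tr$sr + ad$sr
    tr$sz <- tr$sz + ad$sz
  }
  if (cfg$variant != "brownian") {
    sigma_prot <- protrusion_magnitude(A_c, state$A_c_trans, ratio, p)
    if (cfg$variant == "protrusive_discrete") {
      sigma_prot <- protrusion_decay(sigma_prot, state$time,
                                     state$t_bind_latest, p)
    }
    pr <- protrusion_profile(c0, sigma_prot, p)
    tr$sr <- tr$sr + pr$sr
    tr$sz <- tr$sz + pr$sz
  }

  msh <- generate_mesh(c0, layers = cfg$layers, grade = cfg$mesh_grade)
  sys <- assemble_stokes(msh, mu = p$mu, traction = tr)
  p_init <- if (!is.null(state$p_prev) &&
                length(state$p_prev) == sys$N) state$p_prev else NULL
  flow <- uzawa_solve(sys, p_init = p_init, settings = cfg$solver,
                      p_out = p$p_out)

  dt <- compute_timestep(msh, flow, cfg$courant_fraction, cfg$dt_max)
  dt <- min(dt, cfg$t_end - state$time)
  c1 <- NULL
  for (try in 1:6) {
    cand <- advect(c0, flow, msh, dt)
    if (is_simple_contour(cand)) { c1 <- cand; break }
    dt <- dt / 2
  }
  if (is.null(c1)) stop("advection kept self-intersecting after 5 halvings",
                        call. = FALSE)

  n_bonds <- NA_integer_
  t_new <- state$time + dt
  sites <- state$sites
  t_bind <- state$t_bind_latest
  if (cfg$variant == "protrusive_discrete") {
    upd <- update_contact_discrete(c1, sites, tau, A_cell, t_new, p)
    c1 <- upd$contour
    sites <- upd$sites
    if (upd$n_new > 0) t_bind <- t_new
    n_bonds <- sum(sites$bound)
  } else {
    c1 <- update_contact_continuum(c1, p$contact_threshold)
  }

  c1 <- smooth_contour(c1)
  c1 <- resample_contour(c1, n_free = cfg$n_free,
                         n_adherent = cfg$n_adherent,
                         grade = cfg$contour_grade)
  c1 <- correct_volume(c1, state$V0)

  m2 <- measure_contour(c1)
  max_v <- max(sqrt(flow$vr^2 + flow$vz^2))
  row <- data.frame(
    t = t_new, dt = dt,
    A_c = pi * c1$r[c1$contact_index]^2,
    A_cell = m2$surface_area, V = m2$volume,
    tau = tau, sigma_prot = sigma_prot, n_bonds = n_bonds,
    uzawa_iters = flow$iterations, max_v = max_v,
    eps = sys$epsilon, h_mesh = msh$h_mesh)

  state$time <- t_new
  state$contour <- c1
  state$sites <- sites
  state$t_bind_latest <- t_bind
  state$p_prev <- flow$p
  state$row <- row
  state
}

#' Run a spreading simulation
#'
#' Initialises the spherical-cap cell and advances [spread_step()] until
#' the end time, the plateau criterion, or the step cap.  Deterministic
#' for a given configuration.
#'
#' @param cfg a [run_config()].
#' @return a `spreading_series`: a data frame with one row per step
#'   (t, dt, A_c, A_cell, V, tau, sigma_prot, n_bonds, solver
#'   diagnostics), with the configuration and final state attached as
#'   attributes.
#' @export
run_simulation <- function(cfg) {
  state <- simulation_state(cfg)
  rows <- vector("list", 2048L)
  nr <- 0L
  while (state$time < cfg$t_end && nr < cfg$max_steps) {
    state <- spread_step(state, cfg)
    nr <- nr + 1L
    if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[nr]] <- state$row
    if (cfg$verbose > 0 && nr %% cfg$verbose == 0) {
      message(sprintf("t = %7.2f s  A_c = %8.3f um^2  dt = %.4f", state$time,
                      state$row$A_c, state$row$dt))
    }
    if (cfg$plateau_stop && state$time > cfg$plateau_window) {
      df <- do.call(rbind, rows[seq_len(nr)])
      j <- findInterval(state$time - cfg$plateau_window, df$t)
      if (j >= 1) {
        rate <- (df$A_c[nr] - df$A_c[j]) / (df$t[nr] - df$t[j])
        if (rate < cfg$plateau_rate) break
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  attr(out, "config") <- cfg
  attr(out, "final_contour") <- state$contour
  attr(out, "final_sites") <- state$sites
  class(out) <- c("spreading_series", "data.frame")
  out
}

#' @export
print.spreading_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "spreading_series (%s): %d steps to t = %.1f s, A_c %.2f -> %.2f um^2\n",
    if (is.null(cfg)) "?" else cfg$variant, nrow(x), max(x$t),
    x$A_c[1], x$A_c[nrow(x)]))
  invisible(x)
}

#' Discrete-site ensemble over lattice shifts
#'
#' Runs the discrete-adhesion variant several times with the binding-site
#' lattice shifted laterally by even fractions of the site spacing, and
#' averages the contact-area histories on a common time grid.
#'
#' @param cfg a [run_config()] with `variant = "protrusive_discrete"`.
#' @param n_shifts number of lateral shifts (>= 2).
#' @param grid_n points of the common time grid.
#' @return list with `mean` (data frame t, A_c), `members` (list of
#'   `spreading_series`) and the `offsets` used.
#' @export
run_discrete_ensemble <- function(cfg, n_shifts = 5L, grid_n = 200L) {
  stopifnot(cfg$variant == "protrusive_discrete", n_shifts >= 2)
  spacing <- 1 / sqrt(cfg$rho_l)
  offsets <- spacing * (seq_len(n_shifts) - 1L) / n_shifts
  members <- vector("list", n_shifts)
  for (i in seq_len(n_shifts)) {
    cfg_i <- cfg
    cfg_i$lattice_offset <- offsets[i]
    members[[i]] <- tryCatch(run_simulation(cfg_i), error = function(e) e)
  }
  failed <- vapply(members, inherits, logical(1), "error")
  if (any(failed)) {
    if (sum(!failed) < 2) {
      stop("discrete ensemble: fewer than 2 members survived", call. = FALSE)
    }
    warning(sprintf("discrete ensemble: %d member(s) failed and were dropped",
                    sum(failed)), call. = FALSE)
    offsets <- offsets[!failed]
    members <- members[!failed]
  }
  t_max <- min(vapply(members, function(s) max(s$t), numeric(1)))
  tg <- seq(0, t_max, length.out = grid_n)
  Ac <- vapply(members, function(s) {
    stats::approx(c(0, s$t), c(s$A_c[1], s$A_c), xout = tg, rule = 2)$y
  }, numeric(grid_n))
  list(mean = data.frame(t = tg, A_c = rowMeans(Ac)),
       members = members, offsets = offsets)
}

#' Young-Dupre equilibrium check of a Brownian run
#'
#' Compares the final contact area of a plateaued Brownian-zipper run
#' against the equilibrium contact area predicted by the Young-Dupre
#' relation for the run's effective adhesion energy (the work of adhesion
#' of the continuum potential), and measures how closely the final free
#' contour approaches a spherical cap.
#'
#' @param series a `spreading_series` from a Brownian run.
#' @param cfg its [run_config()] (defaults to the one attached).
#' @return list with `status` ("ok" or "inconclusive"), the effective
#'   `gamma` (uJ/m^2), simulated and predicted contact areas, their
#'   relative deviation, and the cap-fit RMS deviation relative to the
#'   resting cell radius.
#' @export
equilibrium_check_brownian <- function(series, cfg = attr(series, "config")) {
  if (is.null(cfg) || cfg$variant != "brownian") {
    return(list(status = "inconclusive",
                reason = "not a Brownian-zipper run"))
  }
  n <- nrow(series)
  w <- series$t > max(series$t) - cfg$plateau_window
  rate <- if (sum(w) >= 2) {
    stats::coef(stats::lm(A_c ~ t, data = series[w, ]))[2]
  } else Inf
  if (!is.finite(rate) || rate > 2 * cfg$plateau_rate) {
    return(list(status = "inconclusive", reason = "no plateau reached",
                final_rate = unname(rate)))
  }
  p <- cfg$params
  gamma <- adhesion_work(p, cfg$rho_rel)
  V0 <- pi * p$cell_diameter^3 / 6
  A_pred <- young_dupre_area(gamma, V0, p)
  A_sim <- series$A_c[n]
  cf <- attr(series, "final_contour")
  capfit <- fit_spherical_cap(cf)
  list(status = "ok", gamma = gamma,
       A_c_sim = A_sim, A_c_youngdupre = A_pred,
       rel_deviation = (A_sim - A_pred) / A_pred,
       cap_rms = capfit$rms,
       cap_rms_rel = capfit$rms / (p$cell_diameter / 2),
       cap_R = capfit$R)
}

# least-squares sphere fit (centre on the axis) to the free contour
fit_spherical_cap <- function(c0) {
  ci <- c0$contact_index
  r <- c0$r[1:ci]; z <- c0$z[1:ci]
  # r^2 + z^2 = 2 z zc + (R^2 - zc^2): linear in (zc, c)
  y <- r^2 + z^2
  X <- cbind(2 * z, 1)
  cf <- qr.coef(qr(X), y)
  zc <- cf[1]; R <- sqrt(cf[2] + zc^2)
  res <- sqrt(r^2 + (z - zc)^2) - R
  list(R = unname(R), zc = unname(zc),
       rms = sqrt(mean(res^2)))
}
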