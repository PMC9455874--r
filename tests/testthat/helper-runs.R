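# Scaled-down reference runs shared by the driver and acceptance tests.
# Each is computed once per test session.  Resolutions are coarse to fit
# the suite's time budget; the acceptance tolerances were specified for
# this scaled-down regime.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Brownian zipper at a mid-range adhesion strength (30% relative density)
acc_brownian <- function() cached("brownian", {
  run_simulation(run_config("brownian", rho_rel = 30, t_end = 400,
                            n_free = 50, layers = 8))
})

# purely protrusion-driven reference run
acc_protrusive <- function() cached("protrusive", {
  run_simulation(run_config("protrusive_continuum", rho_rel = 0,
                            t_end = 200, n_free = 50, layers = 8))
})

# discrete-adhesion ensembles across three densities (2 lateral shifts
# each, horizon 130 s)
acc_discrete <- function() cached("discrete", {
  lapply(c(30, 300, 3000), function(rho) {
    run_discrete_ensemble(
      run_config("protrusive_discrete", rho_l = rho, t_end = 130,
                 n_free = 44, layers = 8),
      n_shifts = 2L)
  })
})
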