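# Shared fixtures and a per-session cache for expensive simulation runs.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# reference operating point: sigma2 = 3.33e4, S0 = 1, D3 = 2 D2 = 6,
# heights b1 = 2, b2 = 4, b4 = 14, b5 = 16, hole mouth a3 = 0.1
op_params <- function(shape, alpha, gamma, sigma2 = 3.33e4, S0 = 1) {
  dimensionless_params(sigma2 = sigma2, S0 = S0, D2 = 3, D3 = 6,
                       geometry = geometry_from_levels(shape, alpha, gamma))
}

# coarse "fast-profile" transient run, cached by its arguments
fast_run <- function(shape, alpha, gamma, sigma2 = 3.33e4, S0 = 1,
                     store = FALSE) {
  key <- paste("run", shape, alpha, gamma, sigma2, S0, store, sep = "|")
  cached(key, {
    params <- op_params(shape, alpha, gamma, sigma2, S0)
    mesh <- generate_mesh(params$geometry, h = 1, nr_hole = 3,
                          grading = c(interface = 0.8))
    problem <- build_problem(params, mesh)
    run_transient(problem, solver_config(dt = 0.02, t_max = 400,
                                         dt_growth = 1.08, dt_max = 4,
                                         store_states = store))
  })
}

# the documented 3x3 (alpha, gamma) property grid per shape, fast profile
property_grid <- function() {
  cached("property_grid",
         run_sweep(hole_shapes(),
                   alpha = c(0.92, 0.95, 0.98),
                   gamma = c(0.1, 0.5, 0.9),
                   base = default_config(profile = "fast")))
}

# tiny mesh for algebraic checks (Jacobian consistency etc.)
tiny_problem <- function(sigma2 = 50, S0 = 1) {
  key <- paste("tiny", sigma2, S0, sep = "|")
  cached(key, {
    spec <- geometry_from_levels("cone_up", 0.9, 0.5)
    mesh <- generate_mesh(spec, h = 4, nr_hole = 1)
    build_problem(dimensionless_params(sigma2, S0, 3, 6, spec), mesh)
  })
}
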