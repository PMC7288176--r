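test_that("the substrate Jacobian matches finite differences of the
           residual", {
  prob <- tiny_problem(sigma2 = 50)
  ops <- assemble_operators(prob)
  ns <- length(prob$s_nodes)
  set.seed(7)
  S <- runif(ns, 0.05, 0.9)
  Sp <- runif(ns, 0.05, 0.9)
  P <- numeric(prob$n_nodes)
  sys <- assemble_system(prob, ops, P, S, P, Sp, dt = 0.05, theta = 1)
  J <- as.matrix(sys$jac_S)
  eps <- 1e-7
  scale <- max(abs(J))
  cols <- seq(1, ns, by = max(1L, ns %/% 12))   # a spread of columns
  for (k in cols) {
    Sh <- S; Sh[k] <- Sh[k] + eps
    Sl <- S; Sl[k] <- Sl[k] - eps
    rh <- assemble_system(prob, ops, P, Sh, P, Sp, dt = 0.05)$res_S
    rl <- assemble_system(prob, ops, P, Sl, P, Sp, dt = 0.05)$res_S
    fd <- (rh - rl) / (2 * eps)
    expect_lt(max(abs(fd - J[, k])) / scale, 1e-6)
  }
})

test_that("constant fields with no reaction give zero residual; the exact
           linear steady profile is reproduced", {
  spec <- geometry_from_levels("cylinder", 0, 0.5)
  mesh <- generate_mesh(spec, h = 1, nr_hole = 1)
  pars <- dimensionless_params(0, 1, 3, 6, spec)
  prob <- build_problem(pars, mesh)
  ops <- assemble_operators(prob)
  ns <- length(prob$s_nodes)
  sys <- assemble_system(prob, ops, rep(0.7, prob$n_nodes), rep(0.3, ns),
                         dt = Inf)
  expect_lt(sys$res_free_ss, 1e-24)
  # sigma2 = 0 steady state: S relaxes to the uniform bulk value
  # (steady detection on the identically-zero current would stop after one
  # window, so run the full horizon)
  tr <- run_transient(prob, solver_config(dt = 0.1, t_max = 300,
                                          dt_growth = 1.1, dt_max = 5,
                                          ss_window = 301))
  expect_true(all(abs(tr$i_values) < 1e-13))   # no product is ever produced
  expect_equal(unname(tr$S), rep(1, ns), tolerance = 1e-3)
})

test_that("Newton converges in one iteration on a linear problem and meets
           the residual criterion on stiff ones", {
  # sigma2 = 0 removes the nonlinearity entirely
  spec <- geometry_from_levels("cone_up", 0.95, 0.5)
  mesh <- generate_mesh(spec, h = 2, nr_hole = 2)
  prob0 <- build_problem(dimensionless_params(0, 1, 3, 6, spec), mesh)
  tr0 <- run_transient(prob0, solver_config(dt = 0.05, t_max = 2))
  expect_true(all(tr0$newton_iters == 1L))
  expect_true(all(tr0$newton_rss <= 1e-7))
  # stiff toy slab: criterion still met at every accepted step
  tr <- fast_run("cylinder", 0.95, 0.5)
  expect_lte(tr$max_newton_rss, 1e-7)
  expect_true(tr$converged)
})

test_that("Newton iterates converge superlinearly on a fixed stiff step", {
  prob <- tiny_problem(sigma2 = 500)
  ops <- assemble_operators(prob)
  ns <- length(prob$s_nodes)
  dir_idx <- prob$s_index[prob$s_dirichlet$nodes]
  free <- setdiff(seq_len(ns), dir_idx)
  S_prev <- numeric(ns); S_prev[dir_idx] <- prob$params$S0
  S <- S_prev
  rss <- numeric(0)
  for (it in 1:6) {
    sys <- assemble_system(prob, ops, numeric(prob$n_nodes), S,
                           numeric(prob$n_nodes), S_prev, dt = 0.5)
    rss <- c(rss, sum(sys$res_S[free]^2))
    dS <- Matrix::solve(sys$jac_S[free, free], sys$res_S[free])
    S[free] <- S[free] - as.vector(dS)
  }
  # keep the pre-roundoff-floor part of the sequence
  rss <- rss[rss > 1e-24]
  expect_gte(length(rss), 2)
  ratios <- rss[-1] / rss[-length(rss)]
  # each iteration slashes the residual sum of squares by many orders of
  # magnitude -- far beyond any linearly convergent contraction
  expect_true(all(ratios < 1e-6))
})

test_that("substrate stays within physical bounds up to the documented
           overshoot tolerance and the late-time field is tight", {
  tr <- fast_run("paraboloid_up", 0.95, 0.5, store = TRUE)
  expect_gte(tr$S_range[1], -0.05)
  expect_lte(tr$S_range[2], 1 * (1 + 0.05) + 1e-12)
  # the steady field is much tighter than the worst transient excursion
  # (a small residual undershoot at the unresolved reaction front remains
  # on the coarse profile)
  expect_gte(min(tr$S), -1e-3)
  expect_lte(max(tr$S), 1 + 1e-6)
  expect_gte(min(tr$i_values), -1e-12 * max(tr$i_values))
})

test_that("the transient current rises monotonically to its plateau", {
  for (key in list(c("cylinder", 0.95, 0.5), c("cone_down", 0.92, 0.9))) {
    tr <- fast_run(key[1], as.numeric(key[2]), as.numeric(key[3]))
    di <- diff(tr$i_values)
    expect_true(all(di > -1e-9 * max(tr$i_values)), info = key[1])
  }
})

test_that("halving the time step leaves the steady current unchanged to
           0.1 percent", {
  params <- op_params("concave_paraboloid_up", 0.95, 0.5)
  mesh <- generate_mesh(params$geometry, h = 1, nr_hole = 3,
                        grading = c(interface = 0.8))
  prob <- build_problem(params, mesh)
  ops <- assemble_operators(prob)
  I1 <- run_transient(prob, solver_config(dt = 0.04, t_max = 80,
                                          store_states = FALSE), ops)$I
  I2 <- run_transient(prob, solver_config(dt = 0.02, t_max = 80,
                                          store_states = FALSE), ops)$I
  expect_lt(abs(I1 / I2 - 1), 1e-3)
})

test_that("backward Euler and Crank-Nicolson agree on the steady current", {
  spec <- geometry_from_levels("cylinder", 0.92, 0.5)
  pars <- dimensionless_params(100, 1, 3, 6, spec)
  mesh <- generate_mesh(spec, h = 1.5, nr_hole = 2)
  prob <- build_problem(pars, mesh)
  ops <- assemble_operators(prob)
  Ibe <- run_transient(prob, solver_config(dt = 0.05, t_max = 100,
                                           dt_growth = 1.05, dt_max = 1,
                                           store_states = FALSE), ops)$I
  Icn <- run_transient(prob, solver_config(dt = 0.05, t_max = 100,
                                           dt_growth = 1.05, dt_max = 1,
                                           scheme = "crank_nicolson",
                                           store_states = FALSE), ops)$I
  expect_lt(abs(Ibe / Icn - 1), 1e-3)
})

test_that("steady current self-converges in space at order >= 2 on the
           smooth open-cell case", {
  spec <- geometry_from_levels("cylinder", 0, 0.5)
  pars <- dimensionless_params(1, 1, 3, 6, spec)
  Is <- sapply(c(2, 1, 0.5), function(h)
    solve_steady(build_problem(pars, generate_mesh(spec, h = h,
                                                   nr_hole = 1)))$I)
  order <- log2(abs(Is[1] - Is[2]) / abs(Is[2] - Is[3]))
  expect_gte(order, 2)
})

test_that("direct steady solve agrees with the transient plateau", {
  spec <- geometry_from_levels("cone_up", 0.95, 0.5)
  pars <- op_params("cone_up", 0.95, 0.5)
  mesh <- generate_mesh(spec, h = 1, nr_hole = 3,
                        grading = c(interface = 0.8))
  prob <- build_problem(pars, mesh)
  st <- solve_steady(prob, max_iter = 100)
  tr <- fast_run("cone_up", 0.95, 0.5)
  # the trace stops once the window change is below eps_ss = 1e-4, so a
  # small gap to the true asymptote remains
  expect_lt(abs(st$I / tr$I - 1), 5e-3)
})
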