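test_that("Vmax and Km follow from the kinetic scheme", {
  expect_equal(derive_vmax_km(kinetic_scheme(1, 0, 1, 1)),
               c(Vmax = 1, Km = 1))
  expect_equal(derive_vmax_km(kinetic_scheme(2, 2, 2, 3)),
               c(Vmax = 6, Km = 2))
  a <- derive_vmax_km(kinetic_scheme(2, 1, 4, 5))
  b <- derive_vmax_km(kinetic_scheme(1, 1, 4, 5))   # halve k1
  expect_equal(b[["Km"]], 2 * a[["Km"]])
  expect_equal(b[["Vmax"]], a[["Vmax"]])
  expect_error(kinetic_scheme(-1, 0, 1, 1), "k1")
})

test_that("nondimensionalization matches the defining scales and inverts", {
  p <- dimensional_params(D1s = 1, D2s = 3, D3s = 6,
                          a1s = 2, a2s = 0.1, a3s = 0.2,
                          b1s = 4, b2s = 8, b3s = 18, b4s = 28, b5s = 32,
                          S0s = 2, Vmax = 1, Km = 1, ne = 2)
  dl <- nondimensionalize(p)
  expect_equal(dl$sigma2, 4)                        # Vmax a1^2 / (Km D1)
  expect_equal(dl$S0, 2)
  expect_equal(dl$D2, 3); expect_equal(dl$D3, 6)
  expect_equal(dl$geometry$a2, 0.05)
  expect_equal(with(dl$geometry, c(b1, b2, b3, b4, b5)), c(2, 4, 9, 14, 16))
  # identity scaling leaves ratios untouched
  p2 <- dimensional_params(D1s = 1, D2s = 1, D3s = 1, a1s = 1,
                           a2s = 0.5, a3s = 0.5, b1s = 2, b2s = 4, b3s = 9,
                           b4s = 14, b5s = 16, S0s = 1, Vmax = 1, Km = 1)
  expect_equal(nondimensionalize(p2)$D2, 1)
  # the reference operating point sigma2 = 3.33e4 via Vmax/Km choice
  p3 <- dimensional_params(D1s = 3e-6, D2s = 9e-6, D3s = 1.8e-5,
                           a1s = 1e-2, a2s = 5e-4, a3s = 1e-3,
                           b1s = 2e-2, b2s = 4e-2, b3s = 9e-2,
                           b4s = 0.14, b5s = 0.16,
                           S0s = 1e-7, Vmax = 3.33e4 * 1e-7 * 3e-6 / 1e-4,
                           Km = 1e-7)
  expect_equal(nondimensionalize(p3)$sigma2, 3.33e4, tolerance = 1e-12)
  # time and current conversions round-trip to machine precision
  expect_equal(redimensionalize_time(5, p) / (p$a1s^2 / p$D1s), 5)
  expect_equal(dimensionless_current(dimensional_current(0.37, p), p), 0.37)
  expect_equal(dimensional_current(0, p), 0)
  p_ne <- p; p_ne$ne <- 2L * p$ne
  expect_equal(dimensional_current(1, p_ne), 2 * dimensional_current(1, p))
})

test_that("the Michaelis-Menten rate saturates, is monotone and concave", {
  expect_equal(reaction_rate(0, 5), 0)
  expect_equal(reaction_rate(1, 1), 0.5)
  expect_equal(reaction_rate(1e9, 7), 7, tolerance = 1e-8)
  S <- seq(0, 50, length.out = 400)
  v <- reaction_rate(S, 3)
  expect_true(all(diff(v) > 0))                    # monotone increasing
  expect_true(all(diff(diff(v)) < 1e-12))          # concave
  expect_true(all(v <= pmin(3 * S, 3) + 1e-12))    # bounded
  expect_error(reaction_rate(-0.1, 1), "negative")
})

test_that("build_problem lays out fields, BCs and degenerate interfaces", {
  spec <- geometry_from_levels("cone_up", 0.95, 1)   # gamma = 1
  mesh <- generate_mesh(spec, h = 2, nr_hole = 2)
  pars <- dimensionless_params(10, 1, 3, 6, spec)
  prob <- build_problem(pars, mesh)
  # S has no dofs in the selective membrane and no Dirichlet value on Gamma1
  z_s <- mesh$nodes[prob$s_nodes, 2]
  expect_true(all(z_s >= spec$b1 - 1e-12))
  expect_true(all(mesh$nodes[prob$s_dirichlet$nodes, 2] == spec$b5))
  expect_equal(prob$s_dirichlet$values, rep(1, length(prob$s_dirichlet$nodes)))
  # product vanishes on electrode and bulk top
  z_p <- mesh$nodes[prob$p_dirichlet$nodes, 2]
  expect_true(all(z_p < 1e-12 | abs(z_p - spec$b5) < 1e-12))
  # gamma = 1: the in-hole interface coincides with the carrier top plane
  expect_true(all(abs(mesh$nodes[mesh$sets$gamma3, 2] - spec$b4) < 1e-9))
  # mismatched geometry is rejected
  other <- dimensionless_params(10, 1, 3, 6,
                                geometry_from_levels("cone_up", 0.95, 0.5))
  expect_error(build_problem(other, mesh), "does not match")
})

test_that("the source enters product and substrate equations with opposite
           sign (S + P obeys pure diffusion when D2 = D3)", {
  spec <- geometry_from_levels("cone_up", 0.9, 0.5)
  mesh <- generate_mesh(spec, h = 2, nr_hole = 2)
  pars0 <- dimensionless_params(0, 1, 4, 4, spec)
  pars1 <- dimensionless_params(1e4, 1, 4, 4, spec)
  pr0 <- build_problem(pars0, mesh); pr1 <- build_problem(pars1, mesh)
  ops0 <- assemble_operators(pr0); ops1 <- assemble_operators(pr1)
  set.seed(42)
  nn <- pr0$n_nodes; ns <- length(pr0$s_nodes)
  P <- runif(nn); S <- runif(ns)
  r0 <- assemble_system(pr0, ops0, P, S, dt = Inf)
  r1 <- assemble_system(pr1, ops1, P, S, dt = Inf)
  # the sigma2-dependent parts cancel in the sum of the two residuals
  sum0 <- r0$res_P[pr0$s_nodes] + r0$res_S
  sum1 <- r1$res_P[pr1$s_nodes] + r1$res_S
  expect_equal(sum1, sum0, tolerance = 1e-10)
  # but each residual individually feels the source
  expect_gt(max(abs(r1$res_S - r0$res_S)), 1)
})
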