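# Reference thicknesses of the fully open cell: selective membrane 2,
# enzyme (slab + filled hole at gamma = 0.5) 7, diffusion layer 7.
slab_ref <- function(sigma2, S0, nz = 160)
  slab1d_params(L1 = 2, L2 = 7, L3 = 7, D2 = 3, D3 = 6,
                sigma2 = sigma2, S0 = S0, nz = nz)

test_that("closed-form linear steady current is verified against a
           brute-force fine-grid finite-difference solve", {
  p <- slab_ref(10, 1e-3)
  # independent dense FD of the *linear* two-point problem
  fd_linear <- function(N) {
    L <- p$L1 + p$L2 + p$L3
    z <- seq(0, L, length.out = N + 1); h <- z[2] - z[1]
    zm <- (z[-1] + z[-(N + 1)]) / 2
    Dint <- ifelse(zm < p$L1, 1, ifelse(zm < p$L1 + p$L2, p$D2, p$D3))
    react <- ifelse(z > p$L1 & z < p$L1 + p$L2, p$sigma2,
                    ifelse(abs(z - p$L1) < h / 2 | abs(z - p$L1 - p$L2) < h / 2,
                           p$sigma2 / 2, 0))
    iS <- which(z >= p$L1 - 1e-12); nS <- length(iS)
    W <- Dint / h^2
    bd <- function(idx, dirich_last) {
      n <- length(idx)
      lower <- numeric(n - 1); upper <- numeric(n - 1); main <- numeric(n)
      for (k in seq_len(n)) {
        i <- idx[k]
        if (k > 1) { main[k] <- main[k] + W[i - 1]; lower[k - 1] <- -W[i - 1] }
        if (k < n) { main[k] <- main[k] + W[i];     upper[k]     <- -W[i] }
      }
      Matrix::bandSparse(n, n, -1:1, list(lower, main, upper))
    }
    A <- bd(iS) + Matrix::Diagonal(nS, react[iS])
    A[nS, ] <- 0; A[nS, nS] <- 1
    rhs <- numeric(nS); rhs[nS] <- p$S0
    S <- as.vector(Matrix::solve(A, rhs))
    Sf <- numeric(N + 1); Sf[iS] <- S
    B <- bd(1:(N + 1))
    B[1, ] <- 0; B[1, 1] <- 1; B[N + 1, ] <- 0; B[N + 1, N + 1] <- 1
    rp <- react * Sf; rp[c(1, N + 1)] <- 0
    P <- as.vector(Matrix::solve(B, rp))
    0.5 * (-3 * P[1] + 4 * P[2] - P[3]) / (2 * h)
  }
  I_fd <- fd_linear(32000)
  expect_equal(analytic_linear_steady(p), I_fd, tolerance = 1e-4)
})

test_that("linear-kinetics limits of the closed form", {
  p0 <- slab_ref(1e-12, 1e-3)
  expect_lt(analytic_linear_steady(p0), 1e-9)
  expect_equal(analytic_linear_steady(slab_ref(0, 1e-3)), 0)
  # shrinking the diffusion layer raises the current (less resistance)
  thick <- analytic_linear_steady(slab_ref(10, 1e-3))
  thin <- analytic_linear_steady(slab1d_params(2, 7, 0.5, 3, 6, 10, 1e-3))
  expect_gt(thin, thick)
  # overflow-safe at very large sigma2
  expect_true(is.finite(analytic_linear_steady(slab_ref(1e8, 1e-3))))
})

test_that("the transient 1-D solver matches the closed form in the linear
           regime and self-converges under grid refinement", {
  p <- slab_ref(10, 1e-3, nz = 160)
  tr <- solve_1d_transient(p)
  expect_true(tr$converged)
  expect_equal(tr$I, analytic_linear_steady(p), tolerance = 5e-3)
  tr2 <- solve_1d_transient(slab_ref(10, 1e-3, nz = 320))
  expect_lt(abs(tr$I / tr2$I - 1), 2e-3)
  # no reaction, no current
  tr0 <- solve_1d_transient(slab_ref(0, 1))
  expect_true(all(abs(tr0$i_values) < 1e-14))
})

test_that("the 2-D solver in the open-cell limit matches the 1-D oracle
           across the Damkohler sweep", {
  spec <- geometry_from_levels("cylinder", 0, 0.5)
  for (s2 in c(1, 100, 3.33e4)) {
    pars <- dimensionless_params(s2, 1, 3, 6, spec)
    prob <- build_problem(pars, generate_mesh(spec, h = 0.5, nr_hole = 1))
    tr2d <- run_transient(prob, solver_config(dt = 0.01, t_max = 400,
                                              dt_growth = 1.05, dt_max = 2,
                                              store_states = FALSE))
    tr1d <- solve_1d_transient(slab_ref(s2, 1, nz = 320))
    expect_lt(abs(tr2d$I / tr1d$I - 1), 0.01)
    expect_lt(abs(tr2d$T_half - tr1d$T_half) / tr1d$T_half, 0.02)
  }
})

test_that("nonlinear solvers collapse onto the linear solution for small
           bulk concentrations", {
  p <- slab_ref(10, 1e-3, nz = 320)
  I_lin <- analytic_linear_steady(p)
  expect_lt(abs(solve_1d_transient(p)$I / I_lin - 1), 5e-3)
  spec <- geometry_from_levels("cylinder", 0, 0.5)
  prob <- build_problem(dimensionless_params(10, 1e-3, 3, 6, spec),
                        generate_mesh(spec, h = 0.5, nr_hole = 1))
  tr2d <- run_transient(prob, solver_config(dt = 0.01, t_max = 400,
                                            dt_growth = 1.05, dt_max = 2,
                                            store_states = FALSE))
  expect_lt(abs(tr2d$I / I_lin - 1), 5e-3)
})
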