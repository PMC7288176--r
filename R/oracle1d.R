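#' Parameters of the one-dimensional multilayer reference model
#'
#' The membrane-free (fully open cell) limit of the unit-cell model reduces
#' to a 1-D three-layer slab: selective membrane of thickness `L1`
#' (product only, diffusivity 1), enzyme layer `L2` (both species,
#' diffusivity `D2`, Michaelis-Menten consumption/production) and external
#' diffusion layer `L3` (diffusivity `D3`). This module provides two
#' independent reference solvers used as correctness oracles for the 2-D
#' finite-element code: a transient finite-difference solver and a
#' closed-form linear-kinetics steady state.
#'
#' @param L1,L2,L3 layer thicknesses (dimensionless), all > 0.
#' @param D2,D3 diffusivity ratios.
#' @param sigma2 diffusion modulus.
#' @param S0 scaled bulk substrate concentration.
#' @param nz target number of grid intervals over the whole stack
#'   (at least 3 per layer are enforced).
#' @param dt initial time step.
#' @return An object of class `"slab1d_params"`.
#' @export
slab1d_params <- function(L1, L2, L3, D2, D3, sigma2, S0,
                          nz = 160, dt = 0.01) {
  stopifnot(L1 > 0, L2 > 0, L3 > 0, D2 > 0, D3 > 0, sigma2 >= 0, S0 > 0,
            nz >= 9, dt > 0)
  structure(list(L1 = L1, L2 = L2, L3 = L3, D2 = D2, D3 = D3,
                 sigma2 = sigma2, S0 = S0, nz = nz, dt = dt),
            class = "slab1d_params")
}

#' @rdname slab1d_params
#' @param params a `"dimensionless_params"` whose geometry is a fully open
#'   cell (`alpha = 0`); the layer thicknesses are taken from it.
#' @export
slab1d_from_params <- function(params, nz = 160, dt = 0.01) {
  g <- params$geometry
  if (g$a2 < 1 - 1e-10)
    warning("geometry has alpha > 0; the 1-D reduction ignores the carrier")
  slab1d_params(L1 = g$b1, L2 = g$b3 - g$b1, L3 = g$b5 - g$b3,
                D2 = params$D2, D3 = params$D3,
                sigma2 = params$sigma2, S0 = params$S0, nz = nz, dt = dt)
}

# grid and finite-volume coefficients for the 1-D stack
slab1d_grid <- function(p) {
  L <- p$L1 + p$L2 + p$L3
  n1 <- max(3L, round(p$nz * p$L1 / L))
  n2 <- max(3L, round(p$nz * p$L2 / L))
  n3 <- max(3L, round(p$nz * p$L3 / L))
  z <- c(seq(0, p$L1, length.out = n1 + 1),
         seq(p$L1, p$L1 + p$L2, length.out = n2 + 1)[-1],
         seq(p$L1 + p$L2, L, length.out = n3 + 1)[-1])
  n <- length(z)
  zmid <- (z[-n] + z[-1]) / 2
  Dint <- ifelse(zmid < p$L1, 1, ifelse(zmid < p$L1 + p$L2, p$D2, p$D3))
  hint <- diff(z)
  # control-volume sizes and enzyme-region volume fraction per node
  lo <- c(z[1], zmid); hi <- c(zmid, z[n])
  vol <- hi - lo
  enz <- pmax(0, pmin(hi, p$L1 + p$L2) - pmax(lo, p$L1)) / vol
  list(z = z, n = n, Dint = Dint, hint = hint, vol = vol, enz = enz,
       i_b1 = which.min(abs(z - p$L1)), i_b3 = which.min(abs(z - p$L1 - p$L2)))
}

# tridiagonal diffusion operator (rows = nodes of the given index range),
# zero-flux closure at absent neighbours
slab1d_stiffness <- function(grid, idx) {
  n <- length(idx)
  W <- grid$Dint / grid$hint
  main <- numeric(n); lower <- numeric(n - 1); upper <- numeric(n - 1)
  for (k in seq_len(n)) {
    i <- idx[k]
    if (k > 1)     { main[k] <- main[k] + W[i - 1]; lower[k - 1] <- -W[i - 1] }
    if (k < n)     { main[k] <- main[k] + W[i];     upper[k]     <- -W[i] }
  }
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(lower, main, upper))
}

#' Transient 1-D finite-difference reference solver
#'
#' Second-order conservative finite differences in z on a per-layer uniform
#' grid with interfaces on grid nodes, the same boundary conditions and
#' Michaelis-Menten kinetics as the 2-D model, and backward-Euler time
#' stepping with Newton-Raphson on the substrate block. The reported
#' current is `i(t) = 0.5 * dP/dz(0)` (one-sided second-order difference),
#' carrying the same uniform radial-integral factor 1/2 as the 2-D
#' definition so the two are directly comparable. Entirely independent of
#' the finite-element discretization.
#'
#' @param p a `"slab1d_params"`.
#' @param t_max horizon; `dt_growth`/`dt_max` grow the step geometrically.
#' @param eps_ss,window steady-state rule (as in [steady_state_current()]).
#' @param newton_tol,newton_max_iter Newton residual-sum-of-squares
#'   criterion and iteration cap.
#' @return A `"current_trace"` with the final nodal profiles attached
#'   (`z`, `S_profile`, `P_profile`).
#' @export
solve_1d_transient <- function(p, t_max = 400, dt_growth = 1.05, dt_max = 2,
                               eps_ss = 1e-4, window = 1,
                               newton_tol = 1e-7, newton_max_iter = 25) {
  stopifnot(inherits(p, "slab1d_params"))
  g <- slab1d_grid(p)
  n <- g$n
  idxS <- g$i_b1:n                       # S lives on [b1, b5]
  nS <- length(idxS)
  KS <- slab1d_stiffness(g, idxS)
  KP <- slab1d_stiffness(g, 1:n)
  volS <- g$vol[idxS]; enzS <- g$enz[idxS]
  sig <- p$sigma2

  S <- numeric(nS); S[nS] <- p$S0        # Dirichlet from the first step
  P <- numeric(n)
  freeS <- seq_len(nS - 1)               # last node Dirichlet
  freeP <- 2:(n - 1)                     # both ends Dirichlet

  src <- function(S) sig * S / (1 + S) * enzS * volS
  src_d <- function(S) sig / (1 + S)^2 * enzS * volS

  times <- 0; ivals <- 0
  t <- 0; dt <- p$dt; converged <- FALSE
  while (t < t_max - 1e-12) {
    dt <- min(dt, t_max - t)
    # Newton on the substrate block
    Sn <- S
    for (it in seq_len(newton_max_iter)) {
      res <- volS * (S - Sn) / dt + as.vector(KS %*% S) + src(S)
      J <- KS + Matrix::Diagonal(nS, volS / dt + src_d(S))
      S[freeS] <- S[freeS] -
        as.vector(Matrix::solve(J[freeS, freeS, drop = FALSE], res[freeS]))
      res <- volS * (S - Sn) / dt + as.vector(KS %*% S) + src(S)
      if (sum(res[freeS]^2) <= newton_tol) break
      if (it == newton_max_iter)
        stop("1-D Newton did not converge; reduce dt")
    }
    qP <- numeric(n); qP[idxS] <- src(S)
    AP <- KP + Matrix::Diagonal(n, g$vol / dt)
    rhsP <- g$vol * P / dt + qP
    P[freeP] <- as.vector(Matrix::solve(AP[freeP, freeP, drop = FALSE],
                                        rhsP[freeP]))
    t <- t + dt
    h1 <- g$z[2] - g$z[1]
    i_t <- 0.5 * (-3 * P[1] + 4 * P[2] - P[3]) / (2 * h1)
    times <- c(times, t); ivals <- c(ivals, i_t)
    if (t >= window) {
      i_then <- stats::approx(times, ivals, t - window, rule = 2)$y
      if (abs(i_t - i_then) / max(abs(i_t), 1e-12) < eps_ss) {
        converged <- TRUE; break
      }
    }
    dt <- min(dt * dt_growth, dt_max)
  }
  tr <- current_trace(times, ivals, converged = converged,
                      eps_ss = eps_ss, window = window)
  tr$z <- g$z
  tr$P_profile <- P
  tr$S_profile <- { Sf <- rep(NA_real_, n); Sf[idxS] <- S; Sf }
  tr
}

#' Closed-form steady current for linear kinetics
#'
#' In the first-order regime (`S << 1`) the steady substrate equation in
#' the enzyme layer is `D2 S'' = sigma2 S`, solved by
#' `S = A cosh(kappa (z - b1))` with `kappa = sqrt(sigma2 / D2)` (zero flux
#' at `b1`); the diffusion layer is linear and flux-matched. The product
#' problem then has the explicit piecewise solution (linear in the passive
#' layers, `-A cosh` particular solution in the enzyme layer), giving the
#' steady current
#' `I = 0.5 * [A (cosh(kappa L2) - 1) + E L3] / (L1 + L2/D2 + L3/D3)`
#' where `E` is the diffusion-layer substrate slope. Evaluated in a
#' cosh-overflow-safe form via `tanh`. The leading 0.5 is the radial
#' integral factor shared with the other current definitions.
#'
#' @param p a `"slab1d_params"` (its `S0` should be << 1 for the linear
#'   approximation to describe the nonlinear model).
#' @return The steady current `I_lin` (a number).
#' @export
analytic_linear_steady <- function(p) {
  stopifnot(inherits(p, "slab1d_params"))
  if (p$sigma2 == 0) return(0)
  kap <- sqrt(p$sigma2 / p$D2)
  kL <- kap * p$L2
  th <- tanh(kL)
  # A*cosh(kL) without forming cosh (overflow-safe)
  Acosh <- p$S0 / (1 + (p$D2 * kap / p$D3) * p$L3 * th)
  A <- if (kL > 300) 0 else Acosh / cosh(kL)
  E <- (p$D2 * kap / p$D3) * Acosh * th
  0.5 * (Acosh - A + E * p$L3) / (p$L1 + p$L2 / p$D2 + p$L3 / p$D3)
}
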