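#' Solver controls for the transient finite-element integration
#'
#' @param dt dimensionless time step (default 0.01).
#' @param t_max integration horizon (dimensionless time).
#' @param scheme `"backward_euler"` (default, robust for stiff kinetics) or
#'   `"crank_nicolson"`.
#' @param newton_tol convergence criterion on the residual sum of squares
#'   over all equation blocks (default 1e-7).
#' @param newton_max_iter maximum Newton iterations per step.
#' @param dt_growth multiplicative growth of the step after each accepted
#'   step (1 = fixed step); `dt_max` caps the step.
#' @param dt_max largest allowed step when `dt_growth > 1`.
#' @param eps_ss,ss_window steady-state detection: the run is declared
#'   steady when the current changes by less than `eps_ss` (relative) over
#'   a trailing window of `ss_window` time units.
#' @param eps_over allowed relative overshoot of the substrate above `S0`
#'   before the solver aborts (undershoots below 0 are clamped inside the
#'   Michaelis-Menten source only). The default 0.05 accommodates the
#'   startup Gibbs overshoot of the discontinuous initial condition, which
#'   decays within a few steps; the recorded `S_range` reports the worst
#'   excursion of a run.
#' @param store_states if `TRUE`, keep the final nodal fields in the result.
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(dt = 0.01, t_max = 100,
                          scheme = c("backward_euler", "crank_nicolson"),
                          newton_tol = 1e-7, newton_max_iter = 25,
                          dt_growth = 1, dt_max = 50 * dt,
                          eps_ss = 1e-4, ss_window = 1,
                          eps_over = 0.05, store_states = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, t_max > dt, newton_tol > 0, dt_growth >= 1, dt_max >= dt,
            eps_ss > 0, ss_window > 0)
  structure(list(dt = dt, t_max = t_max, scheme = scheme,
                 theta = if (scheme == "backward_euler") 1 else 0.5,
                 newton_tol = newton_tol, newton_max_iter = newton_max_iter,
                 dt_growth = dt_growth, dt_max = dt_max,
                 eps_ss = eps_ss, ss_window = ss_window,
                 eps_over = eps_over, store_states = store_states),
            class = "solver_config")
}

#' Assemble the axisymmetric finite-element operators
#'
#' Region-wise mass and stiffness matrices in the r-weighted axisymmetric
#' weak form (measure `r dr dz`), which is the self-adjoint equivalent of
#' the strong axisymmetric Laplacian, plus the per-element quadrature data
#' needed to evaluate the nonlinear Michaelis-Menten source and its
#' Jacobian on the enzyme region. Assembly order is deterministic, so runs
#' are bit-reproducible for a fixed mesh and configuration.
#'
#' @param problem a `"bs_problem"`.
#' @return A list of operators (used by [run_transient()] and
#'   [assemble_system()]); treat as opaque.
#' @export
assemble_operators <- function(problem) {
  mesh <- problem$mesh
  tab <- p2_tabulate()
  ne <- nrow(mesh$elems); nn <- nrow(mesh$nodes); nq <- tab$nq
  NNpair <- matrix(0, nq, 36)     # N_i N_j at each quadrature point
  for (q in seq_len(nq)) NNpair[q, ] <- as.vector(outer(tab$N[q, ], tab$N[q, ]))

  ii <- matrix(0L, ne, 36); jj <- matrix(0L, ne, 36)
  xm <- matrix(0, ne, 36); xk <- matrix(0, ne, 36)
  W <- matrix(0, ne, nq)          # w * detJ * r at each quadrature point
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    xy <- mesh$nodes[en, , drop = FALSE]
    Ke <- matrix(0, 6, 6); Me <- matrix(0, 6, 6)
    for (q in seq_len(nq)) {
      J11 <- sum(tab$dNxi[q, ] * xy[, 1]);  J12 <- sum(tab$dNxi[q, ] * xy[, 2])
      J21 <- sum(tab$dNeta[q, ] * xy[, 1]); J22 <- sum(tab$dNeta[q, ] * xy[, 2])
      detJ <- J11 * J22 - J12 * J21
      rq <- sum(tab$N[q, ] * xy[, 1])
      gr <- cbind(( J22 * tab$dNxi[q, ] - J12 * tab$dNeta[q, ]) / detJ,
                  (-J21 * tab$dNxi[q, ] + J11 * tab$dNeta[q, ]) / detJ)
      wq <- tab$w[q] * detJ * rq
      W[e, q] <- wq
      Ke <- Ke + wq * tcrossprod(gr)
      Me <- Me + wq * tcrossprod(tab$N[q, ])
    }
    ii[e, ] <- rep(en, times = 6)
    jj[e, ] <- rep(en, each = 6)
    xm[e, ] <- as.vector(Me)
    xk[e, ] <- as.vector(Ke)
  }
  reg_mat <- function(x, k) {
    sel <- mesh$region == k
    if (!any(sel)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0), dims = c(nn, nn)))
    Matrix::sparseMatrix(i = as.vector(ii[sel, ]), j = as.vector(jj[sel, ]),
                         x = as.vector(x[sel, ]), dims = c(nn, nn))
  }
  M <- lapply(1:3, function(k) reg_mat(xm, k))
  K <- lapply(1:3, function(k) reg_mat(xk, k))

  # enzyme-region source data, on substrate dof numbering
  e2 <- which(mesh$region == 2L)
  loc_nodes <- mesh$elems[e2, , drop = FALSE]
  loc_s <- matrix(problem$s_index[loc_nodes], nrow = length(e2))
  # column-major 6x6 outer product: entry (i, j) sits at column i + 6(j-1)
  src <- list(elems = e2, loc_nodes = loc_nodes, loc_s = loc_s,
              W = W[e2, , drop = FALSE], N = tab$N, NNpair = NNpair,
              ii = as.vector(loc_s[, rep(1:6, times = 6), drop = FALSE]),
              jj = as.vector(loc_s[, rep(1:6, each = 6), drop = FALSE]))

  s <- problem$s_nodes
  D2 <- problem$params$D2; D3 <- problem$params$D3
  ops <- list(
    tab = tab, W = W,
    M_P = M[[1]] + M[[2]] + M[[3]],
    K_P = K[[1]] + D2 * K[[2]] + D3 * K[[3]],
    M_S = (M[[2]] + M[[3]])[s, s, drop = FALSE],
    K_S = (D2 * K[[2]] + D3 * K[[3]])[s, s, drop = FALSE],
    src = src)
  ops
}

# Michaelis-Menten source. The rational expression S/(1+S) is smooth for
# S > -1, so small transient undershoots below zero are evaluated as-is
# (the negative source then restores S toward zero); this keeps the Newton
# Jacobian consistent and quadratic convergence intact. Severe undershoot
# aborts the run.
mm_f <- function(S, sigma2) {
  if (any(S < -0.5))
    stop("severe substrate undershoot (min S = ", signif(min(S), 4),
         "); refine the mesh or reduce the time step")
  sigma2 * S / (1 + S)
}
mm_fprime <- function(S, sigma2) sigma2 / (1 + S)^2

# source vector q_i = int sigma2 S/(1+S) xi_i r dOmega2, on S dofs
source_vector <- function(ops, S, sigma2, ns) {
  src <- ops$src
  if (length(src$elems) == 0L) return(numeric(ns))
  Sq <- matrix(S[src$loc_s], nrow = nrow(src$loc_s)) %*% t(src$N)
  B <- (src$W * mm_f(Sq, sigma2)) %*% src$N          # ne2 x 6
  q <- numeric(ns)
  agg <- rowsum(as.vector(B), group = as.vector(src$loc_s))
  q[as.integer(rownames(agg))] <- agg
  q
}

# source Jacobian N_ij = int sigma2/(1+S)^2 xi_i xi_j r dOmega2, on S dofs
source_jacobian <- function(ops, S, sigma2, ns) {
  src <- ops$src
  if (length(src$elems) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(ns, ns)))
  Sq <- matrix(S[src$loc_s], nrow = nrow(src$loc_s)) %*% t(src$N)
  X <- (src$W * mm_fprime(Sq, sigma2)) %*% src$NNpair  # ne2 x 36
  Matrix::sparseMatrix(i = src$ii, j = src$jj, x = as.vector(X),
                       dims = c(ns, ns))
}

#' Residuals and Jacobian of the discrete system
#'
#' Evaluates the time-discrete Galerkin residuals of the product and
#' substrate equations (mass, diffusion, and the Michaelis-Menten source on
#' the enzyme region) for a given state, together with the substrate-block
#' Jacobian. With `dt = Inf` the transient terms drop and the residuals are
#' those of the steady problem. Exposed mainly for verification: the
#' Jacobian can be checked column-by-column against finite differences of
#' the residual.
#'
#' @param problem a `"bs_problem"`.
#' @param ops operators from [assemble_operators()].
#' @param P,S current nodal fields (P on all nodes, S on `problem$s_nodes`).
#' @param P_prev,S_prev fields at the previous time level.
#' @param dt time step; `Inf` for the steady residual.
#' @param theta time-weighting (1 backward Euler, 0.5 Crank-Nicolson).
#' @return List with `res_P`, `res_S` (full-length residual vectors,
#'   Dirichlet rows included as computed, i.e. they carry the boundary
#'   flux), `res_free_ss` (sum of squared residuals over the free rows of
#'   both fields, the Newton convergence quantity) and `jac_S` (Jacobian of
#'   `res_S` with respect to `S`).
#' @export
assemble_system <- function(problem, ops, P, S, P_prev = P, S_prev = S,
                            dt = Inf, theta = 1) {
  sig <- problem$params$sigma2
  ns <- length(problem$s_nodes); nn <- problem$n_nodes
  qS_new <- source_vector(ops, S, sig, ns)
  qS_old <- source_vector(ops, S_prev, sig, ns)
  inv_dt <- if (is.finite(dt)) 1 / dt else 0
  res_S <- inv_dt * as.vector(ops$M_S %*% (S - S_prev)) +
    theta * (as.vector(ops$K_S %*% S) + qS_new) +
    (1 - theta) * (as.vector(ops$K_S %*% S_prev) + qS_old)
  qP_new <- numeric(nn); qP_new[problem$s_nodes] <- qS_new
  qP_old <- numeric(nn); qP_old[problem$s_nodes] <- qS_old
  res_P <- inv_dt * as.vector(ops$M_P %*% (P - P_prev)) +
    theta * (as.vector(ops$K_P %*% P) - qP_new) +
    (1 - theta) * (as.vector(ops$K_P %*% P_prev) - qP_old)
  jac_S <- inv_dt * ops$M_S + theta * (ops$K_S + source_jacobian(ops, S, sig, ns))
  s_free <- setdiff(seq_len(ns), problem$s_index[problem$s_dirichlet$nodes])
  p_free <- setdiff(seq_len(nn), problem$p_dirichlet$nodes)
  list(res_P = res_P, res_S = res_S, jac_S = jac_S,
       res_free_ss = sum(res_S[s_free]^2) + sum(res_P[p_free]^2))
}

# One implicit step of the substrate equation by Newton-Raphson.
# Returns the new S, iteration count and final residual sum of squares.
newton_step_S <- function(problem, ops, S_prev, dt, theta, tol, max_iter) {
  ns <- length(problem$s_nodes)
  sig <- problem$params$sigma2
  dir_idx <- problem$s_index[problem$s_dirichlet$nodes]
  free <- setdiff(seq_len(ns), dir_idx)
  S <- S_prev
  S[dir_idx] <- problem$s_dirichlet$values
  qS_old <- source_vector(ops, S_prev, sig, ns)
  expl <- (1 - theta) * (as.vector(ops$K_S %*% S_prev) + qS_old)
  residual <- function(S) {
    qS <- source_vector(ops, S, sig, ns)
    as.vector(ops$M_S %*% (S - S_prev)) / dt +
      theta * (as.vector(ops$K_S %*% S) + qS) + expl
  }
  res <- residual(S)
  # always take at least one update: the residual criterion is absolute
  # (sum of squares <= tol), so a stale state must not be accepted
  for (it in seq_len(max_iter)) {
    J <- ops$M_S / dt + theta * (ops$K_S + source_jacobian(ops, S, sig, ns))
    dS <- Matrix::solve(J[free, free, drop = FALSE], res[free])
    S[free] <- S[free] - as.vector(dS)
    res <- residual(S)
    rss <- sum(res[free]^2)
    if (rss <= tol) return(list(S = S, iters = it, rss = rss))
  }
  stop("Newton-Raphson did not converge in ", max_iter,
       " iterations (residual sum of squares ", signif(rss, 3),
       "); try a smaller time step")
}

#' Integrate the transient biosensor problem
#'
#' Starts from the zero initial state (substrate and product zero
#' everywhere; the bulk value `S0` is imposed on the bulk interface from
#' the first step) and advances the coupled system with the implicit
#' theta-scheme. Each step solves the nonlinear substrate equation by
#' Newton-Raphson to the residual criterion and then the (linear) product
#' equation; the electrode current is extracted every step by the
#' consistent boundary-flux method. Integration stops once the current is
#' steady to within the configured tolerance, or at `t_max`.
#'
#' @param problem a `"bs_problem"`.
#' @param config a `"solver_config"`.
#' @param ops optional precomputed [assemble_operators()] result.
#' @return A `"current_trace"` (see [current_trace()]) with solver
#'   diagnostics attached: Newton iteration counts, the maximum accepted
#'   residual, substrate bounds, and (if requested) the final fields.
#' @export
run_transient <- function(problem, config = solver_config(), ops = NULL) {
  stopifnot(inherits(problem, "bs_problem"), inherits(config, "solver_config"))
  if (is.null(ops)) ops <- assemble_operators(problem)
  nn <- problem$n_nodes; ns <- length(problem$s_nodes)
  sig <- problem$params$sigma2; S0 <- problem$params$S0
  theta <- config$theta

  p_dir <- problem$p_dirichlet$nodes
  p_free <- setdiff(seq_len(nn), p_dir)

  P <- numeric(nn); S <- numeric(ns)
  S[problem$s_index[problem$s_dirichlet$nodes]] <- problem$s_dirichlet$values

  n_guess <- ceiling(config$t_max / config$dt) + 1L
  times <- numeric(n_guess); ivals <- numeric(n_guess)
  iters <- integer(n_guess); resid <- numeric(n_guess)
  times[1] <- 0; ivals[1] <- 0
  k <- 1L; t <- 0; dt <- config$dt
  max_res <- 0; minS <- 0; maxS <- max(S)
  converged <- FALSE
  dt_cached <- NA_real_; chol_P <- NULL

  while (t < config$t_max - 1e-12) {
    dt <- min(dt, config$t_max - t)
    st <- newton_step_S(problem, ops, S, dt, theta,
                        config$newton_tol, config$newton_max_iter)
    S_new <- st$S
    if (max(S_new) > S0 * (1 + config$eps_over) + config$eps_over)
      stop("substrate overshoot beyond tolerance at t = ", signif(t + dt, 6),
           ": max S = ", signif(max(S_new), 6), " > S0 = ", S0)

    qS_new <- source_vector(ops, S_new, sig, ns)
    qS_old <- source_vector(ops, S, sig, ns)
    qP_new <- numeric(nn); qP_new[problem$s_nodes] <- qS_new
    qP_old <- numeric(nn); qP_old[problem$s_nodes] <- qS_old
    rhs <- as.vector(ops$M_P %*% P) / dt -
      (1 - theta) * (as.vector(ops$K_P %*% P) - qP_old) + theta * qP_new
    if (!identical(dt, dt_cached)) {
      A_P <- (ops$M_P / dt + theta * ops$K_P)[p_free, p_free, drop = FALSE]
      chol_P <- Matrix::Cholesky(Matrix::forceSymmetric(A_P), LDL = FALSE)
      dt_cached <- dt
    }
    P_new <- numeric(nn)
    P_new[p_free] <- as.vector(Matrix::solve(chol_P, rhs[p_free]))

    # consistent boundary flux at the electrode: i(t) = int dP/dz r dr
    res_P <- as.vector(ops$M_P %*% (P_new - P)) / dt +
      theta * (as.vector(ops$K_P %*% P_new) - qP_new) +
      (1 - theta) * (as.vector(ops$K_P %*% P) - qP_old)
    i_t <- -sum(res_P[problem$mesh$sets$electrode])

    t <- t + dt; k <- k + 1L
    if (k > length(times)) {
      times <- c(times, numeric(k)); ivals <- c(ivals, numeric(k))
      iters <- c(iters, integer(k)); resid <- c(resid, numeric(k))
    }
    times[k] <- t; ivals[k] <- i_t; iters[k] <- st$iters; resid[k] <- st$rss
    max_res <- max(max_res, st$rss)
    minS <- min(minS, min(S_new)); maxS <- max(maxS, max(S_new))
    P <- P_new; S <- S_new

    # steady-state detection on a trailing window
    if (t >= config$ss_window) {
      i_then <- stats::approx(times[1:k], ivals[1:k], t - config$ss_window,
                              rule = 2)$y
      denom <- max(abs(i_t), 1e-12)
      if (abs(i_t - i_then) / denom < config$eps_ss) { converged <- TRUE; break }
    }
    dt <- min(dt * config$dt_growth, config$dt_max)
  }

  trace <- current_trace(times[1:k], ivals[1:k], converged = converged,
                         eps_ss = config$eps_ss, window = config$ss_window)
  trace$newton_iters <- iters[2:k]
  trace$newton_rss <- resid[2:k]
  trace$max_newton_rss <- max_res
  trace$S_range <- c(minS, maxS)
  trace$config <- config
  if (config$store_states) {
    trace$P <- P; trace$S <- S
    trace$problem <- problem; trace$ops <- ops
  }
  trace
}

#' Direct steady-state solve
#'
#' Newton-Raphson on the steady (infinite-dt) equations: the substrate
#' block is solved with a residual-backtracking line search from the
#' well-mixed initial guess `S = S0`, then the product block is linear.
#' Intended for smooth operating points (mesh-convergence studies and
#' cross-checks); strongly reaction-limited cases are more robustly
#' reached through [run_transient()].
#'
#' @param problem a `"bs_problem"`.
#' @param ops optional precomputed operators.
#' @param tol residual sum-of-squares criterion (default 1e-7).
#' @param max_iter Newton iteration cap.
#' @return List with nodal fields `P`, `S`, the steady current `I`
#'   (consistent boundary flux), iteration count and final residual.
#' @export
solve_steady <- function(problem, ops = NULL, tol = 1e-7, max_iter = 50) {
  if (is.null(ops)) ops <- assemble_operators(problem)
  ns <- length(problem$s_nodes); nn <- problem$n_nodes
  sig <- problem$params$sigma2
  dir_idx <- problem$s_index[problem$s_dirichlet$nodes]
  free <- setdiff(seq_len(ns), dir_idx)
  S <- rep(problem$params$S0, ns)
  S[dir_idx] <- problem$s_dirichlet$values
  res_of <- function(S) as.vector(ops$K_S %*% S) + source_vector(ops, S, sig, ns)
  res <- res_of(S); rss <- sum(res[free]^2)
  it <- 0L
  while (rss > tol && it < max_iter) {
    it <- it + 1L
    J <- ops$K_S + source_jacobian(ops, S, sig, ns)
    dS <- as.vector(Matrix::solve(J[free, free, drop = FALSE], res[free]))
    step <- 1
    repeat {
      S_try <- S; S_try[free] <- S[free] - step * dS
      res_try <- tryCatch(res_of(S_try), error = function(e) NULL)
      if (!is.null(res_try) && sum(res_try[free]^2) < rss) break
      step <- step / 2
      if (step < 1e-6) stop("steady Newton line search failed")
    }
    S <- S_try; res <- res_try; rss <- sum(res[free]^2)
  }
  if (rss > tol)
    stop("steady Newton did not reach the residual criterion (rss = ",
         signif(rss, 3), ")")
  qP <- numeric(nn); qP[problem$s_nodes] <- source_vector(ops, S, sig, ns)
  p_free <- setdiff(seq_len(nn), problem$p_dirichlet$nodes)
  P <- numeric(nn)
  P[p_free] <- as.vector(Matrix::solve(ops$K_P[p_free, p_free, drop = FALSE],
                                       qP[p_free]))
  I <- -sum((as.vector(ops$K_P %*% P) - qP)[problem$mesh$sets$electrode])
  list(P = P, S = S, I = I, iters = it, rss = rss)
}
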