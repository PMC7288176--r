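#' Default simulation configuration
#'
#' The reference operating point of the parameter study: unit-cell radius 1
#' with hole mouth `a3 = 0.1` (so admissible perforation levels satisfy
#' `alpha >= 0.9` when the hole is truly narrower than the mouth),
#' `S0 = 1`, `D3 = 2 D2 = 6`, heights `b1 = 2`, `b2 = 4`, `b4 = 14`,
#' `b5 = 16`, and diffusion modulus `sigma2 = 3.33e4`.
#'
#' @param shape hole shape, one of [hole_shapes()].
#' @param alpha perforation level.
#' @param gamma enzyme filling level.
#' @param profile solver profile name, `"default"` or `"fast"` (see
#'   [solver_profile()]).
#' @return A nested configuration list (`geometry`, `dimensionless`,
#'   `solver`) as accepted by [run_single()] and [bs_simulate()].
#' @export
default_config <- function(shape = "cylinder", alpha = 0.95, gamma = 0.5,
                           profile = "default") {
  list(version = 1L,
       geometry = list(shape = shape, alpha = alpha, gamma = gamma,
                       a3 = 0.1, b1 = 2, b2 = 4, b4 = 14, b5 = 16),
       dimensionless = list(sigma2 = 3.33e4, S0 = 1, D2 = 3, D3 = 6),
       solver = list(profile = profile))
}

#' Solver profiles
#'
#' Bundled mesh and time-stepping settings. `"default"` targets accuracy
#' (element height 0.5, 4 radial hole elements, initial step 0.01 growing
#' 5% per step to at most 2); `"fast"` is the coarse profile used for
#' large property sweeps (element height 1, 3 radial hole elements, step
#' growth 8% to at most 4). Both use backward Euler and the 1e-7 Newton
#' residual criterion.
#'
#' @param profile `"default"` or `"fast"`.
#' @param overrides named list overriding any of `h`, `nr_hole`, `grading`,
#'   or [solver_config()] arguments.
#' @return List with `h`, `nr_hole`, `grading` and `control` (a
#'   `"solver_config"`).
#' @export
solver_profile <- function(profile = c("default", "fast"), overrides = list()) {
  profile <- match.arg(profile)
  base <- switch(profile,
    default = list(h = 0.5, nr_hole = 4, grading = c(electrode = 0.8, interface = 0.8),
                   dt = 0.01, dt_growth = 1.05, dt_max = 2, t_max = 400),
    fast = list(h = 1, nr_hole = 3, grading = c(electrode = 1, interface = 0.8),
                dt = 0.02, dt_growth = 1.08, dt_max = 4, t_max = 400))
  base[names(overrides)] <- overrides
  ctl_args <- setdiff(names(base), c("h", "nr_hole", "grading"))
  control <- do.call(solver_config, base[ctl_args])
  list(profile = profile, h = base$h, nr_hole = base$nr_hole,
       grading = base$grading, control = control)
}

#' Read a simulation configuration file
#'
#' YAML configuration with a `geometry` block (`shape`, and either
#' `alpha`/`gamma` levels or explicit `a2`/`b3`), exactly one of a
#' `dimensionless` block (`sigma2`, `S0`, `D2`, `D3`) or a `dimensional`
#' block (starred quantities as in [dimensional_params()], which the tool
#' nondimensionalizes itself), and an optional `solver` block.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$geometry) && is.null(cfg$dimensional))
    stop("configuration error: no 'geometry' or 'dimensional' block")
  has_dl <- !is.null(cfg$dimensionless); has_dim <- !is.null(cfg$dimensional)
  if (has_dl && has_dim)
    stop("configuration error: give either 'dimensionless' or 'dimensional', not both")
  if (!has_dl && !has_dim)
    stop("configuration error: missing 'dimensionless' (or 'dimensional') block")
  if (has_dl) {
    need <- c("sigma2", "S0", "D2", "D3")
    miss <- setdiff(need, names(cfg$dimensionless))
    if (length(miss))
      stop("configuration error: dimensionless block lacks ",
           paste(miss, collapse = ", "))
    g <- cfg$geometry
    if (is.null(g$shape)) stop("configuration error: geometry$shape missing")
    if (is.null(g$alpha) && is.null(g$a2))
      stop("configuration error: geometry needs alpha or a2")
  }
  cfg
}

#' Build dimensionless parameters from a configuration
#'
#' @param cfg configuration list (see [read_config()], [default_config()]).
#' @return A `"dimensionless_params"`.
#' @export
config_to_params <- function(cfg) {
  cfg <- validate_config(cfg)
  if (!is.null(cfg$dimensional)) {
    d <- cfg$dimensional
    d$shape <- d$shape %||% cfg$geometry$shape %||% "cylinder"
    return(do.call(dimensional_params, d) |> nondimensionalize())
  }
  g <- cfg$geometry
  geom <- if (!is.null(g$alpha)) {
    geometry_from_levels(g$shape, g$alpha, g$gamma %||% 0.5,
                         a3 = g$a3 %||% 0.1,
                         b1 = g$b1 %||% 2, b2 = g$b2 %||% 4,
                         b4 = g$b4 %||% 14, b5 = g$b5 %||% 16)
  } else {
    geometry_spec(g$shape, a2 = g$a2, a3 = g$a3 %||% g$a2,
                  b1 = g$b1 %||% 2, b2 = g$b2 %||% 4,
                  b3 = g$b3 %||% 9, b4 = g$b4 %||% 14, b5 = g$b5 %||% 16)
  }
  dl <- lapply(cfg$dimensionless, as.numeric)  # tolerate YAML string scalars
  dimensionless_params(sigma2 = dl$sigma2, S0 = dl$S0,
                       D2 = dl$D2, D3 = dl$D3, geometry = geom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one biosensor configuration
#'
#' End-to-end single run: meshes the unit cell, assembles the problem,
#' integrates the transient to steady state and extracts the response
#' quantities. This is the main entry point for interactive use.
#'
#' @param params a `"dimensionless_params"`, or a configuration list as
#'   from [default_config()]/[read_config()].
#' @param profile solver profile name or the result of [solver_profile()].
#' @param overrides named list forwarded to [solver_profile()].
#' @return An object of class `"bs_run"`: the input parameters, the trace,
#'   steady current `I`, half-time `T_half`, mass-balance ledger, mesh and
#'   solver diagnostics.
#' @examples
#' run <- bs_simulate(default_config("cone_up", alpha = 0.95, gamma = 0.5),
#'                    profile = "fast")
#' print(run)
#' @export
bs_simulate <- function(params, profile = "default", overrides = list()) {
  cfg_in <- NULL
  if (!inherits(params, "dimensionless_params")) {
    cfg_in <- params
    if (!is.null(cfg_in$solver)) {
      # an explicitly passed profile argument wins over the config's
      if (missing(profile)) profile <- cfg_in$solver$profile %||% profile
      overrides <- utils::modifyList(
        cfg_in$solver[setdiff(names(cfg_in$solver), "profile")], overrides)
    }
    params <- config_to_params(cfg_in)
  }
  prof <- if (is.list(profile) && !is.null(profile$control)) profile
          else solver_profile(profile, overrides)
  t0 <- proc.time()[3]
  mesh <- generate_mesh(params$geometry, h = prof$h, nr_hole = prof$nr_hole,
                        grading = prof$grading)
  problem <- build_problem(params, mesh)
  trace <- run_transient(problem, prof$control)
  mb <- if (!is.null(trace$P)) mass_balance_report(trace) else NULL
  structure(list(params = params, config = cfg_in, profile = prof$profile,
                 mesh_size = c(nodes = nrow(mesh$nodes),
                               elements = nrow(mesh$elems)),
                 h = prof$h, dt = prof$control$dt,
                 trace = trace, I = trace$I, T_half = trace$T_half,
                 converged = trace$converged,
                 mass_balance = mb,
                 max_newton_rss = trace$max_newton_rss,
                 elapsed = proc.time()[3] - t0),
            class = "bs_run")
}

#' @export
print.bs_run <- function(x, ...) {
  g <- x$params$geometry
  cat(sprintf("Biosensor run: %s, alpha = %g, gamma = %g (profile %s)\n",
              g$shape, g$alpha, g$gamma, x$profile))
  cat(sprintf("  mesh: %d nodes / %d elements, dt0 = %g\n",
              x$mesh_size[1], x$mesh_size[2], x$dt))
  if (x$converged)
    cat(sprintf("  I = %.6g, T0.5 = %.4g  (mass-balance closure %.2g)\n",
                x$I, x$T_half,
                if (!is.null(x$mass_balance)) x$mass_balance$closure_consistent
                else NA_real_))
  else cat("  did not reach steady state within the horizon\n")
  invisible(x)
}

#' @export
summary.bs_run <- function(object, ...) {
  x <- object
  out <- list(
    shape = x$params$geometry$shape,
    alpha = x$params$geometry$alpha, gamma = x$params$geometry$gamma,
    sigma2 = x$params$sigma2, S0 = x$params$S0,
    D2 = x$params$D2, D3 = x$params$D3,
    I = x$I, T_half = x$T_half, converged = x$converged,
    closure = if (!is.null(x$mass_balance)) x$mass_balance$closure_consistent
              else NA_real_,
    max_newton_rss = x$max_newton_rss,
    nodes = unname(x$mesh_size[1]), h = x$h, dt = x$dt,
    profile = x$profile, elapsed_s = unname(x$elapsed))
  class(out) <- "summary.bs_run"
  out
}

#' @export
print.summary.bs_run <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
plot.bs_run <- function(x, ...) plot(x$trace, ...)

#' Run one configuration and write its artifacts
#'
#' Deterministic batch entry point: simulates a configuration (path to a
#' YAML file or a configuration list) and writes `trace.csv` (`t`, `i`),
#' `summary.json` (response quantities, mass balance, the fully resolved
#' configuration and its hash) and optionally `fields.vtk` (final S, P
#' and region tags) into `out_dir`.
#'
#' @param config YAML path or configuration list.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing and just return the run.
#' @param vtk also export the final fields as VTK.
#' @return The `"bs_run"`, invisibly; artifacts on disk.
#' @export
run_single <- function(config, out_dir = NULL, vtk = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  run <- bs_simulate(cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(run$trace, file.path(out_dir, "trace.csv"))
    smry <- summary(run)
    smry$config <- cfg
    smry$config_hash <- config_hash(cfg)
    smry$package_version <- as.character(utils::packageVersion("biosensim"))
    jsonlite::write_json(unclass(smry), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    if (vtk && !is.null(run$trace$P)) {
      prob <- run$trace$problem
      S_full <- rep(NA_real_, prob$n_nodes)
      S_full[prob$s_nodes] <- run$trace$S
      write_mesh_vtk(prob$mesh, file.path(out_dir, "fields.vtk"),
                     point_data = list(P = run$trace$P, S = S_full))
    }
  }
  invisible(run)
}

#' Batch sweep over hole shapes and perforation/filling levels
#'
#' Runs every combination of `shapes`, `alpha` and `gamma` at the base
#' operating point and collects the responses in a long-format table
#' (deterministically ordered; each cell is independent, so results do not
#' depend on execution order). Individual failures are recorded in the
#' `error` column rather than aborting the sweep.
#'
#' @param shapes character vector of hole shapes.
#' @param alpha,gamma numeric vectors of perforation and filling levels.
#' @param base base configuration (see [default_config()]); its geometry
#'   block supplies `a3` and the heights, its solver block the profile.
#' @param out_dir optional directory for a `sweep.csv` artifact.
#' @param quiet suppress per-cell progress messages.
#' @return A `data.frame` of class `"bs_sweep"` with columns `shape`,
#'   `alpha`, `gamma`, `I`, `T_half`, `converged`, `closure_err`, `h`,
#'   `dt`, `error`.
#' @export
run_sweep <- function(shapes, alpha, gamma, base = default_config(),
                      out_dir = NULL, quiet = TRUE) {
  stopifnot(length(shapes) > 0, length(alpha) > 0, length(gamma) > 0)
  grid <- expand.grid(shape = shapes, alpha = alpha, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$shape, grid$alpha, grid$gamma), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- base
    cfg$geometry$shape <- grid$shape[k]
    cfg$geometry$alpha <- grid$alpha[k]
    cfg$geometry$gamma <- grid$gamma[k]
    if (!quiet)
      message(sprintf("[%d/%d] %s alpha=%g gamma=%g", k, nrow(grid),
                      grid$shape[k], grid$alpha[k], grid$gamma[k]))
    res <- tryCatch({
      run <- bs_simulate(cfg)
      data.frame(shape = grid$shape[k], alpha = grid$alpha[k],
                 gamma = grid$gamma[k], I = run$I, T_half = run$T_half,
                 converged = run$converged,
                 closure_err = if (!is.null(run$mass_balance))
                   run$mass_balance$closure_consistent else NA_real_,
                 h = run$h, dt = run$dt, error = NA_character_)
    }, error = function(e)
      data.frame(shape = grid$shape[k], alpha = grid$alpha[k],
                 gamma = grid$gamma[k], I = NA_real_, T_half = NA_real_,
                 converged = FALSE, closure_err = NA_real_,
                 h = NA_real_, dt = NA_real_, error = conditionMessage(e)))
    rows[[k]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(!is.na(out$error)))
    stop("sweep failed: every cell errored; first error: ", out$error[1])
  class(out) <- c("bs_sweep", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }
  out
}

#' @export
plot.bs_sweep <- function(x, response = c("I", "T_half"), ...) {
  response <- match.arg(response)
  shapes <- unique(x$shape)
  cols <- grDevices::hcl.colors(max(3, length(shapes)), "Dark 3")
  xvar <- if (length(unique(x$gamma)) > 1) "gamma" else "alpha"
  graphics::plot(range(x[[xvar]]), range(x[[response]], na.rm = TRUE),
                 type = "n", xlab = xvar, ylab = response, ...)
  for (i in seq_along(shapes)) {
    d <- x[x$shape == shapes[i], ]
    d <- d[order(d[[xvar]]), ]
    graphics::lines(d[[xvar]], d[[response]], col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("topleft", legend = shapes, col = cols[seq_along(shapes)],
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
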