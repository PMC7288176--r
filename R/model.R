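#' Michaelis-Menten kinetic scheme
#'
#' Rate constants of the enzymatic scheme E + S <-> ES -> E + P: binding
#' rate `k1` (1/(concentration time)), dissociation rate `k_minus1` (1/time),
#' catalytic rate `k2` (1/time), and total enzyme concentration `E0`.
#' The reverse of the catalytic step is neglected.
#'
#' @param k1,k_minus1,k2,E0 strictly positive rate constants
#'   (`k_minus1` may be zero).
#' @return An object of class `"kinetic_scheme"`.
#' @export
kinetic_scheme <- function(k1, k_minus1, k2, E0) {
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, E0 = E0)
  if (any(!is.finite(vals)) || k1 <= 0 || k2 <= 0 || E0 <= 0 || k_minus1 < 0)
    stop("invalid kinetic scheme: k1, k2, E0 must be > 0 and k_minus1 >= 0")
  structure(as.list(vals), class = "kinetic_scheme")
}

#' Maximal rate and Michaelis constant from a kinetic scheme
#'
#' Under the quasi-steady-state assumption the production rate is
#' `v = Vmax S / (Km + S)` with `Vmax = k2 E0` and
#' `Km = (k2 + k_minus1) / k1`.
#'
#' @param scheme a `"kinetic_scheme"`.
#' @return Named numeric vector with `Vmax` and `Km`.
#' @export
derive_vmax_km <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  c(Vmax = scheme$k2 * scheme$E0,
    Km = (scheme$k2 + scheme$k_minus1) / scheme$k1)
}

#' Dimensional biosensor parameters
#'
#' Physical parameters of the device: diffusion coefficients `D1s`, `D2s`,
#' `D3s` (area/time) of the selective membrane, enzyme and external
#' diffusion layer; lengths `a1s` (unit-cell radius), `a2s`, `a3s` (hole
#' throat/mouth radii) and `b1s`..`b5s` (layer heights); bulk substrate
#' concentration `S0s`; Michaelis-Menten `Vmax` (concentration/time) and
#' `Km` (concentration); electrons per charge transfer `ne` and the
#' Faraday constant `F`. All in one consistent unit system.
#'
#' @param D1s,D2s,D3s diffusion coefficients.
#' @param a1s,a2s,a3s radii; `a1s` is the length scale.
#' @param b1s,b2s,b3s,b4s,b5s layer heights.
#' @param S0s bulk substrate concentration.
#' @param Vmax,Km kinetic parameters (see [derive_vmax_km()]).
#' @param ne electrons per transfer (integer >= 1).
#' @param F Faraday constant (charge/mol); default SI value.
#' @param shape hole shape, one of [hole_shapes()].
#' @return An object of class `"dimensional_params"`.
#' @export
dimensional_params <- function(D1s, D2s, D3s, a1s, a2s, a3s = a2s,
                               b1s, b2s, b3s, b4s, b5s,
                               S0s, Vmax, Km, ne = 1L, F = 96485.33212,
                               shape = "cylinder") {
  vals <- c(D1s, D2s, D3s, a1s, a2s, a3s, b1s, b2s, b3s, b4s, b5s,
            S0s, Vmax, Km, ne, F)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid dimensional parameters: all must be positive and finite")
  if (ne < 1) stop("invalid dimensional parameters: ne must be >= 1")
  structure(list(D1s = D1s, D2s = D2s, D3s = D3s,
                 a1s = a1s, a2s = a2s, a3s = a3s,
                 b1s = b1s, b2s = b2s, b3s = b3s, b4s = b4s, b5s = b5s,
                 S0s = S0s, Vmax = Vmax, Km = Km,
                 ne = as.integer(ne), F = F, shape = shape),
            class = "dimensional_params")
}

#' Dimensionless model parameters
#'
#' The dimensionless groups governing the unit-cell model: diffusivity
#' ratios `D2 = D2*/D1*`, `D3 = D3*/D1*`; the diffusion modulus (Damkohler
#' number) `sigma2 = Vmax a1*^2 / (Km D1*)`, comparing the enzymatic rate
#' `Vmax/Km` with transport `D1*/a1*^2`; the scaled bulk concentration
#' `S0 = S0*/Km`; and the unit-cell geometry. Concentrations are scaled by
#' `Km`, lengths by `a1*`, time by `a1*^2/D1*`.
#'
#' @param sigma2 diffusion modulus (Damkohler number), > 0.
#' @param S0 scaled bulk substrate concentration, > 0.
#' @param D2,D3 diffusivity ratios, > 0.
#' @param geometry a `"geometry_spec"`.
#' @return An object of class `"dimensionless_params"`.
#' @export
dimensionless_params <- function(sigma2, S0, D2, D3, geometry) {
  stopifnot(inherits(geometry, "geometry_spec"))
  vals <- c(sigma2 = sigma2, S0 = S0, D2 = D2, D3 = D3)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || sigma2 < 0)
    stop("invalid dimensionless parameters: S0, D2, D3 must be > 0 and sigma2 >= 0")
  structure(list(sigma2 = sigma2, S0 = S0, D2 = D2, D3 = D3,
                 geometry = geometry),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless biosensor parameters\n")
  cat(sprintf("  sigma2 (Damkohler) = %g, S0 = %g, D2 = %g, D3 = %g\n",
              x$sigma2, x$S0, x$D2, x$D3))
  print(x$geometry)
  invisible(x)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Scales lengths by `a1*`, concentrations by `Km`, time by `a1*^2/D1*`;
#' diffusivities become ratios to `D1*` and the reaction enters through the
#' diffusion modulus `sigma2 = Vmax a1*^2/(Km D1*)`. The returned object
#' carries the scale factors needed to map dimensionless times and currents
#' back to physical units (see [redimensionalize_time()],
#' [dimensional_current()]).
#'
#' @param p a `"dimensional_params"`.
#' @return A `"dimensionless_params"` with an attached `scales` attribute
#'   (`length`, `time`, `conc`, and the original parameter set).
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  geom <- geometry_spec(p$shape,
                        a2 = p$a2s / p$a1s, a3 = p$a3s / p$a1s,
                        b1 = p$b1s / p$a1s, b2 = p$b2s / p$a1s,
                        b3 = p$b3s / p$a1s, b4 = p$b4s / p$a1s,
                        b5 = p$b5s / p$a1s)
  out <- dimensionless_params(
    sigma2 = p$Vmax * p$a1s^2 / (p$Km * p$D1s),
    S0 = p$S0s / p$Km,
    D2 = p$D2s / p$D1s, D3 = p$D3s / p$D1s,
    geometry = geom)
  attr(out, "scales") <- list(length = p$a1s, time = p$a1s^2 / p$D1s,
                              conc = p$Km, dimensional = p)
  out
}

#' Redimensionalize a dimensionless time
#'
#' @param t dimensionless time(s).
#' @param p the `"dimensional_params"` defining the scales.
#' @return Time in the units of `p` (`t * a1*^2 / D1*`).
#' @export
redimensionalize_time <- function(t, p) {
  stopifnot(inherits(p, "dimensional_params"))
  t * p$a1s^2 / p$D1s
}

#' Michaelis-Menten source term (dimensionless)
#'
#' The scaled reaction rate `sigma2 * S / (1 + S)`, applied with a plus
#' sign to the product and a minus sign to the substrate inside the enzyme
#' region. Monotone increasing and concave in `S`, bounded by
#' `min(sigma2 * S, sigma2)`.
#'
#' @param S scaled substrate concentration(s), must be >= 0.
#' @param sigma2 diffusion modulus.
#' @return The scaled rate, vectorized over `S`.
#' @export
reaction_rate <- function(S, sigma2) {
  stopifnot(is.numeric(S), sigma2 >= 0)
  if (any(S < 0)) stop("negative substrate concentration (solver overshoot?)")
  sigma2 * S / (1 + S)
}

#' Assemble the discrete problem description
#'
#' Attaches the field layout and boundary conditions to a mesh: the product
#' `P` lives on all of Omega1-Omega3 with piecewise diffusivity
#' `(1, D2, D3)`; the substrate `S` on Omega2 and Omega3 only (the
#' selective membrane passes product only) with diffusivity `(D2, D3)` and
#' a zero-flux closure at the membrane top Gamma1. Dirichlet conditions:
#' `P = 0` on the electrode (fast oxidation) and on the bulk interface;
#' `S = S0` on the bulk interface. All other boundaries (axis, outer cell
#' wall, hole wall, carrier faces) are zero-flux and enter the Galerkin
#' form naturally. Interface matching (continuity of concentration and
#' flux) is enforced weakly by the single continuous field per species with
#' region-wise diffusivity. The Michaelis-Menten source acts on Omega2
#' only, +/- `sigma2 S/(1+S)` for product/substrate.
#'
#' @param params a `"dimensionless_params"`.
#' @param mesh a `"bs_mesh"` generated from `params$geometry`.
#' @return An object of class `"bs_problem"`: degree-of-freedom maps for
#'   both fields, Dirichlet node lists and values, diffusivity per region,
#'   and the source description.
#' @export
build_problem <- function(params, mesh) {
  stopifnot(inherits(params, "dimensionless_params"), inherits(mesh, "bs_mesh"))
  gm <- params$geometry; gs <- mesh$spec
  if (!isTRUE(all.equal(unclass(gm)[c("a2", "a3", "b1", "b2", "b3", "b4", "b5")],
                        unclass(gs)[c("a2", "a3", "b1", "b2", "b3", "b4", "b5")],
                        tolerance = 1e-10)) || gm$shape != gs$shape)
    stop("mesh geometry does not match params$geometry")
  need <- c("electrode", "bulk_top", "axis", "outer")
  miss <- need[!need %in% names(mesh$sets)]
  if (length(miss))
    stop("mesh is missing boundary tags: ", paste(miss, collapse = ", "))

  nn <- nrow(mesh$nodes)
  # S is defined on nodes of Omega2/Omega3 elements only
  s_nodes <- sort(unique(as.vector(mesh$elems[mesh$region != 1L, ])))
  s_index <- integer(nn); s_index[s_nodes] <- seq_along(s_nodes)

  p_dir_nodes <- sort(unique(c(mesh$sets$electrode, mesh$sets$bulk_top)))
  s_dir_nodes <- intersect(mesh$sets$bulk_top, s_nodes)

  structure(list(
    params = params, mesh = mesh,
    n_nodes = nn,
    s_nodes = s_nodes, s_index = s_index,
    diffusivity = c(1, params$D2, params$D3),
    p_dirichlet = list(nodes = p_dir_nodes,
                       values = rep(0, length(p_dir_nodes))),
    s_dirichlet = list(nodes = s_dir_nodes,
                       values = rep(params$S0, length(s_dir_nodes))),
    source_region = 2L
  ), class = "bs_problem")
}

#' @export
print.bs_problem <- function(x, ...) {
  cat("Discrete reaction-diffusion problem\n")
  cat(sprintf("  P dofs: %d (Dirichlet %d), S dofs: %d (Dirichlet %d)\n",
              x$n_nodes, length(x$p_dirichlet$nodes),
              length(x$s_nodes), length(x$s_dirichlet$nodes)))
  cat(sprintf("  sigma2 = %g, S0 = %g, D = (1, %g, %g)\n",
              x$params$sigma2, x$params$S0, x$params$D2, x$params$D3))
  invisible(x)
}
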