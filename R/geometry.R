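#' Hole shapes of the perforated membrane
#'
#' The seven axisymmetric hole geometries supported by the unit-cell model:
#' a cylinder plus upward/downward pairs of a circular cone, a paraboloid and
#' a concave paraboloid. "Upward" shapes point upward: the narrow end
#' (throat radius `a2`, the apex for a cone) sits at the top of the
#' perforated membrane (`z = b4`, the bulk side) and the hole is widest
#' (mouth radius `a3`) at the enzyme side; "downward" is the mirror image
#' through the mid-plane of the membrane.
#'
#' @return Character vector of the seven shape identifiers.
#' @export
hole_shapes <- function() {
  c("cylinder",
    "cone_up", "cone_down",
    "paraboloid_up", "paraboloid_down",
    "concave_paraboloid_up", "concave_paraboloid_down")
}

#' Geometry of the axisymmetric unit cell
#'
#' Constructs and validates the dimensionless geometry of one unit cell of a
#' perforated-membrane biosensor. All lengths are scaled by the unit-cell
#' radius, so the cell spans `0 <= r <= 1`. The cell is a stack of
#' a selective membrane (region Omega1, `0 <= z <= b1`), an enzyme layer
#' (Omega2, `b1 <= z <= b2` plus the enzyme-filled part of the hole,
#' `b2 <= z <= b3`), the perforated membrane (`b2 <= z <= b4`) whose
#' impermeable carrier (Omega4) is excluded from the computational domain,
#' and the external diffusion layer (Omega3: the unfilled part of the hole,
#' `b3 <= z <= b4`, plus the full-width layer `b4 <= z <= b5`).
#'
#' @param shape one of [hole_shapes()].
#' @param a2 dimensionless throat (minimum) radius of the hole, in (0, 1].
#' @param a3 dimensionless mouth (maximum) radius, `a2 <= a3 <= 1`. Ignored
#'   for the cylinder, whose radius is `a2` throughout.
#' @param b1,b2,b3,b4,b5 dimensionless heights: top of the selective
#'   membrane, bottom of the perforated membrane (= top of the enzyme slab),
#'   enzyme filling height inside the hole, top of the perforated membrane,
#'   top of the external diffusion layer. Must satisfy
#'   `0 < b1 < b2 <= b3 <= b4 < b5`.
#'
#' @return An object of class `"geometry_spec"`: a list with the fields
#'   above plus the derived perforation level `alpha = 1 - a2` and enzyme
#'   filling level `gamma = (b3 - b2) / (b4 - b2)`.
#' @seealso [geometry_from_levels()] to parameterize by `(alpha, gamma)`.
#' @export
geometry_spec <- function(shape, a2, a3 = a2,
                          b1 = 2, b2 = 4, b3 = 9, b4 = 14, b5 = 16) {
  shape <- match.arg(shape, hole_shapes())
  stopifnot(is.numeric(a2), length(a2) == 1L, is.numeric(a3), length(a3) == 1L)
  if (!(a2 > 0 && a2 <= 1)) stop("invalid geometry: need 0 < a2 <= 1")
  if (shape == "cylinder") a3 <- a2   # throat parameterizes the cylinder
  if (!(a3 >= a2 && a3 <= 1)) stop("invalid geometry: need a2 <= a3 <= 1")
  b <- c(b1, b2, b3, b4, b5)
  if (any(!is.finite(b)) || b1 <= 0 || !(b1 < b2) || !(b2 <= b3) ||
      !(b3 <= b4) || !(b4 < b5))
    stop("invalid geometry: need 0 < b1 < b2 <= b3 <= b4 < b5")
  g <- list(shape = shape, a2 = a2, a3 = a3,
            b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5,
            alpha = 1 - a2,
            gamma = if (b4 > b2) (b3 - b2) / (b4 - b2) else 0)
  class(g) <- "geometry_spec"
  g
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("Unit-cell geometry (dimensionless, cell radius 1)\n")
  cat(sprintf("  hole shape : %s\n", x$shape))
  cat(sprintf("  radii      : a2 = %g (throat), a3 = %g (mouth)\n", x$a2, x$a3))
  cat(sprintf("  heights    : b1 = %g, b2 = %g, b3 = %g, b4 = %g, b5 = %g\n",
              x$b1, x$b2, x$b3, x$b4, x$b5))
  cat(sprintf("  perforation level alpha = %g, enzyme filling gamma = %g\n",
              x$alpha, x$gamma))
  invisible(x)
}

#' Perforation level and hole-throat radius
#'
#' The perforation level `alpha = 1 - a2` measures the fraction of the unit
#' cell blocked by the impermeable carrier at the hole throat; `alpha = 0`
#' is a membrane-free (fully open) cell and `alpha -> 1` a vanishing hole.
#'
#' @param a2 dimensionless throat radius in (0, 1].
#' @param alpha perforation level in \[0, 1).
#' @return `perforation_level()` returns `alpha`; `throat_from_alpha()`
#'   returns `a2`. The two maps are exact inverses.
#' @export
perforation_level <- function(a2) {
  stopifnot(is.numeric(a2))
  if (any(a2 <= 0 | a2 > 1)) stop("invalid throat radius: need 0 < a2 <= 1")
  1 - a2
}

#' @rdname perforation_level
#' @export
throat_from_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha))
  if (any(alpha < 0 | alpha >= 1)) stop("invalid perforation level: need 0 <= alpha < 1")
  1 - alpha
}

#' Enzyme filling height inside the hole
#'
#' The filling level `gamma` is the fraction of the perforated-membrane
#' height occupied by enzyme, so the enzyme/diffusion interface inside the
#' hole sits at `b3 = b2 + gamma * (b4 - b2)`.
#'
#' @param gamma filling level in \[0, 1\].
#' @param b2,b4 bottom and top heights of the perforated membrane, `b2 < b4`.
#' @return The interface height `b3`.
#' @export
filling_height <- function(gamma, b2, b4) {
  stopifnot(is.numeric(gamma), b2 < b4)
  if (any(gamma < 0 | gamma > 1)) stop("invalid filling level: need 0 <= gamma <= 1")
  b2 + gamma * (b4 - b2)
}

#' Build a geometry from perforation and filling levels
#'
#' Convenience constructor for parameter sweeps: the throat radius is
#' `a2 = 1 - alpha` and the enzyme interface `b3 = b2 + gamma (b4 - b2)`.
#' The mouth radius is `max(a3, a2)` so that wide-open cells
#' (`alpha` below `1 - a3`) degenerate gracefully: at `alpha = 0` every
#' shape collapses to the same three-slab stack of full-width layers.
#'
#' @param shape one of [hole_shapes()].
#' @param alpha perforation level in \[0, 1).
#' @param gamma enzyme filling level in \[0, 1\].
#' @param a3 mouth radius of the hole (held fixed across a sweep).
#' @param b1,b2,b4,b5 layer heights as in [geometry_spec()].
#' @return A `"geometry_spec"`.
#' @export
geometry_from_levels <- function(shape, alpha, gamma, a3 = 0.1,
                                 b1 = 2, b2 = 4, b4 = 14, b5 = 16) {
  a2 <- throat_from_alpha(alpha)
  geometry_spec(shape, a2 = a2, a3 = max(a3, a2),
                b1 = b1, b2 = b2, b3 = filling_height(gamma, b2, b4),
                b4 = b4, b5 = b5)
}

#' Hole-wall radius profile a(z)
#'
#' Radius of the hole wall at height `z` inside the perforated membrane
#' (`b2 <= z <= b4`). The wall is continuous, takes the throat value `a2`
#' at the narrow end and the mouth value `a3` at the wide end. Cones are
#' linear in `z`; paraboloids are quadratic with zero slope (vertex) at the
#' narrow end; concave paraboloids are quadratic with zero slope at the
#' wide end. Upward shapes have the narrow end (the apex, for a cone) at
#' the top `z = b4` and narrow with increasing `z`; downward shapes are
#' their mirror images.
#'
#' @param shape one of [hole_shapes()] (or a `"geometry_spec"` as `spec`
#'   with `shape` omitted).
#' @param z height(s), must lie in `[b2, b4]`.
#' @param spec a `"geometry_spec"`.
#' @return The wall radius `a(z)`, vectorized over `z`; values in
#'   `[a2, a3]`.
#' @export
hole_radius_profile <- function(shape, z, spec) {
  if (inherits(shape, "geometry_spec") && missing(spec)) {
    spec <- shape; shape <- spec$shape
  }
  shape <- match.arg(shape, hole_shapes())
  a2 <- spec$a2; a3 <- spec$a3
  if (a2 > a3) stop("invalid geometry: a2 > a3")
  tol <- 1e-12 * max(1, abs(spec$b4))
  if (any(z < spec$b2 - tol | z > spec$b4 + tol))
    stop("z outside the perforated membrane [b2, b4]")
  # s in [0, 1]: 0 at the bottom (z = b2), 1 at the top (z = b4)
  s <- pmin(1, pmax(0, (z - spec$b2) / (spec$b4 - spec$b2)))
  da <- a3 - a2
  switch(shape,
    cylinder               = rep_len(a2, length(s)),
    cone_up                = a2 + da * (1 - s),
    cone_down              = a2 + da * s,
    paraboloid_up          = a2 + da * (1 - s)^2,
    paraboloid_down        = a2 + da * s^2,
    concave_paraboloid_up  = a3 - da * s^2,
    concave_paraboloid_down = a3 - da * (1 - s)^2)
}

## exact integral of a(z) over [b2, b4] (used by area oracles)
hole_profile_integral <- function(spec, z_lo = spec$b2, z_hi = spec$b4) {
  stats::integrate(function(z) hole_radius_profile(spec$shape, z, spec),
                   z_lo, z_hi, rel.tol = 1e-12)$value
}

#' Region boundary description of the unit cell
#'
#' Assembles the closed boundary description of the computational domain:
#' region extents, the hole-wall curve, the carrier annuli, and the
#' (r, z)-plane areas of each region computed from the wall profile. The
#' impermeable carrier Omega4 is excluded; it enters the model only through
#' zero-flux walls.
#'
#' @param spec a `"geometry_spec"`.
#' @return A list of class `"unit_cell"` with elements `spec`, per-region
#'   planar areas (`area_omega1`, `area_omega2`, `area_omega3`), the radii
#'   at the membrane faces, and flags for degenerate configurations
#'   (`gamma` 0 or 1, where the in-hole enzyme interface collapses onto the
#'   carrier bottom/top plane; `alpha = 0`, where the cell is a plain
#'   three-slab stack and the carrier vanishes).
#' @export
build_unit_cell <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  a_b2 <- hole_radius_profile(spec$shape, spec$b2, spec)
  a_b3 <- hole_radius_profile(spec$shape, spec$b3, spec)
  a_b4 <- hole_radius_profile(spec$shape, spec$b4, spec)
  area1 <- spec$b1 * 1
  area_hole_enz <- if (spec$b3 > spec$b2) hole_profile_integral(spec, spec$b2, spec$b3) else 0
  area_hole_dif <- if (spec$b4 > spec$b3) hole_profile_integral(spec, spec$b3, spec$b4) else 0
  cell <- list(
    spec = spec,
    radius_at_b2 = a_b2, radius_at_b3 = a_b3, radius_at_b4 = a_b4,
    area_omega1 = area1,
    area_omega2 = (spec$b2 - spec$b1) * 1 + area_hole_enz,
    area_omega3 = area_hole_dif + (spec$b5 - spec$b4) * 1,
    slab_limit = spec$a2 >= 1,                    # alpha = 0: no carrier
    gamma_zero = spec$b3 <= spec$b2,              # Gamma3 on carrier bottom
    gamma_one  = spec$b3 >= spec$b4)              # Gamma3 on carrier top
  class(cell) <- "unit_cell"
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat("Unit cell:", x$spec$shape, "\n")
  cat(sprintf("  planar areas: Omega1 = %.6g, Omega2 = %.6g, Omega3 = %.6g\n",
              x$area_omega1, x$area_omega2, x$area_omega3))
  if (x$slab_limit) cat("  degenerate: alpha = 0, three-slab stack (no carrier)\n")
  if (x$gamma_zero) cat("  degenerate: gamma = 0, enzyme interface on the carrier bottom plane\n")
  if (x$gamma_one)  cat("  degenerate: gamma = 1, enzyme interface on the carrier top plane\n")
  invisible(x)
}
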