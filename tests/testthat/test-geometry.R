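test_that("perforation and filling levels invert exactly", {
  expect_equal(perforation_level(1), 0)
  expect_equal(perforation_level(0.1), 0.9)
  expect_equal(throat_from_alpha(0.5), 0.5)
  for (a2 in c(1e-3, 0.25, 0.5, 0.999, 1))
    expect_equal(throat_from_alpha(perforation_level(a2)), a2)
  expect_error(perforation_level(0), "throat")
  expect_error(perforation_level(1.2), "throat")
  expect_error(throat_from_alpha(1), "perforation")

  expect_equal(filling_height(0, 4, 14), 4)
  expect_equal(filling_height(1, 4, 14), 14)
  expect_equal(filling_height(0.5, 4, 14), 9)
  expect_error(filling_height(1.5, 4, 14), "filling")
})

test_that("hole wall profiles hit their endpoints and stay within [a2, a3]", {
  spec <- geometry_spec("cone_up", a2 = 0.1, a3 = 0.3,
                        b1 = 2, b2 = 4, b3 = 9, b4 = 14, b5 = 16)
  # upward shapes point upward: apex (narrow end a2) at the top z = b4
  expect_equal(hole_radius_profile("cone_up", 14, spec), 0.1)
  expect_equal(hole_radius_profile("cone_up", 4, spec), 0.3)
  expect_equal(hole_radius_profile("cone_up", 9, spec), 0.2)  # linear midpoint
  expect_equal(hole_radius_profile("cone_down", 4, spec), 0.1)
  expect_equal(hole_radius_profile("paraboloid_down", 4, spec), 0.1)
  expect_equal(hole_radius_profile("paraboloid_down", 14, spec), 0.3)
  expect_equal(hole_radius_profile("cylinder", c(4, 7.3, 14), spec),
               rep(0.1, 3))

  z <- seq(4, 14, length.out = 101)
  for (s in hole_shapes()) {
    a <- hole_radius_profile(s, z, spec)
    expect_true(all(a >= 0.1 - 1e-12 & a <= 0.3 + 1e-12), info = s)
    expect_true(max(abs(diff(a))) < 0.05, info = s)  # continuity
    endpoints <- sort(c(a[1], a[101]))
    if (s != "cylinder") expect_equal(endpoints, c(0.1, 0.3), info = s)
  }
  expect_error(hole_radius_profile("cone_up", 2, spec), "outside")
  bad <- spec; bad$a2 <- 0.5
  expect_error(hole_radius_profile("cone_up", 9, bad), "a2 > a3")
})

test_that("upward and downward variants are mirror images through the
           membrane mid-plane", {
  spec <- geometry_spec("cone_up", a2 = 0.05, a3 = 0.2,
                        b1 = 2, b2 = 4, b3 = 9, b4 = 14, b5 = 16)
  mid <- (spec$b2 + spec$b4) / 2
  z <- seq(spec$b2, spec$b4, length.out = 41)
  pairs <- list(c("cone_up", "cone_down"),
                c("paraboloid_up", "paraboloid_down"),
                c("concave_paraboloid_up", "concave_paraboloid_down"))
  for (p in pairs)
    expect_equal(hole_radius_profile(p[1], z, spec),
                 hole_radius_profile(p[2], 2 * mid - z, spec),
                 info = p[1])
  # paraboloid vertex (zero slope) at the narrow end, concave at the wide end
  eps <- 1e-6
  slope_at <- function(s, z0) (hole_radius_profile(s, z0 + eps, spec) -
                               hole_radius_profile(s, z0, spec)) / eps
  expect_lt(abs(slope_at("paraboloid_up", spec$b4 - eps)), 1e-4)
  expect_lt(abs(slope_at("concave_paraboloid_up", spec$b2)), 1e-4)
})

test_that("geometry validation rejects inadmissible specs", {
  expect_error(geometry_spec("cone_up", a2 = 0), "a2")
  expect_error(geometry_spec("cone_up", a2 = 0.5, a3 = 0.2), "a3")
  expect_error(geometry_spec("cone_up", a2 = 0.5, a3 = 0.6,
                             b1 = 4, b2 = 2), "b1")
  expect_error(geometry_spec("cone_up", a2 = 0.5, a3 = 0.6,
                             b1 = 2, b2 = 4, b3 = 15, b4 = 14), "b1")
  expect_error(geometry_spec("not_a_shape", a2 = 0.5))
})

test_that("unit cell reports region areas and degenerate limits", {
  # reference heights: layer thicknesses (2, 2, 10, 2)
  spec <- geometry_from_levels("cylinder", alpha = 0.95, gamma = 0.5)
  expect_equal(with(spec, c(b1, b2 - b1, b4 - b2, b5 - b4)), c(2, 2, 10, 2))
  cell <- build_unit_cell(spec)
  # cylinder of radius 0.05: hole areas are rectangles in the (r, z) plane
  expect_equal(cell$area_omega1, 2)
  expect_equal(cell$area_omega2, 2 + 5 * 0.05)
  expect_equal(cell$area_omega3, 5 * 0.05 + 2)

  # gamma = 0: the enzyme interface collapses onto the carrier bottom plane
  g0 <- build_unit_cell(geometry_from_levels("cone_up", 0.95, 0))
  expect_true(g0$gamma_zero); expect_false(g0$gamma_one)
  g1 <- build_unit_cell(geometry_from_levels("cone_up", 0.95, 1))
  expect_true(g1$gamma_one)

  # alpha = 0 collapses every shape to the same three-slab stack
  areas <- sapply(hole_shapes(), function(s) {
    c0 <- build_unit_cell(geometry_from_levels(s, 0, 0.5))
    expect_true(c0$slab_limit, info = s)
    c(c0$area_omega1, c0$area_omega2, c0$area_omega3)
  })
  expect_true(all(abs(areas - c(2, 7, 7)) < 1e-12))
})

test_that("cone and paraboloid wall areas match closed-form integrals", {
  spec <- geometry_spec("cone_up", a2 = 0.05, a3 = 0.2,
                        b1 = 2, b2 = 4, b3 = 9, b4 = 14, b5 = 16)
  L <- spec$b4 - spec$b2
  da <- spec$a3 - spec$a2
  # integral of a(z) over the hole: trapezoid (cone), a2 L + da L/3
  # (paraboloid, vertex at narrow end), a3 L - da L/3 (concave)
  closed <- list(
    cone_up = (spec$a2 + spec$a3) / 2 * L,
    paraboloid_up = spec$a2 * L + da * L / 3,
    concave_paraboloid_up = spec$a3 * L - da * L / 3)
  for (s in names(closed)) {
    sp <- spec; sp$shape <- s
    cell <- build_unit_cell(sp)
    hole_area <- (cell$area_omega2 - (sp$b2 - sp$b1)) +
      (cell$area_omega3 - (sp$b5 - sp$b4))
    expect_equal(hole_area, closed[[s]], tolerance = 1e-9, info = s)
  }
})
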