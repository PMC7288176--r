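#' Mesh generation for the perforated-membrane unit cell
#'
#' Builds a boundary-fitted triangulation of the computational domain with
#' six-node (quadratic) triangles. The mesh is mapped: inside the hole the
#' radial coordinate follows the wall profile `a(z)`, so curved walls are
#' represented isoparametrically with nodes on the exact curve. Region and
#' boundary tags are assigned exactly (no element crosses an interface) and
#' the enzyme interface inside the hole is a mesh line.
#'
#' @param spec a `"geometry_spec"`.
#' @param h target element height (dimensionless); layer row counts are
#'   `ceiling(layer thickness / h)`.
#' @param nr_hole number of radial elements across the hole.
#' @param nr_annulus number of radial elements across the carrier annulus
#'   (`a(z) <= r <= 1`) in the full-width slabs; default scales with `h`.
#' @param grading named vector: `electrode` is the geometric ratio of
#'   successive element heights in the selective membrane toward the
#'   electrode, `interface` the ratio toward the in-hole enzyme interface
#'   from both sides (1 = uniform; values < 1 refine toward the feature).
#' @return An object of class `"bs_mesh"`: node coordinates `nodes`
#'   (n x 2, columns r and z), element connectivity `elems` (ne x 6,
#'   vertices then midsides), `region` (1, 2 or 3 per element), and `sets`,
#'   a list of boundary/interface node-index vectors (`electrode`, `axis`,
#'   `outer`, `bulk_top`, `hole_wall`, `carrier_bottom`, `carrier_top`,
#'   `gamma1`, `gamma3`).
#' @export
generate_mesh <- function(spec, h = 0.5, nr_hole = 3, nr_annulus = NULL,
                          grading = c(electrode = 1, interface = 1)) {
  stopifnot(inherits(spec, "geometry_spec"), h > 0, nr_hole >= 1)
  if (spec$b4 <= spec$b2)
    stop("zero-thickness perforated membrane cannot be meshed")
  g_el <- if ("electrode" %in% names(grading)) grading[["electrode"]] else 1
  g_if <- if ("interface" %in% names(grading)) grading[["interface"]] else 1

  a_b2 <- hole_radius_profile(spec$shape, spec$b2, spec)
  a_b4 <- hole_radius_profile(spec$shape, spec$b4, spec)
  if (spec$a2 < h * 1e-3)
    stop("hole throat a2 = ", spec$a2, " too small for meshing; reduce h")

  nrow_of <- function(len) if (len <= 0) 0L else max(1L, as.integer(ceiling(len / h)))
  n1 <- nrow_of(spec$b1)
  n2 <- nrow_of(spec$b2 - spec$b1)
  n3 <- nrow_of(spec$b3 - spec$b2)
  n4 <- nrow_of(spec$b4 - spec$b3)
  n5 <- nrow_of(spec$b5 - spec$b4)

  # element-boundary z levels per layer (graded where requested)
  zA <- c(geom_partition(0, spec$b1, n1, g_el, "start"),
          geom_partition(spec$b1, spec$b2, n2, 1, "start")[-1])
  zB_parts <- list()
  if (n3 > 0) zB_parts <- c(zB_parts, list(geom_partition(spec$b2, spec$b3, n3, g_if, "end")))
  if (n4 > 0) zB_parts <- c(zB_parts, list(geom_partition(spec$b3, spec$b4, n4, g_if, "start")))
  zB <- zB_parts[[1]]
  if (length(zB_parts) == 2L) zB <- c(zB, zB_parts[[2]][-1])
  zC <- geom_partition(spec$b4, spec$b5, n5, 1, "start")

  m <- as.integer(nr_hole)
  s_fine <- fine_levels(seq(0, 1, length.out = m + 1))        # hole fractions
  if (is.null(nr_annulus))
    nr_annulus <- max(2L, as.integer(ceiling((1 - min(a_b2, a_b4)) / (2 * h))))

  ann_cols <- function(a_b) {
    if (1 - a_b <= 1e-10) return(numeric(0))
    pts <- geom_partition(a_b, 1, max(1L, as.integer(nr_annulus)), 1.5, "start")
    fine_levels(pts)[-1]                                       # drop shared a_b
  }

  # ---- block A: 0 <= z <= b2, full width -------------------------------
  zAf <- fine_levels(zA)
  rA <- c(s_fine * a_b2, ann_cols(a_b2))
  nzA <- length(zAf); nrAc <- length(rA)
  idA <- matrix(seq_len(nzA * nrAc), nrow = nzA, byrow = TRUE)
  nodesA <- cbind(r = rep(rA, times = nzA), z = rep(zAf, each = nrAc))
  n_nodes <- nzA * nrAc

  # ---- block B: hole, b2 < z <= b4, mapped columns ---------------------
  zBf <- fine_levels(zB)
  nzB <- length(zBf); ncB <- length(s_fine)
  idB <- matrix(0L, nzB, ncB)
  idB[1, ] <- idA[nzA, seq_len(ncB)]                    # shared row at z = b2
  newB <- (nzB - 1L) * ncB
  idB[-1, ] <- matrix(n_nodes + seq_len(newB), nrow = nzB - 1L, byrow = TRUE)
  aBf <- hole_radius_profile(spec$shape, zBf, spec)
  nodesB <- cbind(r = as.vector(t(outer(aBf[-1], s_fine))),
                  z = rep(zBf[-1], each = ncB))
  n_nodes <- n_nodes + newB

  # ---- block C: b4 <= z <= b5, full width ------------------------------
  zCf <- fine_levels(zC)
  rC <- c(s_fine * a_b4, ann_cols(a_b4))
  nzC <- length(zCf); nrCc <- length(rC)
  idC <- matrix(0L, nzC, nrCc)
  idC[1, seq_len(ncB)] <- idB[nzB, ]                    # shared at z = b4 (hole part)
  n_extra0 <- nrCc - ncB
  if (n_extra0 > 0) idC[1, (ncB + 1L):nrCc] <- n_nodes + seq_len(n_extra0)
  nodes_extra0 <- if (n_extra0 > 0)
    cbind(r = rC[(ncB + 1L):nrCc], z = rep(spec$b4, n_extra0)) else NULL
  n_nodes <- n_nodes + max(0L, n_extra0)
  newC <- (nzC - 1L) * nrCc
  idC[-1, ] <- matrix(n_nodes + seq_len(newC), nrow = nzC - 1L, byrow = TRUE)
  nodesC <- cbind(r = rep(rC, times = nzC - 1L), z = rep(zCf[-1], each = nrCc))
  n_nodes <- n_nodes + newC

  nodes <- rbind(nodesA, nodesB, nodes_extra0, nodesC)
  stopifnot(nrow(nodes) == n_nodes)

  # ---- triangles -------------------------------------------------------
  tri_from_block <- function(id) {
    nz <- (nrow(id) - 1L) %/% 2L; nc <- (ncol(id) - 1L) %/% 2L
    if (nz < 1L || nc < 1L) return(NULL)
    out <- matrix(0L, 2L * nz * nc, 6L)
    k <- 0L
    for (i in seq_len(nz)) {
      zi <- 2L * (i - 1L) + 1L
      for (j in seq_len(nc)) {
        cj <- 2L * (j - 1L) + 1L
        A <- id[zi, cj]; B <- id[zi, cj + 2L]
        C <- id[zi + 2L, cj + 2L]; D <- id[zi + 2L, cj]
        mAB <- id[zi, cj + 1L]; mBC <- id[zi + 1L, cj + 2L]
        mCD <- id[zi + 2L, cj + 1L]; mDA <- id[zi + 1L, cj]
        mX <- id[zi + 1L, cj + 1L]                       # cell centre
        out[k + 1L, ] <- c(A, B, C, mAB, mBC, mX)
        out[k + 2L, ] <- c(A, C, D, mX, mCD, mDA)
        k <- k + 2L
      }
    }
    out
  }
  eA <- tri_from_block(idA); eB <- tri_from_block(idB); eC <- tri_from_block(idC)
  elems <- rbind(eA, eB, eC)

  # region per element (by centroid height)
  zc <- (nodes[elems[, 1], 2] + nodes[elems[, 2], 2] + nodes[elems[, 3], 2]) / 3
  region <- ifelse(zc < spec$b1, 1L, ifelse(zc < spec$b3, 2L, 3L))
  # in-hole elements below b3 are enzyme even when b3 == b2 handled above;
  # elements in the full-width top slab are always region 3
  region[zc > spec$b4] <- 3L

  tol <- 1e-9 * max(1, spec$b5)
  near <- function(x, y) abs(x - y) <= tol
  r <- nodes[, 1]; z <- nodes[, 2]
  slab_limit <- (1 - spec$a2 <= 1e-10) && (1 - spec$a3 <= 1e-10)
  wall <- as.integer(idB[, ncB])
  sets <- list(
    electrode      = as.integer(idA[1, ]),
    axis           = which(near(r, 0)),
    outer          = which(near(r, 1)),
    bulk_top       = as.integer(idC[nzC, ]),
    hole_wall      = if (slab_limit) integer(0) else wall,
    carrier_bottom = if (nrAc > ncB) as.integer(idA[nzA, ncB:nrAc]) else integer(0),
    carrier_top    = if (nrCc > ncB) as.integer(idC[1, ncB:nrCc]) else integer(0),
    gamma1         = which(near(z, spec$b1)),
    gamma3         = which(near(z, spec$b3) & r <= hole_radius_profile(spec$shape, spec$b3, spec) + tol)
  )

  mesh <- structure(list(nodes = nodes, elems = elems, region = region,
                         sets = sets, spec = spec,
                         h = h, nr_hole = m, nr_annulus = nr_annulus),
                    class = "bs_mesh")
  jmin <- min_jacobian(mesh)
  if (jmin <= 0)
    stop("mesh generation failed: nonpositive element Jacobian (min ", jmin,
         "); reduce h or the grading ratios")
  mesh
}

# geometric partition of [lo, hi] into n elements whose sizes form a
# geometric sequence; the smallest element sits at `towards`. `ratio`
# may be given either way round (0.8 and 1.25 mean the same refinement).
geom_partition <- function(lo, hi, n, ratio = 1, towards = c("start", "end")) {
  towards <- match.arg(towards)
  n <- as.integer(n)
  stopifnot(n >= 1L, ratio > 0)
  if (ratio == 1 || n == 1L) return(seq(lo, hi, length.out = n + 1L))
  q <- if (ratio >= 1) ratio else 1 / ratio
  sizes <- q^(seq_len(n) - 1L)            # grows away from the start
  if (towards == "end") sizes <- rev(sizes)
  sizes <- sizes / sum(sizes) * (hi - lo)
  c(lo, lo + cumsum(sizes))
}

# insert midpoints between consecutive break points
fine_levels <- function(pts) {
  n <- length(pts) - 1L
  out <- numeric(2L * n + 1L)
  out[seq(1, 2 * n + 1, by = 2)] <- pts
  out[seq(2, 2 * n, by = 2)] <- (pts[-(n + 1L)] + pts[-1L]) / 2
  out
}

# minimum Jacobian determinant over all elements and quadrature points
min_jacobian <- function(mesh) {
  tab <- p2_tabulate()
  jmin <- Inf
  for (e in seq_len(nrow(mesh$elems))) {
    xy <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (q in seq_len(tab$nq)) {
      J11 <- sum(tab$dNxi[q, ] * xy[, 1]); J12 <- sum(tab$dNxi[q, ] * xy[, 2])
      J21 <- sum(tab$dNeta[q, ] * xy[, 1]); J22 <- sum(tab$dNeta[q, ] * xy[, 2])
      jmin <- min(jmin, J11 * J22 - J12 * J21)
    }
  }
  jmin
}

#' Planar area of a mesh, total and by region
#'
#' Integrates 1 over each element in the (r, z) plane (no axisymmetric
#' weight), for comparison against the closed-form region areas of
#' [build_unit_cell()].
#'
#' @param mesh a `"bs_mesh"`.
#' @return List with `total` and `by_region` (named numeric, regions 1-3).
#' @export
mesh_area <- function(mesh) {
  tab <- p2_tabulate()
  areas <- numeric(nrow(mesh$elems))
  for (e in seq_len(nrow(mesh$elems))) {
    xy <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    aa <- 0
    for (q in seq_len(tab$nq)) {
      J11 <- sum(tab$dNxi[q, ] * xy[, 1]); J12 <- sum(tab$dNxi[q, ] * xy[, 2])
      J21 <- sum(tab$dNeta[q, ] * xy[, 1]); J22 <- sum(tab$dNeta[q, ] * xy[, 2])
      aa <- aa + tab$w[q] * (J11 * J22 - J12 * J21)
    }
    areas[e] <- aa
  }
  by_region <- vapply(1:3, function(k) sum(areas[mesh$region == k]), numeric(1))
  names(by_region) <- paste0("omega", 1:3)
  list(total = sum(areas), by_region = by_region, per_element = areas)
}

#' @export
print.bs_mesh <- function(x, ...) {
  cat("Axisymmetric unit-cell mesh (quadratic triangles)\n")
  cat(sprintf("  nodes: %d, elements: %d (h = %g, %d radial hole elements)\n",
              nrow(x$nodes), nrow(x$elems), x$h, x$nr_hole))
  tab <- table(factor(x$region, levels = 1:3))
  cat(sprintf("  elements by region: Omega1 %d, Omega2 %d, Omega3 %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
plot.bs_mesh <- function(x, ...) {
  v <- x$elems[, 1:3]
  graphics::plot(x$nodes, type = "n", xlab = "r", ylab = "z", asp = 1, ...)
  graphics::segments(x$nodes[v[, 1], 1], x$nodes[v[, 1], 2],
                     x$nodes[v[, 2], 1], x$nodes[v[, 2], 2], col = "grey50")
  graphics::segments(x$nodes[v[, 2], 1], x$nodes[v[, 2], 2],
                     x$nodes[v[, 3], 1], x$nodes[v[, 3], 2], col = "grey50")
  graphics::segments(x$nodes[v[, 3], 1], x$nodes[v[, 3], 2],
                     x$nodes[v[, 1], 1], x$nodes[v[, 1], 2], col = "grey50")
  invisible(x)
}
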