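# Quadratic (P2) Lagrange basis on the reference triangle
# vertices (0,0), (1,0), (0,1); node order: v1, v2, v3, m12, m23, m31.

p2_shape <- function(xi, eta) {
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
    4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
}

p2_dshape <- function(xi, eta) {
  l1 <- 1 - xi - eta
  # rows: basis functions; cols: d/dxi, d/deta
  matrix(c(
    1 - 4 * l1,        1 - 4 * l1,
    4 * xi - 1,        0,
    0,                 4 * eta - 1,
    4 * (l1 - xi),    -4 * xi,
    4 * eta,           4 * xi,
    -4 * eta,          4 * (l1 - eta)
  ), nrow = 6, byrow = TRUE)
}

# 7-point symmetric rule, exact to degree 5; weights include the 1/2
# reference-triangle area so that sum(w) = 1/2.
tri_quadrature <- function() {
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  pts <- rbind(
    c(1 / 3, 1 / 3),
    c(a1, b1), c(b1, a1), c(b1, b1),
    c(a2, b2), c(b2, a2), c(b2, b2))
  w <- c(0.225,
         rep(0.1323941527885062, 3),
         rep(0.1259391805448271, 3)) * 0.5
  list(xi = pts[, 1], eta = pts[, 2], w = w)
}

# shape values / derivatives tabulated at the quadrature points
p2_tabulate <- function(quad = tri_quadrature()) {
  nq <- length(quad$w)
  N <- matrix(0, nq, 6); dNxi <- matrix(0, nq, 6); dNeta <- matrix(0, nq, 6)
  for (q in seq_len(nq)) {
    N[q, ] <- p2_shape(quad$xi[q], quad$eta[q])
    d <- p2_dshape(quad$xi[q], quad$eta[q])
    dNxi[q, ] <- d[, 1]; dNeta[q, ] <- d[, 2]
  }
  list(N = N, dNxi = dNxi, dNeta = dNeta, w = quad$w, nq = nq)
}

# 3-point Gauss rule on [-1, 1] (degree 5), for boundary-edge integrals
gauss3 <- function() {
  list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
}

# 1-D quadratic edge basis on [-1, 1], nodes at -1, 0, +1
edge2_shape <- function(t) cbind(t * (t - 1) / 2, 1 - t^2, t * (t + 1) / 2)
edge2_dshape <- function(t) cbind(t - 0.5, -2 * t, t + 0.5)
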