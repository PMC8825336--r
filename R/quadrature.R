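# Numerical integration over surfaces of "generalized revolution":
#   r(t, psi) = ( x(t), A(t) cos psi, k A(t) sin psi ),
# an elliptic cross-section of fixed aspect ratio k swept along the x axis.
# Both the elliptic hyperboloid tube and the spheroid cap cut perpendicular to
# an equatorial axis are of this form, so one integrator serves both.
#
# Gauss-Legendre nodes in t; uniform midpoint rule in the periodic psi
# direction (trapezoidal on a periodic integrand, spectrally accurate).

.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n, lo, hi) {
  key <- as.character(n)
  gl <- .gl_cache[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- gl
  }
  h <- (hi - lo) / 2
  list(x = (lo + hi) / 2 + h * gl$x, w = h * gl$w)
}

# Fundamental-form integrals at given node values.
# x, x1, x2, A, A1, A2: vectors (length nt) of x(t), x'(t), x''(t), A(t), ...
# w: GL weights; k: cross-section aspect ratio; npsi: azimuthal nodes.
# Orientation: outward normal assumed; requires x1 > 0 throughout.
# Returns area, volume (between end planes, i.e. integral of the elliptic
# cross-section area), I1 = int (c1+c2) dA, I2 = int (c1+c2)^2 dA.
grev_integrals <- function(x, x1, x2, A, A1, A2, w, k, npsi) {
  psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
  wpsi <- 2 * pi / npsi
  cs <- cos(psi); sn <- sin(psi)
  cs2 <- cs^2; sn2 <- sn^2

  # nt x npsi matrices by outer products
  E <- outer(x1^2, rep(1, npsi)) + outer(A1^2, cs2 + k^2 * sn2)
  Fm <- outer(A * A1, sn * cs * (k^2 - 1))
  G <- outer(A^2, sn2 + k^2 * cs2)
  W2 <- E * G - Fm^2
  W <- sqrt(pmax(W2, 0))

  # unit outward normal = -(k A A1, -k A x1 cos, -A x1 sin)/W
  nx <- -outer(k * A * A1, rep(1, npsi)) / W
  ny <- outer(k * A * x1, cs) / W
  nz <- outer(A * x1, sn) / W

  L <- outer(x2, rep(1, npsi)) * nx + outer(A2, cs) * ny + outer(k * A2, sn) * nz
  M <- outer(-A1, sn) * ny + outer(k * A1, cs) * nz
  N <- outer(-A, cs) * ny + outer(-k * A, sn) * nz

  # sphere-positive sign convention: c1 + c2 = 2/r for a sphere of radius r
  two_h <- -(E * N - 2 * Fm * M + G * L) / W2

  wt <- outer(w, rep(wpsi, npsi))
  dA <- W * wt
  area <- sum(dA)
  i1 <- sum(two_h * dA)
  i2 <- sum(two_h^2 * dA)
  volume <- pi * k * sum(w * A^2 * x1)
  list(area = area, volume = volume, i1 = i1, i2 = i2)
}

# Tube (one-sheet elliptic hyperboloid segment) node values; tube is the
# struct from solve_tube_junction(). Quadrature over axial x in [-l/2, l/2].
# Axial/azimuthal orders adapted to the cross-section aspect ratio k:
# flat elliptic sections concentrate curvature near the equatorial plane.
adapt_orders <- function(k, nt, npsi) {
  bump <- min(256, ceiling(10 / max(k, 0.04)))
  c(nt = max(nt, bump), npsi = max(npsi, bump))
}

tube_integrals <- function(tube, nt, npsi) {
  ao <- adapt_orders(tube$bh / tube$ah, nt, npsi)
  nt <- ao[["nt"]]; npsi <- ao[["npsi"]]
  g <- gl_nodes(nt, -tube$l / 2, tube$l / 2)
  u <- tube$asym^2
  f <- sqrt(1 + g$x^2 / u)
  A <- tube$ah * f
  A1 <- tube$ah * g$x / (u * f)
  A2 <- tube$ah / (u * f^3)
  grev_integrals(x = g$x, x1 = rep(1, nt), x2 = rep(0, nt),
                 A = A, A1 = A1, A2 = A2, w = g$w,
                 k = tube$bh / tube$ah, npsi = npsi)
}

# Spheroid cap beyond the junction plane at distance xj from the center,
# cut perpendicular to an equatorial axis. Parameterized x = a sin(tau),
# in-plane semi-width A = a cos(tau), out-of-plane ratio k = c/a.
cap_integrals <- function(a, c, xj, nt, npsi) {
  ao <- adapt_orders(c / a, nt, npsi)
  nt <- ao[["nt"]]; npsi <- ao[["npsi"]]
  tau_j <- asin(min(xj / a, 1))
  g <- gl_nodes(nt, tau_j, pi / 2)
  grev_integrals(x = a * sin(g$x), x1 = a * cos(g$x), x2 = -a * sin(g$x),
                 A = a * cos(g$x), A1 = -a * sin(g$x), A2 = -a * cos(g$x),
                 w = g$w, k = c / a, npsi = npsi)
}

# Full oblate spheroid curvature moments about the polar (z) axis, 1D
# quadrature in the polar angle with closed-form principal curvatures:
#   kappa_meridional = a c / D^(3/2),  kappa_azimuthal = c / (a sqrt(D)),
#   D = a^2 cos^2(theta) + c^2 sin^2(theta).
spheroid_moments <- function(a, c, n) {
  # the meridional-curvature peak at the equator has angular width ~ c/a;
  # flat pancakes need proportionally more nodes to resolve the rim
  n <- min(max(n, ceiling(16 * a / c)), 4096)
  g <- gl_nodes(n, 0, pi)
  D <- a^2 * cos(g$x)^2 + c^2 * sin(g$x)^2
  km <- a * c / D^1.5
  ka <- c / (a * sqrt(D))
  dA <- 2 * pi * a * sin(g$x) * sqrt(D) * g$w
  list(area = sum(dA),
       volume = 4 / 3 * pi * a^2 * c,
       i1 = sum((km + ka) * dA),
       i2 = sum((km + ka)^2 * dA))
}

# Run fn(n) with doubling resolution until all returned components change by
# less than rtol relative, or error out at the refinement cap.
converge_quadrature <- function(fn, n0, rtol = 1e-5, max_doublings = 8,
                                what = "quadrature") {
  prev <- fn(n0)
  n <- n0
  for (i in seq_len(max_doublings)) {
    n <- n * 2
    cur <- fn(n)
    floor_scale <- 1e-3 * max(abs(unlist(cur)), 1e-300)
    rel <- mapply(function(p, q) abs(q - p) / max(abs(q), floor_scale),
                  prev, cur)
    if (all(rel < rtol)) {
      return(c(cur, list(n_nodes = n, rel_change = max(rel))))
    }
    prev <- cur
  }
  abort(sprintf("%s failed to converge to relative %.1e within %d refinements.",
                what, rtol, max_doublings),
        class = "cellplate_numerical_error")
}
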