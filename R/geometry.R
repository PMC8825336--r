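#' Oblate spheroid surface area
#'
#' Closed-form surface area of an oblate spheroid with equatorial radius `a`
#' and polar radius `c` (a sphere when `a == c`). The quadrature route used by
#' the composite assembler agrees with this closed form to 1e-6 relative (see
#' the test suite).
#'
#' @param a equatorial (major) radius, nm.
#' @param c polar (minor) radius, nm; requires `a >= c > 0`.
#' @return Surface area, nm^2.
#' @export
#' @examples
#' spheroid_area(30, 30)   # sphere: 4*pi*30^2
#' spheroid_area(50, 20)
spheroid_area <- function(a, c) {
  check_spheroid(a, c)
  if (abs(a - c) < 1e-12 * a) return(4 * pi * a^2)
  e <- sqrt(1 - c^2 / a^2)
  2 * pi * a^2 + pi * c^2 / e * log((1 + e) / (1 - e))
}

#' Oblate spheroid volume
#'
#' @inheritParams spheroid_area
#' @return Volume `(4/3) pi a^2 c`, nm^3.
#' @export
spheroid_volume <- function(a, c) {
  check_spheroid(a, c)
  4 / 3 * pi * a^2 * c
}

#' Bending integral over an oblate spheroid
#'
#' The Helfrich bending integrand integrated over the closed spheroid:
#' `I = integral (c1 + c2 - c0)^2 dA`, with closed-form principal curvatures
#' and Gauss-Legendre quadrature in the polar angle, refined by grid doubling
#' until the result is converged to 1e-5 relative. For a sphere with `c0 = 0`
#' this is the Willmore energy `16 pi`, independent of radius.
#'
#' @inheritParams spheroid_area
#' @param c0 spontaneous curvature, 1/nm.
#' @return Dimensionless integral (multiply by KB/2 for energy).
#' @export
#' @examples
#' spheroid_bending_integral(30, 30, 0)       # 16*pi
#' spheroid_bending_integral(30, 30, 2 / 30)  # ~0
spheroid_bending_integral <- function(a, c, c0 = 0) {
  check_spheroid(a, c)
  if (c0 < 0) abort("`c0` must be non-negative.", class = "cellplate_validation_error")
  # converge the raw moments (bounded away from zero) and combine after:
  # the c0 combination can vanish identically (sphere at c0 = 2/r)
  res <- converge_quadrature(function(n) {
    m <- spheroid_moments(a, c, n)
    list(area = m$area, i1 = m$i1, i2 = m$i2)
  }, n0 = 24, rtol = 1e-5, what = "spheroid bending integral")
  res$i2 - 2 * c0 * res$i1 + c0^2 * res$area
}

check_spheroid <- function(a, c) {
  if (!is.numeric(a) || !is.numeric(c) || length(a) != 1 || length(c) != 1 ||
      !is.finite(a) || !is.finite(c) || a <= 0 || c <= 0) {
    abort("Spheroid radii must be positive finite numbers.",
          class = "cellplate_validation_error")
  }
  if (a < c * (1 - 1e-12)) {
    abort("Oblate spheroid requires a >= c.", class = "cellplate_validation_error")
  }
  invisible(TRUE)
}

#' Solve the tube-spheroid junction
#'
#' Determines the elliptic one-sheet hyperboloid that joins two oblate
#' spheroids continuously. The tube end is the planar cut of the spheroid
#' perpendicular to the tube axis at distance `xj` from the spheroid center;
#' the cut ellipse has semi-axes `(a s, c s)` with `s = sqrt(1 - xj^2/a^2)`.
#' Matching both semi-axes (C0) forces the tube's out-of-plane waist
#' `bh = ah c / a`; matching the in-plane profile tangent as well (C1) fixes
#' the asymptote parameter and `xj` in closed form: with `u = asym^2`,
#' `(a^2 - ah^2) u^2 - (ah^2 l^2/4) u - ah^4 l^2/4 = 0` (positive root) and
#' `xj = ah^2 l / (2 u)`.
#'
#' @param a,c spheroid radii, nm (`a >= c > 0`).
#' @param ah tube waist semi-axis in the equatorial plane, nm; must satisfy
#'   `ah < a`.
#' @param l tube length between its two junction planes, nm.
#' @return An object of class `cp_tube`: list with `l`, `ah`, `bh`, `asym`,
#'   `xj`, parent radii `a`, `c`, and the junction `residual` (maximum
#'   distance-like implicit-equation defect of the tube end curve on the
#'   spheroid; guaranteed `< 1e-6 a`).
#' @export
#' @examples
#' solve_tube_junction(60, 25, 15, 40)
solve_tube_junction <- function(a, c, ah, l) {
  check_spheroid(a, c)
  if (!is.finite(ah) || !is.finite(l) || ah <= 0 || l <= 0) {
    abort("Tube parameters ah and l must be positive.",
          class = "cellplate_validation_error")
  }
  if (ah >= a) {
    abort(sprintf(
      "Infeasible junction: tube waist ah = %g must be smaller than the spheroid radius a = %g (no junction plane exists).",
      ah, a), class = "cellplate_geometry_error")
  }
  A2 <- a^2 - ah^2
  B2 <- ah^2 * l^2 / 4
  C2 <- ah^4 * l^2 / 4
  u <- (B2 + sqrt(B2^2 + 4 * A2 * C2)) / (2 * A2)
  asym <- sqrt(u)
  xj <- ah^2 * l / (2 * u)
  bh <- ah * c / a

  tube <- structure(
    list(l = l, ah = ah, bh = bh, asym = asym, xj = xj, a = a, c = c),
    class = "cp_tube")

  # Verify the end cross-section lies on the spheroid: points
  # (xj, A_end cos, (c/a) A_end sin) must satisfy the spheroid implicit eq.
  A_end <- ah * sqrt(1 + (l / 2)^2 / u)
  psi <- seq(0, 2 * pi, length.out = 65)
  res_impl <- abs(xj^2 / a^2 + (A_end * cos(psi))^2 / a^2 +
                    (bh / ah * A_end * sin(psi))^2 / c^2 - 1)
  # implicit defect ~ 2*distance/a near the surface; report as length
  tube$residual <- max(res_impl) * a / 2
  if (tube$residual > 1e-6 * a) {
    abort(sprintf("Junction continuity residual %.3e exceeds 1e-6 * a.",
                  tube$residual), class = "cellplate_geometry_error")
  }
  # C1 tangent check in the equatorial plane
  slope_tube <- ah * (l / 2) / (u * sqrt(1 + (l / 2)^2 / u))
  slope_sph <- xj / sqrt(a^2 - xj^2)
  if (abs(slope_tube - slope_sph) > 1e-8 * max(1, slope_sph)) {
    abort("Tangent matching failed at the junction.",
          class = "cellplate_geometry_error")
  }
  tube
}

#' @export
print.cp_tube <- function(x, ...) {
  cat(sprintf(
    "<cp_tube> l = %g, ah = %g, bh = %g, asym = %g, xj = %g nm (residual %.2e)\n",
    x$l, x$ah, x$bh, x$asym, x$xj, x$residual))
  invisible(x)
}

check_tube <- function(tube) {
  if (!inherits(tube, "cp_tube")) {
    abort("Expected a `cp_tube` from solve_tube_junction().",
          class = "cellplate_validation_error")
  }
  invisible(TRUE)
}

#' Tube surface area, volume, and bending integral
#'
#' Quadrature over the hyperboloid segment between its junction planes:
#' lateral surface area, enclosed volume (between the end planes), and the
#' Helfrich bending integral `integral (c1 + c2 - c0)^2 dA`. Gauss-Legendre in
#' the axial coordinate, uniform in azimuth, refined by node doubling to 1e-5
#' relative. In the circular-cylinder limit (`asym -> Inf`, `bh = ah = r`)
#' these approach `2 pi r l`, `pi r^2 l` and `2 pi l / r` (for `c0 = 0`).
#'
#' @param tube a `cp_tube` from [solve_tube_junction()].
#' @param c0 spontaneous curvature, 1/nm.
#' @return Scalar area (nm^2), volume (nm^3), or dimensionless bending
#'   integral.
#' @export
tube_area <- function(tube) {
  check_tube(tube)
  converge_quadrature(function(n) {
    r <- tube_integrals(tube, n, n)
    list(val = r$area)
  }, n0 = 16, rtol = 1e-5, what = "tube area")$val
}

#' @rdname tube_area
#' @export
tube_volume <- function(tube) {
  check_tube(tube)
  converge_quadrature(function(n) {
    r <- tube_integrals(tube, n, n)
    list(val = r$volume)
  }, n0 = 16, rtol = 1e-5, what = "tube volume")$val
}

#' @rdname tube_area
#' @export
tube_bending_integral <- function(tube, c0 = 0) {
  check_tube(tube)
  res <- converge_quadrature(function(n) {
    r <- tube_integrals(tube, n, n)
    list(area = r$area, i1 = r$i1, i2 = r$i2)
  }, n0 = 16, rtol = 1e-5, what = "tube bending integral")
  res$i2 - 2 * c0 * res$i1 + c0^2 * res$area
}

#' Spheroid cap area / volume / bending integral
#'
#' Integrals over the spheroid cap cut off beyond the junction plane (the
#' piece removed when a tube is attached), cut perpendicular to an equatorial
#' axis at distance `xj` from the center.
#'
#' @inheritParams spheroid_area
#' @param xj distance from the spheroid center to the cut plane, nm
#'   (`0 < xj < a`).
#' @param c0 spontaneous curvature, 1/nm.
#' @return List with `area`, `volume` (between the cut plane and the pole),
#'   `i1`, `i2` (curvature moments: integrals of `(c1+c2)` and `(c1+c2)^2`),
#'   and the bending integral at the given `c0`.
#' @export
cap_quantities <- function(a, c, xj, c0 = 0) {
  check_spheroid(a, c)
  if (xj <= 0 || xj >= a) {
    abort("Cap cut requires 0 < xj < a.", class = "cellplate_geometry_error")
  }
  res <- converge_quadrature(function(n) {
    r <- cap_integrals(a, c, xj, n, n)
    list(area = r$area, volume = r$volume, i1 = r$i1, i2 = r$i2)
  }, n0 = 16, rtol = 1e-5, what = "cap quadrature")
  res$bending <- res$i2 - 2 * c0 * res$i1 + c0^2 * res$area
  res[c("area", "volume", "i1", "i2", "bending")]
}
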