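# Assembly of a full conformation from shared shape parameters (a, c, ah, l):
# every vesicle is the same oblate spheroid, every tube the same hyperboloid.
# Totals are sums over primitives with the junction caps removed:
#   area  = V * A_spheroid - 2T * A_cap + T * A_tube
# and likewise for volume and the curvature moments i1 = int (c1+c2) dA,
# i2 = int (c1+c2)^2 dA. Storing the raw moments makes the bending energy an
# algebraic function of c0: int (c1+c2-c0)^2 dA = i2 - 2 c0 i1 + c0^2 area.

# Fast area-only integral for root-solving the area constraint. Uses the same
# nodes as the full integral so both routes agree exactly.
grev_area_only <- function(x1, A, A1, w, k, npsi) {
  psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
  cs2 <- cos(psi)^2; sn2 <- sin(psi)^2
  sncs <- sin(psi) * cos(psi)
  E <- outer(x1^2, rep(1, npsi)) + outer(A1^2, cs2 + k^2 * sn2)
  Fm <- outer(A * A1, sncs * (k^2 - 1))
  G <- outer(A^2, sn2 + k^2 * cs2)
  sum(sqrt(pmax(E * G - Fm^2, 0)) * outer(w, rep(2 * pi / npsi, npsi)))
}

tube_area_fast <- function(tube, nt, npsi) {
  ao <- adapt_orders(tube$bh / tube$ah, nt, npsi)
  nt <- ao[["nt"]]; npsi <- ao[["npsi"]]
  g <- gl_nodes(nt, -tube$l / 2, tube$l / 2)
  u <- tube$asym^2
  f <- sqrt(1 + g$x^2 / u)
  grev_area_only(rep(1, nt), tube$ah * f, tube$ah * g$x / (u * f), g$w,
                 tube$bh / tube$ah, npsi)
}

cap_area_fast <- function(a, c, xj, nt, npsi) {
  ao <- adapt_orders(c / a, nt, npsi)
  nt <- ao[["nt"]]; npsi <- ao[["npsi"]]
  tau_j <- asin(min(xj / a, 1))
  g <- gl_nodes(nt, tau_j, pi / 2)
  grev_area_only(a * cos(g$x), a * cos(g$x), -a * sin(g$x), g$w, c / a, npsi)
}

# Total membrane area of a conformation at shape parameters; NA if the
# junction is infeasible. Used inside the area-constraint root solve.
composite_area <- function(conf, a, c, ah, l, n_quad = 24) {
  if (a < c || (conf$t > 0 && ah >= a)) return(NA_real_)
  A <- spheroid_area(a, c) * conf$v
  if (conf$t > 0) {
    tube <- solve_tube_junction(a, c, ah, l)
    A <- A - 2 * conf$t * cap_area_fast(a, c, tube$xj, n_quad, n_quad) +
      conf$t * tube_area_fast(tube, n_quad, n_quad)
  }
  A * conf$copies
}

# Geometric feasibility of the layout beyond the junction itself:
#  - caps on the same vesicle must not overlap (in-plane cap half-angle
#    beta = acos(xj/a); incident tube directions must be >= 2 beta apart);
#  - non-adjacent vesicles must not intersect (center distance >= 2a).
# Adjacent vesicles may be closer: the full-spheroid intersection circle lies
# at axial distance d/2 = l/2 + xj > xj from both centers, inside the removed
# caps, so the retained surfaces cannot intersect.
layout_feasible <- function(conf, a, xj, centers) {
  v <- conf$v
  edges <- conf$edges
  if (conf$t == 0) return(TRUE)
  beta <- acos(min(xj / a, 1))
  adj <- matrix(FALSE, v, v)
  adj[edges] <- TRUE; adj[edges[, 2:1, drop = FALSE]] <- TRUE
  for (i in seq_len(v)) {
    nb <- which(adj[i, ])
    if (length(nb) >= 2) {
      dirs <- centers[nb, , drop = FALSE] -
        matrix(centers[i, ], length(nb), 2, byrow = TRUE)
      ang <- atan2(dirs[, 2], dirs[, 1])
      for (p in seq_len(length(nb) - 1)) {
        for (q in seq(p + 1, length(nb))) {
          dang <- abs(ang[p] - ang[q])
          dang <- min(dang, 2 * pi - dang)
          if (dang < 2 * beta - 1e-12) return(FALSE)
        }
      }
    }
  }
  if (v > 2) {
    dd <- as.matrix(stats::dist(centers))
    for (i in seq_len(v - 1)) {
      for (j in seq(i + 1, v)) {
        if (!adj[i, j] && dd[i, j] < 2 * a - 1e-12) return(FALSE)
      }
    }
  }
  TRUE
}

# Core descriptor computation shared by assemble() and the minimizer.
# Returns NULL when the geometry is infeasible.
composite_descriptors <- function(conf, a, c, ah, l, n_quad = 24,
                                  footprint_n = 128, footprint = TRUE) {
  if (a < c) return(NULL)
  sph <- spheroid_moments(a, c, max(2 * n_quad, 48))
  sph$area <- spheroid_area(a, c)       # exact closed forms
  sph$volume <- spheroid_volume(a, c)

  tube <- NULL; centers <- NULL; d <- NA_real_
  if (conf$t > 0) {
    if (ah >= a || is.na(ah) || is.na(l) || ah <= 0 || l <= 0) return(NULL)
    tube <- solve_tube_junction(a, c, ah, l)
    d <- l + 2 * tube$xj
    centers <- layout_centers(conf, d)
    if (!layout_feasible(conf, a, tube$xj, centers)) return(NULL)
    cap <- cap_integrals(a, c, tube$xj, n_quad, n_quad)
    tub <- tube_integrals(tube, n_quad, n_quad)
    tot <- lapply(c(area = "area", volume = "volume", i1 = "i1", i2 = "i2"),
                  function(f) conf$v * sph[[f]] - 2 * conf$t * cap[[f]] +
                    conf$t * tub[[f]])
  } else {
    centers <- matrix(0, 1, 2)
    tot <- list(area = sph$area, volume = sph$volume,
                i1 = sph$i1, i2 = sph$i2)
  }
  a_eq <- NA_real_
  if (footprint) {
    a_eq <- footprint_covered(conf, a, tube, centers, footprint_n)
  }
  list(a = a, c = c, ah = if (conf$t > 0) ah else NA_real_,
       l = if (conf$t > 0) l else NA_real_,
       area = tot$area * conf$copies, volume = tot$volume * conf$copies,
       i1 = tot$i1 * conf$copies, i2 = tot$i2 * conf$copies,
       a_eq = a_eq * conf$copies,
       tube = tube, centers = centers, spacing = d)
}

# Covered (material) projected area of one copy in the equatorial plane.
# Chains are axisymmetric about the chain axis: every cross-section is a
# y-symmetric interval, so the union is an exact 1D integral of the maximum
# half-width. Ring/ladder layouts are rasterized.
footprint_covered <- function(conf, a, tube, centers, footprint_n,
                              resolution = NULL) {
  if (conf$t == 0) return(pi * a^2)
  if (conf$layout == "chain") {
    footprint_chain(conf, a, tube, centers)
  } else {
    raster_footprint(conf, a, tube, centers, footprint_n, resolution)$a_eq
  }
}

footprint_chain <- function(conf, a, tube, centers, nx = 4001) {
  xc <- centers[, 1]
  lo <- min(xc) - a; hi <- max(xc) + a
  x <- seq(lo, hi, length.out = nx)
  w <- matrix(0, length(x), conf$v + conf$t)
  for (i in seq_len(conf$v)) {
    s2 <- a^2 - (x - xc[i])^2
    w[, i] <- sqrt(pmax(s2, 0))
  }
  u <- tube$asym^2
  for (e in seq_len(conf$t)) {
    mid <- (xc[conf$edges[e, 1]] + xc[conf$edges[e, 2]]) / 2
    xi <- x - mid
    inside <- abs(xi) <= tube$l / 2
    w[, conf$v + e] <- ifelse(inside, tube$ah * sqrt(1 + xi^2 / u), 0)
  }
  wmax <- do.call(pmax, as.data.frame(w))
  # composite Simpson (nx odd)
  h <- (hi - lo) / (nx - 1)
  simp <- c(1, rep(c(4, 2), length.out = nx - 2), 1)
  if (nx %% 2 == 0) stop("internal: nx must be odd")
  sum(simp * 2 * wmax) * h / 3
}

raster_footprint <- function(conf, a, tube, centers, footprint_n = 128,
                             resolution = NULL, gaps = FALSE) {
  pad <- a * 1.05
  xr <- range(centers[, 1]) + c(-pad, pad)
  yr <- range(centers[, 2]) + c(-pad, pad)
  span <- max(diff(xr), diff(yr))
  h <- if (is.null(resolution)) span / footprint_n else resolution
  ncells <- ceiling(diff(xr) / h) * ceiling(diff(yr) / h)
  if (ncells > 4e7) {
    abort(sprintf(
      "Footprint raster would need %.2g cells; use a coarser resolution.",
      ncells), class = "cellplate_validation_error")
  }
  gx <- seq(xr[1] + h / 2, xr[2], by = h)
  gy <- seq(yr[1] + h / 2, yr[2], by = h)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  covered <- rep(FALSE, length(px))
  for (i in seq_len(nrow(centers))) {
    covered <- covered |
      ((px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= a^2)
  }
  if (!is.null(tube) && conf$t > 0) {
    u <- tube$asym^2
    for (e in seq_len(conf$t)) {
      p1 <- centers[conf$edges[e, 1], ]; p2 <- centers[conf$edges[e, 2], ]
      mid <- (p1 + p2) / 2
      dl <- sqrt(sum((p2 - p1)^2))
      ux <- (p2[1] - p1[1]) / dl; uy <- (p2[2] - p1[2]) / dl
      xi <- (px - mid[1]) * ux + (py - mid[2]) * uy
      eta <- -(px - mid[1]) * uy + (py - mid[2]) * ux
      covered <- covered |
        (abs(xi) <= tube$l / 2 & abs(eta) <= tube$ah * sqrt(1 + xi^2 / u))
    }
  }
  a_eq <- sum(covered) * h^2
  gap_area <- NA_real_
  if (gaps) {
    cov <- matrix(covered, nrow = length(gx))
    reach <- flood_outside(cov)
    gap_area <- sum(!cov & !reach) * h^2
  }
  list(a_eq = a_eq, gap_area = gap_area, h = h)
}

# Cells reachable from the raster border without crossing covered cells.
flood_outside <- function(cov) {
  nr <- nrow(cov); nc <- ncol(cov)
  open <- !cov
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- open[1, ]; reach[nr, ] <- open[nr, ]
  reach[, 1] <- reach[, 1] | open[, 1]; reach[, nc] <- reach[, nc] | open[, nc]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

#' Assemble a conformation into a composite surface
#'
#' Places vesicle centers according to the conformation layout (chain, ring,
#' or ladder), solves every tube junction, and integrates total membrane
#' area, enclosed volume, curvature moments, and the covered equatorial
#' footprint. All spheroids share `(a, c)` and all tubes share `(ah, l)`.
#'
#' @param conf a [conformation()].
#' @param a,c spheroid equatorial and polar radii, nm (`a >= c`).
#' @param ah,l tube waist semi-axis and length, nm (ignored when `T = 0`).
#' @param n_quad quadrature nodes per axis for tube and cap integrals.
#' @param footprint_n raster cells across the bounding box for ring/ladder
#'   footprints (chains use an exact 1D union integral).
#' @return An object of class `cp_surface` with fields `conf`, `a`, `c`,
#'   `ah`, `l`, `area`, `volume`, `i1`, `i2` (curvature moments), `a_eq`
#'   (covered equatorial footprint), `tube`, `centers`, `spacing`, `hos`
#'   (equatorial-plane thickness 2c).
#' @export
#' @examples
#' s <- assemble(conformation("2x1x0"), a = 60, c = 25, ah = 15, l = 40)
#' s$area < 2 * spheroid_area(60, 25) + tube_area(s$tube)  # caps removed
assemble <- function(conf, a, c, ah = NA, l = NA, n_quad = 48,
                     footprint_n = 256) {
  stopifnot(inherits(conf, "cp_conformation"))
  check_spheroid(a, c)
  if (conf$t > 0 && (is.na(ah) || is.na(l))) {
    abort("This conformation has tubes: provide `ah` and `l`.",
          class = "cellplate_validation_error")
  }
  d <- composite_descriptors(conf, a, c, ah, l, n_quad = n_quad,
                             footprint_n = footprint_n)
  if (is.null(d)) {
    abort("Infeasible geometry: overlapping vesicles or unsolvable junction for these parameters.",
          class = "cellplate_geometry_error")
  }
  structure(c(d, list(conf = conf, hos = 2 * c)), class = "cp_surface")
}

#' @export
print.cp_surface <- function(x, ...) {
  cat(sprintf("<cp_surface> %s (%s layout)%s\n", format(x$conf),
              x$conf$layout,
              if (x$conf$copies > 1) sprintf(" x %d copies", x$conf$copies) else ""))
  cat(sprintf("  a = %.3g, c = %.3g", x$a, x$c))
  if (!is.na(x$ah)) cat(sprintf(", ah = %.3g, l = %.3g", x$ah, x$l))
  cat(" nm\n")
  cat(sprintf("  area = %.6g nm^2, volume = %.6g nm^3\n", x$area, x$volume))
  cat(sprintf("  footprint a_eq = %.6g nm^2, thickness hos = %.3g nm\n",
              x$a_eq, x$hos))
  invisible(x)
}

#' Equatorial footprint and gap area of a composite surface
#'
#' The covered footprint `A_eq` is the area of the union of equatorial-plane
#' projections of all primitives; `gap_area` is the total area of bounded
#' uncovered regions enclosed by that union (the fenestrations). Chains have
#' no enclosed gaps and use an exact 1D union integral; ring and ladder
#' layouts are rasterized at the requested resolution and gaps found by a
#' border flood fill.
#'
#' @param s a `cp_surface` from [assemble()].
#' @param resolution raster cell size, nm (must be positive). The default
#'   adapts to the structure size; pass e.g. `0.5` for a fixed fine grid.
#' @return A tibble with columns `a_eq` and `gap_area` (nm^2).
#' @export
footprint_area <- function(s, resolution = NULL) {
  stopifnot(inherits(s, "cp_surface"))
  if (!is.null(resolution) && resolution <= 0) {
    abort("`resolution` must be positive.", class = "cellplate_validation_error")
  }
  if (s$conf$t == 0) {
    return(tibble(a_eq = pi * s$a^2 * s$conf$copies, gap_area = 0))
  }
  if (s$conf$layout == "chain") {
    nx <- if (is.null(resolution)) 4001 else {
      n <- ceiling((diff(range(s$centers[, 1])) + 2 * s$a) / resolution)
      n + (n + 1) %% 2  # odd for Simpson
    }
    a_eq <- footprint_chain(s$conf, s$a, s$tube, s$centers, nx = max(nx, 101))
    return(tibble(a_eq = a_eq * s$conf$copies, gap_area = 0))
  }
  r <- raster_footprint(s$conf, s$a, s$tube, s$centers,
                        footprint_n = 512, resolution = resolution,
                        gaps = TRUE)
  tibble(a_eq = r$a_eq * s$conf$copies, gap_area = r$gap_area * s$conf$copies)
}
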