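# Constrained variational minimization: the energy is minimized over the
# shared shape parameters at fixed total membrane area. The equatorial radius
# `a` is root-solved from the area constraint on a log-spaced grid over the
# remaining axes ((c) for a single spheroid, (c, ah, l) otherwise), so every
# candidate matches the target area by construction; a deterministic
# coarse-grid scan with local refinement around the incumbent follows.

log_seq <- function(lim, n) exp(seq(log(lim[1]), log(lim[2]), length.out = n))

# Solve composite_area(a) = a_target for a in [lo, hi]; NA if no root.
solve_a_for_area <- function(conf, c, ah, l, a_target, grid) {
  lo <- max(c, if (conf$t > 0) ah * 1.0005 else 0, grid$a_lim[1] * 0.5)
  hi <- grid$a_lim[2]
  if (lo >= hi) return(NA_real_)
  f <- function(a) composite_area(conf, a, c, ah, l, n_quad = grid$n_quad) - a_target
  flo <- tryCatch(f(lo), error = function(e) NA_real_)
  fhi <- tryCatch(f(hi), error = function(e) NA_real_)
  if (is.na(flo) || is.na(fhi) || flo > 0 || fhi < 0) return(NA_real_)
  r <- tryCatch(
    uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
            tol = max(1e-10 * hi, 1e-9)),
    error = function(e) NULL)
  if (is.null(r)) NA_real_ else r$root
}

# Evaluate descriptors for one (c, ah, l) grid point at fixed area.
feasible_point <- function(conf, cc, ah, l, a_target, grid) {
  a <- solve_a_for_area(conf, cc, ah, l, a_target, grid)
  if (is.na(a)) return(NULL)
  d <- tryCatch(
    composite_descriptors(conf, a, cc, ah, l, n_quad = grid$n_quad,
                          footprint_n = grid$footprint_n),
    error = function(e) NULL)
  if (is.null(d)) return(NULL)
  if (abs(d$area - a_target) / a_target > grid$area_rtol) return(NULL)
  # re-validate the area at doubled quadrature order
  a2 <- composite_area(conf, a, cc, ah, l, n_quad = 2 * grid$n_quad)
  if (is.na(a2) || abs(a2 - a_target) / a_target > grid$area_rtol) return(NULL)
  tibble(a = d$a, c = d$c, ah = d$ah, l = d$l, area = d$area,
         volume = d$volume, i1 = d$i1, i2 = d$i2, a_eq = d$a_eq)
}

scan_grid <- function(conf, a_target, grid, c_lim, ah_lim, l_lim, n_c,
                      n_ahl) {
  cs <- log_seq(c_lim, n_c)
  if (conf$t == 0) {
    rows <- purrr::map(cs, function(cc)
      feasible_point(conf, cc, NA, NA, a_target, grid))
  } else {
    ahs <- log_seq(ah_lim, n_ahl)
    ls <- log_seq(l_lim, n_ahl)
    pts <- expand.grid(c = cs, ah = ahs, l = ls, KEEP.OUT.ATTRS = FALSE)
    rows <- purrr::pmap(pts, function(c, ah, l)
      feasible_point(conf, c, ah, l, a_target, grid))
  }
  dplyr::bind_rows(rows)
}

#' Feasible shape parameters at a fixed total membrane area
#'
#' Returns all shape-parameter points of the deterministic search grid whose
#' assembled total area matches `a_target` to the grid's relative tolerance
#' (default 1e-4, tighter than the 0.01% working tolerance of the energy
#' minimization). The equatorial radius `a` is root-solved from the area
#' constraint on a log-spaced grid over the remaining axes, and every
#' returned point is re-validated by an independent area recomputation at
#' doubled quadrature order.
#'
#' @param conf a [conformation()].
#' @param a_target total membrane area, nm^2 (of all copies combined).
#' @param grid a [grid_spec()].
#' @return A tibble with columns `a`, `c`, `ah`, `l`, `area`, `volume`,
#'   `i1`, `i2`, `a_eq` (one row per feasible shape).
#' @export
feasible_set <- function(conf, a_target, grid = grid_spec()) {
  stopifnot(inherits(conf, "cp_conformation"), inherits(grid, "cp_grid"))
  if (!is.numeric(a_target) || a_target <= 0) {
    abort("`a_target` must be a positive area in nm^2.",
          class = "cellplate_validation_error")
  }
  out <- scan_grid(conf, a_target, grid,
                   c_lim = grid$c_lim, ah_lim = grid$ah_lim,
                   l_lim = grid$l_lim,
                   n_c = if (conf$t == 0) grid$n_single else grid$n,
                   n_ahl = grid$n)
  if (nrow(out) == 0) {
    # report the closest achievable area from the sphere lower bound
    amin <- conf$copies * conf$v * 4 * pi * grid$c_lim[1]^2
    abort(sprintf(
      "No feasible shapes for %s at area %.4g nm^2 on this grid (smallest spheroid-only area ~%.4g nm^2).",
      format(conf), a_target, amin),
      class = "cellplate_infeasible_error")
  }
  out
}

# Deterministic tie-break: lowest energy, then smallest a, then smallest c.
pick_incumbent <- function(desc, e) {
  emin <- min(e)
  tol <- max(abs(emin), 1) * 1e-10
  tied <- which(e <= emin + tol)
  tied <- tied[order(desc$a[tied], desc$c[tied])]
  tied[1]
}

#' Minimize the modified Helfrich energy at fixed area
#'
#' Coarse log-spaced grid scan over the feasible set, followed by local
#' refinement rounds that shrink each free axis window around the incumbent
#' (the grid's `refine` and `shrink` settings). Ties are broken
#' deterministically by lowest energy, then smallest `a`, then smallest `c`.
#'
#' @param conf a [conformation()].
#' @param a_target total membrane area, nm^2.
#' @param p a [model_params()].
#' @param grid a [grid_spec()].
#' @param base optional precomputed base feasible set (from
#'   [feasible_set()]), reused across calls that share the geometry -- e.g.
#'   spontaneous-curvature sweeps, where the feasible set is c0-independent.
#' @return An object of class `cp_fit`: list with `conf`, `a_target`, `p`,
#'   `best` (named shape parameters), `emin`, `breakdown` (a `cp_energy`
#'   row), `hos`, `a_eq`, `n_feasible`, `surface` (the assembled optimum).
#' @export
#' @examples
#' \donttest{
#' p <- model_params(kb = 100, c0 = 0, dp = 0, gamma = 0, kg = 0, lambda = 0)
#' fit <- minimize_energy(conformation("1x0x0"), 4 * pi * 30^2, p)
#' fit$emin / (8 * pi * 100)  # Willmore: sphere is optimal, ~1
#' }
minimize_energy <- function(conf, a_target, p, grid = grid_spec(),
                            base = NULL) {
  stopifnot(inherits(conf, "cp_conformation"))
  p <- as_cp_params(p)
  desc <- base %||% feasible_set(conf, a_target, grid)
  if (nrow(desc) == 0) {
    abort("Empty feasible set.", class = "cellplate_infeasible_error")
  }
  e <- energy_from_descriptors(desc, p, conf)
  best <- pick_incumbent(desc, e)
  n_feasible <- nrow(desc)

  widths <- list(c = log(grid$c_lim[2] / grid$c_lim[1]),
                 ah = log(grid$ah_lim[2] / grid$ah_lim[1]),
                 l = log(grid$l_lim[2] / grid$l_lim[1]))
  if (grid$refine > 0) {
    for (round in seq_len(grid$refine)) {
      shrinkf <- grid$shrink^round
      win <- function(x0, w0, lim) {
        w <- w0 / shrinkf
        lo <- max(lim[1], x0 * exp(-w / 2))
        hi <- min(lim[2], x0 * exp(w / 2))
        c(lo, hi)
      }
      cl <- win(desc$c[best], widths$c, grid$c_lim)
      al <- if (conf$t > 0) win(desc$ah[best], widths$ah, grid$ah_lim) else grid$ah_lim
      ll <- if (conf$t > 0) win(desc$l[best], widths$l, grid$l_lim) else grid$l_lim
      ref <- scan_grid(conf, a_target, grid, c_lim = cl, ah_lim = al,
                       l_lim = ll,
                       n_c = if (conf$t == 0) grid$n_refine * 2 else grid$n_refine,
                       n_ahl = grid$n_refine)
      if (nrow(ref) > 0) {
        n_feasible <- n_feasible + nrow(ref)
        desc <- dplyr::bind_rows(desc, ref)
        e <- c(e, energy_from_descriptors(ref, p, conf))
        best <- pick_incumbent(desc, e)
      }
    }
  }

  b <- desc[best, ]
  surface <- assemble(conf, b$a, b$c, ah = b$ah, l = b$l,
                      n_quad = 2 * grid$n_quad,
                      footprint_n = 2 * grid$footprint_n)
  structure(
    list(conf = conf, a_target = a_target, p = p,
         best = c(a = b$a, c = b$c, ah = b$ah, l = b$l),
         emin = e[best], breakdown = total_energy(surface, p),
         hos = 2 * b$c, a_eq = b$a_eq, area = b$area,
         volume = b$volume, n_feasible = n_feasible,
         desc = desc, energies = e, surface = surface, grid = grid),
    class = "cp_fit")
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf("<cp_fit> %s at target area %.6g nm^2\n", format(x$conf),
              x$a_target))
  cat(sprintf("  Emin = %.6g pN nm  (n_feasible = %d)\n", x$emin, x$n_feasible))
  cat(sprintf("  a = %.4g, c = %.4g", x$best["a"], x$best["c"]))
  if (!is.na(x$best["ah"])) {
    cat(sprintf(", ah = %.4g, l = %.4g", x$best["ah"], x$best["l"]))
  }
  cat(sprintf(" nm; hos = %.4g nm\n", x$hos))
  invisible(x)
}

#' Relative stability of a conformation against the single oblate spheroid
#'
#' `delta_emin = Emin(1x0x0) - Emin(conf)` at the same total membrane area
#' and parameters: positive values mean the labelled conformation is the more
#' stable, negative values favor the single (mature cell plate-like)
#' spheroid.
#'
#' @inheritParams minimize_energy
#' @param ref_fit optional precomputed `cp_fit` of the single spheroid at the
#'   same area and parameters (reused across conformations).
#' @return The energy difference in pN nm.
#' @export
delta_emin <- function(conf, a_target, p, grid = grid_spec(), base = NULL,
                       ref_fit = NULL) {
  if (is.null(ref_fit)) {
    ref_fit <- minimize_energy(conformation("1x0x0"), a_target, p, grid)
  }
  fit <- minimize_energy(conf, a_target, p, grid, base = base)
  ref_fit$emin - fit$emin
}

#' Stability curve: relative stability versus total area
#'
#' Evaluates [delta_emin()] over an increasing sequence of total membrane
#' areas. Total area grows monotonically as cytokinetic vesicles arrive, so
#' it serves as a proxy for time during cell-plate development. Per-area
#' failures are recorded as `NA` and the curve continues.
#'
#' @inheritParams minimize_energy
#' @param areas increasing vector of total membrane areas, nm^2.
#' @return A tibble of class `cp_stability` with columns `area`, `emin_ref`
#'   (single spheroid), `emin`, `delta_emin`.
#' @export
stability_curve <- function(conf, areas, p, grid = grid_spec()) {
  if (is.unsorted(areas, strictly = TRUE)) {
    abort("`areas` must be strictly increasing.",
          class = "cellplate_validation_error")
  }
  rows <- purrr::map(areas, function(A) {
    tryCatch({
      ref <- minimize_energy(conformation("1x0x0"), A, p, grid)
      fit <- minimize_energy(conf, A, p, grid)
      tibble(area = A, emin_ref = ref$emin, emin = fit$emin,
             delta_emin = ref$emin - fit$emin)
    }, error = function(e) {
      warn(sprintf("Area %.4g nm^2 failed: %s", A, conditionMessage(e)))
      tibble(area = A, emin_ref = NA_real_, emin = NA_real_,
             delta_emin = NA_real_)
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "conf") <- conf
  attr(out, "params") <- p
  class(out) <- c("cp_stability", class(out))
  out
}

#' Default log-spaced area sweep
#'
#' Twenty log-spaced total areas from single-vesicle scale (1e4 nm^2) to a
#' hundred times that, the range used for the time-proxy experiments.
#'
#' @param n number of areas.
#' @param from,to sweep bounds, nm^2.
#' @return Numeric vector of areas.
#' @export
area_sweep <- function(n = 20, from = 1e4, to = 1e6) log_seq(c(from, to), n)

#' Equilibrium thickness of the single oblate spheroid across an area sweep
#'
#' Minimizes the single-spheroid energy at each area and reports the
#' equatorial-plane thickness `hos = 2c` at the optimum. With the spreading
#' force on, the thickness plateaus in the 40--80 nm band observed for
#' intermediate cell-plate stages; without it the optimum thickens without
#' bound (sphere-like growth).
#'
#' @inheritParams stability_curve
#' @return A tibble of class `cp_thickness` with columns `area`, `a`, `c`,
#'   `hos`, `emin`.
#' @export
thickness_curve <- function(areas, p, grid = grid_spec()) {
  conf <- conformation("1x0x0")
  rows <- purrr::map(areas, function(A) {
    fit <- minimize_energy(conf, A, p, grid)
    tibble(area = A, a = fit$best[["a"]], c = fit$best[["c"]],
           hos = fit$hos, emin = fit$emin)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- p
  class(out) <- c("cp_thickness", class(out))
  out
}

#' Ensemble stability: many dumbbells versus one spheroid of combined area
#'
#' Compares `k` identical disconnected copies of a conformation (default the
#' `2x1x0` dumbbell), each carrying `A_total / k` of membrane area, to a
#' single oblate spheroid of the full combined area:
#' `Emin(1x0x0 at A_total) - k * Emin(copy at A_total / k)`. The Gaussian
#' term counts the k disconnected closed components.
#'
#' @param k number of copies (`k >= 1`).
#' @param a_total combined membrane area, nm^2.
#' @inheritParams minimize_energy
#' @param ref_fit optional precomputed single-spheroid fit at `a_total`.
#' @return Energy difference in pN nm (positive: the ensemble is more
#'   stable).
#' @export
ensemble_delta <- function(k, a_total, p, grid = grid_spec(),
                           conf = conformation("2x1x0"), ref_fit = NULL) {
  stopifnot(k >= 1)
  if (is.null(ref_fit)) {
    ref_fit <- minimize_energy(conformation("1x0x0"), a_total, p, grid)
  }
  copy_fit <- minimize_energy(conf, a_total / k, p, grid)
  ref_fit$emin - k * copy_fit$emin
}

#' Spontaneous-curvature threshold for spheroid-favored maturation
#'
#' With the spreading force on, sweeps the spontaneous curvature upward from
#' `c0_range[1]` in steps of at most `step` until some listed tubular
#' conformation becomes more stable than the single oblate spheroid, then
#' bisects the bracketing interval. The returned crossing is the largest c0
#' at which the single spheroid is favored over every listed conformation:
#' maturation requires the spontaneous curvature to decay below it.
#'
#' The feasible geometry is independent of c0, so the base feasible sets are
#' computed once and reused across the whole sweep.
#'
#' @param specs list of conformations (or spec strings) to test against.
#' @param a_target total membrane area, nm^2.
#' @param p a [model_params()]; its `c0` is ignored. With `lambda = 0` the
#'   tubular conformations stay favored and the scan reports a no-threshold
#'   outcome.
#' @param c0_range sweep range, 1/nm.
#' @param step maximum sweep step, 1/nm.
#' @param grid a [grid_spec()].
#' @return The crossing c0 in 1/nm, with attribute `outcome = "threshold"`;
#'   or `NA` with `outcome = "no-threshold"` when no sign change occurs in
#'   the range (not an error).
#' @export
find_c0_threshold <- function(specs, a_target, p,
                              c0_range = c(0, 0.04), step = 0.001,
                              grid = grid_spec()) {
  p <- as_cp_params(p)
  specs <- lapply(specs, function(s) if (is.character(s)) conformation(s) else s)
  ref_conf <- conformation("1x0x0")
  base_ref <- feasible_set(ref_conf, a_target, grid)
  bases <- lapply(specs, feasible_set, a_target = a_target, grid = grid)

  with_c0 <- function(c0) {
    q <- p; q$c0 <- c0
    ref <- minimize_energy(ref_conf, a_target, q, grid, base = base_ref)
    d <- vapply(seq_along(specs), function(i) {
      fit <- minimize_energy(specs[[i]], a_target, q, grid, base = bases[[i]])
      ref$emin - fit$emin
    }, numeric(1))
    max(d)  # > 0 once any tubular conformation is favored
  }

  c0s <- seq(c0_range[1], c0_range[2], by = step)
  if (c0s[length(c0s)] < c0_range[2]) c0s <- c(c0s, c0_range[2])
  f_prev <- with_c0(c0s[1])
  if (f_prev >= 0) {
    out <- NA_real_
    attr(out, "outcome") <- "no-threshold"
    attr(out, "detail") <- "tubular conformations favored over the whole range"
    return(out)
  }
  bracket <- NULL
  for (i in seq(2, length(c0s))) {
    f_cur <- with_c0(c0s[i])
    if (f_cur >= 0) {
      bracket <- c(c0s[i - 1], c0s[i])
      break
    }
    f_prev <- f_cur
  }
  if (is.null(bracket)) {
    out <- NA_real_
    attr(out, "outcome") <- "no-threshold"
    attr(out, "detail") <- "single spheroid favored over the whole range"
    return(out)
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > step / 20) {
    mid <- (lo + hi) / 2
    if (with_c0(mid) >= 0) hi <- mid else lo <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "outcome") <- "threshold"
  out
}

#' Sign map of relative stability over bending modulus and spreading force
#'
#' Evaluates the sign of `delta_emin(conf)` on a (KB, lambda) grid with the
#' Gaussian modulus tied to `-0.8 KB` throughout. Geometry descriptors do not
#' depend on KB or lambda, so the feasible sets are computed once and the map
#' is evaluated algebraically.
#'
#' @inheritParams minimize_energy
#' @param kb_values,lambda_values grid axes (pN nm and pN/nm).
#' @return A tibble with columns `kb`, `lambda`, `delta_emin`,
#'   `spheroid_favored`.
#' @export
kb_lambda_sweep <- function(conf, a_target, kb_values, lambda_values, p,
                            grid = grid_spec()) {
  p <- as_cp_params(p)
  ref_conf <- conformation("1x0x0")
  base_ref <- feasible_set(ref_conf, a_target, grid)
  base_conf <- feasible_set(conf, a_target, grid)
  cells <- expand.grid(kb = kb_values, lambda = lambda_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(cells, function(kb, lambda) {
    q <- p; q$kb <- kb; q$kg <- -0.8 * kb; q$lambda <- lambda
    d <- tryCatch({
      e_ref <- min(energy_from_descriptors(base_ref, q, ref_conf))
      e_conf <- min(energy_from_descriptors(base_conf, q, conf))
      e_ref - e_conf
    }, error = function(e) NA_real_)
    tibble(kb = kb, lambda = lambda, delta_emin = d,
           spheroid_favored = !is.na(d) & d < 0)
  })
  dplyr::bind_rows(rows)
}

#' Gap shrinkage of a fenestrated conformation under the spreading force
#'
#' Minimizes the energy of a fenestrated (ring or ladder) conformation at
#' each spreading-force value and reports the fenestration (gap) area at the
#' optimum, computed by rasterization with border flood fill. The gap area at
#' the optimum is non-increasing in lambda: the spreading force rewards gap
#' closure.
#'
#' @inheritParams minimize_energy
#' @param lambda_values spreading-force values to sweep, pN/nm.
#' @return A tibble with columns `lambda`, `gap_area`, `a_eq`, `emin`, `hos`.
#' @export
gap_shrink_experiment <- function(conf, a_target, p, lambda_values,
                                  grid = grid_spec()) {
  p <- as_cp_params(p)
  if (conf$g < 1) {
    abort("Gap shrinkage needs a fenestrated conformation (G >= 1).",
          class = "cellplate_validation_error")
  }
  base <- feasible_set(conf, a_target, grid)
  rows <- purrr::map(lambda_values, function(lam) {
    q <- p; q$lambda <- lam
    fit <- minimize_energy(conf, a_target, q, grid, base = base)
    fp <- footprint_area(fit$surface)
    tibble(lambda = lam, gap_area = fp$gap_area, a_eq = fp$a_eq,
           emin = fit$emin, hos = fit$hos)
  })
  dplyr::bind_rows(rows)
}
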