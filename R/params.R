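#' Physical parameters of the modified Helfrich energy
#'
#' Bundles the six constants of the free energy
#' `E = E_bending + E_pressure + E_tension + E_gaussian + E_spreading`
#' together with a temperature for the physiological calculations. Units are
#' fixed throughout the package: lengths in nm, energies in pN nm, pressure in
#' kPa (1 kPa = 1e-3 pN/nm^2).
#'
#' Values outside the ranges established for regular cell-plate development
#' (`kb` 62.5--200 pN nm, `c0` 0--0.04 1/nm, `dp` 2--10 kPa, `lambda` 0--6
#' pN/nm with 2--6 the maturation range, `gamma` = 1.6 pN/nm, `kg` = -0.8 kb)
#' are accepted but trigger a warning, since they produce structures that are
#' too thick or too thin for intermediate cell-plate stages.
#'
#' @param kb bending modulus, pN nm.
#' @param c0 spontaneous curvature, 1/nm.
#' @param dp magnitude of the osmotic deficit of the cell-plate lumen
#'   (p_out - p_in), kPa; the lumen loses volume during maturation, so the
#'   pressure term penalizes enclosed volume.
#' @param gamma membrane surface tension, pN/nm.
#' @param kg Gaussian bending modulus, pN nm; defaults to `-0.8 * kb`.
#' @param lambda spreading-force parameter, pN/nm (0 switches the force off).
#' @param temperature temperature, K.
#' @return An object of class `cp_params`.
#' @export
#' @examples
#' model_params(kb = 100, c0 = 0, lambda = 4)
model_params <- function(kb = 100, c0 = 0.02, dp = 6, gamma = 1.6,
                         kg = -0.8 * kb, lambda = 4, temperature = 298.15) {
  vals <- c(kb = kb, c0 = c0, dp = dp, gamma = gamma, kg = kg,
            lambda = lambda, temperature = temperature)
  if (!is.numeric(vals) || anyNA(vals)) {
    abort("All model parameters must be finite numbers.",
          class = "cellplate_validation_error")
  }
  if (kb <= 0) abort("`kb` must be positive.", class = "cellplate_validation_error")
  if (c0 < 0) abort("`c0` must be non-negative.", class = "cellplate_validation_error")
  if (gamma < 0) abort("`gamma` must be non-negative.", class = "cellplate_validation_error")
  if (lambda < 0) abort("`lambda` must be non-negative.", class = "cellplate_validation_error")
  if (dp < 0) abort("`dp` must be non-negative.", class = "cellplate_validation_error")
  if (temperature <= 0) abort("`temperature` must be positive.", class = "cellplate_validation_error")

  out_of_range <- character()
  if (kb < 62.5 || kb > 200) out_of_range <- c(out_of_range, "kb outside [62.5, 200] pN nm")
  if (c0 > 0.04) out_of_range <- c(out_of_range, "c0 outside [0, 0.04] 1/nm")
  if (dp != 0 && (dp < 2 || dp > 10)) out_of_range <- c(out_of_range, "dp outside [2, 10] kPa")
  if (lambda > 6) out_of_range <- c(out_of_range, "lambda outside [0, 6] pN/nm")
  if (abs(gamma - 1.6) > 1e-9 && gamma != 0) {
    out_of_range <- c(out_of_range, "gamma differs from 1.6 pN/nm")
  }
  if (abs(kg + 0.8 * kb) > 1e-9 * kb && kg != 0) {
    out_of_range <- c(out_of_range, "kg differs from -0.8*kb")
  }
  if (length(out_of_range) > 0) {
    warn(paste0("Parameters outside the regular cell-plate development ranges: ",
                paste(out_of_range, collapse = "; ")),
         class = "cellplate_range_warning")
  }

  structure(
    list(kb = kb, c0 = c0, dp = dp, gamma = gamma, kg = kg,
         lambda = lambda, temperature = temperature),
    class = "cp_params"
  )
}

#' @export
print.cp_params <- function(x, ...) {
  cat("<cp_params> modified Helfrich energy parameters\n")
  cat(sprintf("  kb      = %g pN nm   (bending modulus)\n", x$kb))
  cat(sprintf("  c0      = %g 1/nm    (spontaneous curvature)\n", x$c0))
  cat(sprintf("  dp      = %g kPa     (osmotic pressure difference)\n", x$dp))
  cat(sprintf("  gamma   = %g pN/nm   (surface tension)\n", x$gamma))
  cat(sprintf("  kg      = %g pN nm   (Gaussian modulus)\n", x$kg))
  cat(sprintf("  lambda  = %g pN/nm   (spreading force)\n", x$lambda))
  cat(sprintf("  T       = %g K\n", x$temperature))
  invisible(x)
}

#' @method as_tibble cp_params
#' @export
as_tibble.cp_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

# Internal: accept either a cp_params or a bare list with the same fields.
as_cp_params <- function(p) {
  if (inherits(p, "cp_params")) return(p)
  abort("Expected a `cp_params` object (see `model_params()`).",
        class = "cellplate_validation_error")
}

#' Search-grid specification for energy minimization
#'
#' Controls the deterministic grid-plus-refinement search used by
#' [minimize_energy()]. Axes are log-spaced. For conformations with tubes the
#' grid runs over (c, ah, l) and the equatorial radius `a` is root-solved from
#' the fixed-area constraint; for the single oblate spheroid only `c` is
#' gridded (with `n_single` points).
#'
#' @param n points per axis for the (c, ah, l) grid.
#' @param n_single points on the `c` axis for single-spheroid problems.
#' @param c_lim,ah_lim,l_lim,a_lim axis bounds, nm.
#' @param refine number of local refinement rounds around the incumbent.
#' @param shrink factor by which each axis window shrinks per round.
#' @param n_refine points per axis in refinement rounds.
#' @param n_quad Gauss-Legendre nodes per axis for tube/cap quadrature during
#'   the search (final results are re-validated at doubled order).
#' @param footprint_n rasterization cells across the bounding box for
#'   fenestrated (ring/ladder) footprints during the search.
#' @param area_rtol relative area tolerance accepted for feasible shapes.
#' @return An object of class `cp_grid`.
#' @export
grid_spec <- function(n = 16, n_single = 48,
                      c_lim = c(5, 200), ah_lim = c(5, 100),
                      l_lim = c(10, 500), a_lim = c(10, 2000),
                      refine = 3, shrink = 4, n_refine = 7,
                      n_quad = 24, footprint_n = 128, area_rtol = 1e-4) {
  stopifnot(n >= 3, n_single >= 5, refine >= 0, shrink > 1, n_refine >= 3,
            n_quad >= 8, footprint_n >= 32, area_rtol > 0)
  check_lim <- function(lim, nm) {
    if (length(lim) != 2 || any(lim <= 0) || lim[1] >= lim[2]) {
      abort(sprintf("`%s` must be positive increasing bounds.", nm),
            class = "cellplate_validation_error")
    }
  }
  check_lim(c_lim, "c_lim"); check_lim(ah_lim, "ah_lim")
  check_lim(l_lim, "l_lim"); check_lim(a_lim, "a_lim")
  structure(
    list(n = n, n_single = n_single, c_lim = c_lim, ah_lim = ah_lim,
         l_lim = l_lim, a_lim = a_lim, refine = refine, shrink = shrink,
         n_refine = n_refine, n_quad = n_quad, footprint_n = footprint_n,
         area_rtol = area_rtol),
    class = "cp_grid"
  )
}
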