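# The five-term modified Helfrich free energy.
#
#   E = E_bending + E_pressure + E_tension + E_gaussian + E_spreading
#
# Sign conventions: pressure_energy() is signed as E = -(p_in - p_out) V; in
# the assembled cell-plate model the lumen is osmotically deflated (volume is
# lost during maturation), so model_params$dp holds the outward deficit
# p_out - p_in > 0 and total_energy() calls pressure_energy(s, -dp). The
# spreading term E_spreading = -lambda * A_eq rewards equatorial expansion
# and gap closure. The Gaussian term is purely topological (Gauss-Bonnet):
# 4 pi KG (1 - g) per closed component of genus g.

#' Bending energy of a composite surface
#'
#' `(KB/2) * integral (c1 + c2 - c0)^2 dA` over all primitives with junction
#' caps excluded. Uses the stored curvature moments, so the c0 dependence is
#' exact: `i2 - 2 c0 i1 + c0^2 A`.
#'
#' @param s a `cp_surface` from [assemble()].
#' @param kb bending modulus, pN nm.
#' @param c0 spontaneous curvature, 1/nm.
#' @return Energy in pN nm.
#' @export
#' @examples
#' sph <- assemble(conformation("1x0x0"), a = 30, c = 30)
#' bending_energy(sph, kb = 100, c0 = 0)        # 8*pi*100, any radius
#' bending_energy(sph, kb = 100, c0 = 2 / 30)   # ~0
bending_energy <- function(s, kb, c0) {
  stopifnot(inherits(s, "cp_surface"))
  kb / 2 * (s$i2 - 2 * c0 * s$i1 + c0^2 * s$area)
}

#' Osmotic pressure energy
#'
#' `-dp * V` with `dp` converted from kPa to pN/nm^2 (1 kPa = 1e-3 pN/nm^2).
#' `dp` here is the signed difference p_in - p_out. In the assembled
#' cell-plate model the lumen is osmotically deflated, so [total_energy()]
#' passes `-model_params()$dp` (see that help page).
#'
#' @inheritParams bending_energy
#' @param dp signed osmotic pressure difference (inside minus outside), kPa.
#' @return Energy in pN nm.
#' @export
#' @examples
#' sph <- assemble(conformation("1x0x0"), a = 30, c = 30)
#' pressure_energy(sph, 10)  # -0.01 * (4/3 pi 30^3) = -1131 pN nm
pressure_energy <- function(s, dp) {
  stopifnot(inherits(s, "cp_surface"))
  -dp * 1e-3 * s$volume
}

#' Surface tension energy
#'
#' `gamma * A_total` over the assembled membrane area.
#'
#' @inheritParams bending_energy
#' @param gamma surface tension, pN/nm.
#' @return Energy in pN nm.
#' @export
tension_energy <- function(s, gamma) {
  stopifnot(inherits(s, "cp_surface"))
  gamma * s$area
}

#' Gaussian (topological) bending energy
#'
#' By the Gauss-Bonnet theorem the Gaussian curvature integral of a closed
#' surface of genus g is `2 pi (2 - 2g)`, so the energy is
#' `sum_i 4 pi KG (1 - g_i)` over closed components -- no integration needed.
#' The mesh oracle verifies the theorem itself via angle defects.
#'
#' @param x a `cp_surface` or a [conformation()].
#' @param kg Gaussian bending modulus, pN nm.
#' @return Energy in pN nm.
#' @export
#' @examples
#' gaussian_energy(conformation("1x0x0"), kg = -80)  # 4*pi*(-80)
#' gaussian_energy(conformation("4x4x1"), kg = -80)  # 0 (genus 1)
gaussian_energy <- function(x, kg) {
  conf <- if (inherits(x, "cp_surface")) x$conf else x
  stopifnot(inherits(conf, "cp_conformation"))
  # per copy: components - total genus; copies are disconnected closed surfaces
  4 * pi * kg * (conf$n_components - conf$g) * conf$copies
}

#' Spreading-force energy
#'
#' `-lambda * A_eq`, the two-dimensional areal-pressure work over the covered
#' equatorial footprint (gaps excluded), so both expansion and gap closure
#' lower the energy.
#'
#' @inheritParams bending_energy
#' @param lambda spreading-force parameter, pN/nm.
#' @return Energy in pN nm.
#' @export
spreading_energy <- function(s, lambda) {
  stopifnot(inherits(s, "cp_surface"))
  -lambda * s$a_eq
}

#' Total modified Helfrich energy with breakdown
#'
#' Evaluates all five energy terms and their exact sum for an assembled
#' surface under a parameter set.
#'
#' @param s a `cp_surface` from [assemble()].
#' @param p a [model_params()].
#' @return A one-row tibble of class `cp_energy` with columns `e_bending`,
#'   `e_pressure`, `e_tension`, `e_gaussian`, `e_spreading`, `e_total`, plus
#'   the six parameters echoed for provenance.
#' @export
#' @examples
#' sph <- assemble(conformation("1x0x0"), a = 30, c = 30)
#' p <- model_params(kb = 100, c0 = 0, dp = 0, gamma = 0, kg = -80, lambda = 0)
#' total_energy(sph, p)  # 8*pi*100 + 4*pi*(-80)
total_energy <- function(s, p) {
  p <- as_cp_params(p)
  eb <- bending_energy(s, p$kb, p$c0)
  # model_params$dp is the outward osmotic deficit p_out - p_in of the lumen,
  # so the signed pressure difference entering the energy is -dp.
  ep <- pressure_energy(s, -p$dp)
  et <- tension_energy(s, p$gamma)
  eg <- gaussian_energy(s, p$kg)
  es <- spreading_energy(s, p$lambda)
  out <- tibble(
    e_bending = eb, e_pressure = ep, e_tension = et,
    e_gaussian = eg, e_spreading = es,
    e_total = eb + ep + et + eg + es,
    kb = p$kb, c0 = p$c0, dp = p$dp, gamma = p$gamma, kg = p$kg,
    lambda = p$lambda)
  class(out) <- c("cp_energy", class(out))
  out
}

# Vectorized energy over descriptor rows (tibble with area, volume, i1, i2,
# a_eq) for a conformation's topology. The workhorse of the minimizer and of
# parameter sweeps: geometry enters only through these five descriptors.
energy_from_descriptors <- function(desc, p, conf) {
  chi_sum <- (conf$n_components - conf$g) * conf$copies
  p$kb / 2 * (desc$i2 - 2 * p$c0 * desc$i1 + p$c0^2 * desc$area) +
    p$dp * 1e-3 * desc$volume +
    p$gamma * desc$area +
    4 * pi * p$kg * chi_sum -
    p$lambda * desc$a_eq
}
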