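# Physiological plausibility calculations: the van't Hoff solute
# concentration behind the osmotic pressure range, and a two-dimensional
# Flory self-avoiding-polymer model linking the polysaccharide (callose)
# synthesis rate to the spreading-force parameter lambda.

#' Solute concentration difference from the van't Hoff equation
#'
#' `dc = dp / (R T)`, reported in mol/L. The osmotic pressure range 2--10 kPa
#' corresponds to 8e-4 -- 4e-3 mol/L at room temperature, comparable to
#' protein solute concentration differences in higher plant cells.
#'
#' @param dp osmotic pressure difference, kPa.
#' @param temperature temperature, K.
#' @return Concentration difference, mol/L.
#' @export
#' @examples
#' vant_hoff_concentration(2)    # ~8e-4 mol/L
#' vant_hoff_concentration(10)   # ~4e-3 mol/L
vant_hoff_concentration <- function(dp, temperature = 298.15) {
  if (any(dp < 0)) {
    abort("`dp` must be non-negative.", class = "cellplate_validation_error")
  }
  if (any(temperature <= 0)) {
    abort("`temperature` must be positive kelvin.",
          class = "cellplate_validation_error")
  }
  # dp [kPa] = 1e3 Pa; dc [mol/m^3] = 1e3*dp/(R T); /1e3 -> mol/L
  dp / (.rgas * temperature)
}

#' Two-dimensional Flory polymer model of the spreading force
#'
#' Growing polysaccharide chains grafted in the cell-plate plane behave as
#' two-dimensional self-avoiding walks with mean-square end-to-end excursion
#' `R^2 = b^2 N^(2 nu)` (`nu = 3/4` in 2D). Once the chains overlap, the mat
#' exerts a two-dimensional spreading pressure with the semi-dilute scaling
#' `lambda = alpha kT sigma^3 b^4 N^3` (the 2D des Cloizeaux exponent
#' `2 nu / (2 nu - 1) = 3` in the monomer areal density `sigma N`). The total
#' monomer synthesis rate needed to establish that mat over a plate of area
#' `plate_area` within time `tau` is `sigma plate_area N(lambda) / tau`.
#'
#' All constants must be supplied explicitly -- the printed synthesis-rate
#' scale depends on them, so the model refuses to fabricate silent defaults.
#' A calibrated constants file ships with the package; see
#' [read_polymer_model()].
#'
#' @param b polymer segment (persistence) length, nm.
#' @param sigma areal density of growing chains, 1/nm^2.
#' @param nu Flory exponent, in (0.5, 1); 3/4 for 2D self-avoiding chains.
#' @param alpha order-one scaling prefactor of the 2D pressure law.
#' @param plate_area cell-plate area over which the mat is established, nm^2.
#' @param tau mat establishment time, s.
#' @param temperature temperature, K.
#' @return An object of class `cp_polymer`.
#' @export
polymer_model <- function(b, sigma, nu = 0.75, alpha = 1,
                          plate_area, tau, temperature = 298.15) {
  if (missing(b) || missing(sigma) || missing(plate_area) || missing(tau)) {
    abort(paste(
      "Polymer model constants (b, sigma, plate_area, tau) must be supplied",
      "explicitly; use read_polymer_model() for the calibrated set shipped",
      "with the package."),
      class = "cellplate_config_error")
  }
  if (!all(is.finite(c(b, sigma, nu, alpha, plate_area, tau, temperature)))) {
    abort("Polymer model constants must be finite.",
          class = "cellplate_config_error")
  }
  if (b <= 0 || sigma <= 0 || alpha <= 0 || plate_area <= 0 || tau <= 0) {
    abort("Polymer model constants must be positive.",
          class = "cellplate_config_error")
  }
  if (nu <= 0.5 || nu >= 1) {
    abort("Flory exponent nu must lie in (0.5, 1).",
          class = "cellplate_config_error")
  }
  structure(list(b = b, sigma = sigma, nu = nu, alpha = alpha,
                 plate_area = plate_area, tau = tau,
                 temperature = temperature),
            class = "cp_polymer")
}

#' @export
print.cp_polymer <- function(x, ...) {
  cat("<cp_polymer> 2D Flory spreading-force model\n")
  cat(sprintf("  b = %g nm, sigma = %g /nm^2, nu = %g, alpha = %g\n",
              x$b, x$sigma, x$nu, x$alpha))
  cat(sprintf("  plate_area = %g nm^2, tau = %g s, T = %g K\n",
              x$plate_area, x$tau, x$temperature))
  invisible(x)
}

#' Read polymer-model constants from a config file
#'
#' Reads a YAML (or JSON) file with fields `b`, `sigma`, `nu`, `alpha`,
#' `plate_area`, `tau`, `temperature`. The default is the calibrated set
#' shipped with the package (`extdata/polymer-defaults.yaml`).
#'
#' @param path config file path.
#' @return A [polymer_model()].
#' @export
read_polymer_model <- function(path = system.file("extdata",
                                                  "polymer-defaults.yaml",
                                                  package = "cellplate")) {
  if (!nzchar(path) || !file.exists(path)) {
    abort("Polymer constants file not found.", class = "cellplate_config_error")
  }
  x <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("b", "sigma", "plate_area", "tau")
  missing_fields <- setdiff(need, names(x))
  if (length(missing_fields) > 0) {
    abort(paste0("Polymer constants file lacks required fields: ",
                 paste(missing_fields, collapse = ", "), "."),
          class = "cellplate_config_error")
  }
  polymer_model(b = x$b, sigma = x$sigma,
                nu = x$nu %||% 0.75, alpha = x$alpha %||% 1,
                plate_area = x$plate_area, tau = x$tau,
                temperature = x$temperature %||% 298.15)
}

# Chain length sustaining a given spreading pressure.
polymer_chain_length <- function(lambda, pm) {
  (lambda / (pm$alpha * kbt(pm$temperature) * pm$sigma^3 * pm$b^4))^(1 / 3)
}

#' Polysaccharide synthesis rate required for a spreading force
#'
#' Total monomer addition rate `dN/dt` that establishes the spreading-force
#' parameter `lambda` under the 2D Flory model: strictly increasing in
#' lambda, zero at `lambda = 0`, and exactly invertible by
#' [lambda_from_rate()].
#'
#' @param lambda spreading-force parameter, pN/nm.
#' @param pm a [polymer_model()].
#' @return Rate in monomers per second.
#' @export
#' @examples
#' pm <- read_polymer_model()
#' required_synthesis_rate(4, pm)           # ~1.75e6 /s
#' compare_to_cellular_estimate(required_synthesis_rate(4, pm))
required_synthesis_rate <- function(lambda, pm) {
  if (!inherits(pm, "cp_polymer")) {
    abort("`pm` must be a polymer_model(); constants are never defaulted.",
          class = "cellplate_config_error")
  }
  if (any(lambda < 0)) {
    abort("`lambda` must be non-negative.", class = "cellplate_validation_error")
  }
  pm$sigma * pm$plate_area * polymer_chain_length(lambda, pm) / pm$tau
}

#' @rdname required_synthesis_rate
#' @param rate synthesis rate, monomers per second.
#' @export
lambda_from_rate <- function(rate, pm) {
  if (!inherits(pm, "cp_polymer")) {
    abort("`pm` must be a polymer_model().", class = "cellplate_config_error")
  }
  if (any(rate < 0)) {
    abort("`rate` must be non-negative.", class = "cellplate_validation_error")
  }
  n <- rate * pm$tau / (pm$sigma * pm$plate_area)
  pm$alpha * kbt(pm$temperature) * pm$sigma^3 * pm$b^4 * n^3
}

#' Ratio of a synthesis rate to the cellular callose-synthase estimate
#'
#' Divides a required synthesis rate by the cellular reference value
#' (1.8e5 monomers/s, from in vitro callose synthase activity at average
#' eukaryotic protein concentration).
#'
#' @param rate synthesis rate, monomers per second.
#' @param reference cellular reference rate, monomers per second.
#' @return Dimensionless ratio.
#' @export
compare_to_cellular_estimate <- function(rate, reference = 1.8e5) {
  if (any(rate < 0)) {
    abort("`rate` must be non-negative.", class = "cellplate_validation_error")
  }
  rate / reference
}
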