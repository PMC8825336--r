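#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a minimization result
#'
#' One row per optimized shape parameter, broom style.
#'
#' @param x a `cp_fit` from [minimize_energy()].
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  est <- x$best[!is.na(x$best)]
  tibble(term = names(est), estimate = unname(est),
         unit = rep("nm", length(est)))
}

#' Glance at a minimization result
#'
#' @inheritParams tidy.cp_fit
#' @return A one-row tibble with the conformation, target area, minimum
#'   energy, thickness, footprint and feasible-set size.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  tibble(conformation = format(x$conf), a_target = x$a_target,
         emin = x$emin, hos = x$hos, a_eq = x$a_eq, area = x$area,
         volume = x$volume, n_feasible = x$n_feasible)
}

#' Plot a stability curve
#'
#' Relative stability (`delta_emin`, pN nm) against total membrane area (the
#' time proxy); positive values favor the labelled conformation over the
#' single oblate spheroid.
#'
#' @param object a `cp_stability` tibble from [stability_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cp_stability
#' @export
autoplot.cp_stability <- function(object, ...) {
  conf <- attr(object, "conf")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$area, y = .data$delta_emin)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(Total ~ membrane ~ area ~ (nm^2)),
      y = expression(Delta * E[min] ~ (pN %.% nm)),
      title = if (!is.null(conf)) {
        sprintf("Relative stability of %s vs single oblate spheroid",
                format(conf))
      } else NULL)
}

#' Plot an equilibrium thickness sweep
#'
#' Thickness `hos = 2c` of the optimal single oblate spheroid against total
#' area, with the 40--80 nm band of intermediate cell-plate stages shaded.
#'
#' @param object a `cp_thickness` tibble from [thickness_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cp_thickness
#' @export
autoplot.cp_thickness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$area, y = .data$hos)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 40, ymax = 80,
                      alpha = 0.15, fill = "seagreen") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Total ~ membrane ~ area ~ (nm^2)),
                  y = expression(h[os] == 2 * c ~ (nm)),
                  title = "Equilibrium thickness of the single oblate spheroid")
}

#' @importFrom rlang .data
NULL
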