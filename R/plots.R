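#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PMF profile
#'
#' Free energy along the membrane normal, with a standard-error ribbon when
#' available.
#'
#' @param object A [pmf_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$dG))
  if (!all(is.na(object$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$dG - .data$se, ymax = .data$dG + .data$se),
      fill = "grey80")
  }
  p + ggplot2::geom_line(colour = "#1f6fb4") +
    ggplot2::labs(x = "z (nm)",
                  y = expression(Delta * G ~ "(kJ/mol)"),
                  title = sprintf("PMF (%s-referenced)",
                                  attr(object, "reference_tag"))) +
    ggplot2::theme_minimal()
}

#' Plot a diffusion profile
#'
#' Local diffusion coefficient on a log scale, with cross-walker standard
#' errors when available.
#'
#' @param object A [diffusion_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$D))
  if (!all(is.na(object$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$D - .data$se, .Machine$double.xmin),
                   ymax = .data$D + .data$se),
      fill = "grey80")
  }
  p + ggplot2::geom_line(colour = "#b44d1f") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "z (nm)", y = expression(D ~ (nm^2 / ps))) +
    ggplot2::theme_minimal()
}

#' Plot the 2D free-energy landscape estimate
#'
#' Raster of the bias free-energy estimate over the spatial x alchemical
#' grid (the sampled analogue of a 2D free-energy landscape figure).
#'
#' @param object An `awh_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.awh_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$lambda_index - 1,
                                  fill = .data$f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "f (kJ/mol)") +
    ggplot2::labs(x = "z (nm)", y = "lambda state (0 = coupled)") +
    ggplot2::theme_minimal()
}

#' Convergence comparison plot
#'
#' Root-mean-square deviation of the sampled PMF from the analytic
#' reference as a function of sampling, one line per method (e.g. 1D vs 2D
#' reaction coordinates), as produced by [demo_convergence()].
#'
#' @param data A tibble with columns `method`, `samples` (or `steps`), and
#'   `rmsd`.
#' @return A ggplot.
#' @export
plot_convergence <- function(data) {
  xcol <- if ("samples" %in% names(data)) "samples" else "steps"
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[xcol]], y = .data$rmsd,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xcol, y = "PMF RMSD vs reference (kJ/mol)") +
    ggplot2::theme_minimal()
}
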