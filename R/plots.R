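# ggplot2 display methods for profiles, pair distributions and fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scattering profile
#'
#' Intensity against q on a log10 intensity scale (the standard SAXS
#' display); error bars are drawn when a sigma column is present.
#'
#' @param object A `saxs_profile`.
#' @param log_y Use a log10 intensity axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_profile <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "q (1/Å)", y = "I(q)")
  if ("sigma" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$intensity - .data$sigma,
                   ymax = .data$intensity + .data$sigma),
      alpha = 0.4)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a pair-distance distribution
#'
#' @param object A `saxs_pr`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_pr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "p(r)")
}

#' Plot a grid-search fit
#'
#' chi over the (c1, c2) grid with the minimum marked.
#'
#' @param object A `saxs_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$c1, y = .data$c2,
                                            fill = .data$chi)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$c1, y = object$c2,
                      colour = "white", shape = 4, size = 3) +
    ggplot2::labs(x = "c1 (excluded volume)", y = "c2 (hydration shell)",
                  fill = if (object$squared) "chi^2" else "chi")
}

#' Guinier plot
#'
#' ln I against q^2 with the fitted linear region highlighted.
#'
#' @param profile A `saxs_profile`.
#' @param fit Optionally a precomputed [guinier_fit()] result.
#' @return A ggplot.
#' @export
plot_guinier <- function(profile, fit = guinier_fit(profile)) {
  df <- dplyr::filter(tibble::as_tibble(profile), .data$q > 0,
                      .data$intensity > 0)
  df$in_fit <- df$q >= fit$fit_range[1] & df$q <= fit$fit_range[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q^2,
                                   y = log(.data$intensity))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_fit)) +
    ggplot2::geom_abline(intercept = log(fit$i0),
                         slope = -fit$rg^2 / 3, linetype = 2) +
    ggplot2::labs(x = "q² (1/Å²)", y = "ln I(q)",
                  colour = "in Guinier window")
}
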