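# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.saxs_fit
#' @export
tidy.saxs_guinier <- function(x, ...) {
  tibble::tibble(
    term = c("i0", "rg"),
    estimate = c(x$i0, x$rg)
  )
}

#' @rdname glance.saxs_fit
#' @export
glance.saxs_guinier <- function(x, ...) {
  tibble::tibble(
    i0 = x$i0, rg = x$rg, r_squared = x$r_squared,
    n_points = x$n_points,
    q_min = x$fit_range[1], q_max = x$fit_range[2]
  )
}

#' Tidy a grid-search fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `saxs_fit` (from [fit_grid()]) or `saxs_guinier` (from
#'   [guinier_fit()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.saxs_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale_c", "c1", "c2"),
    estimate = c(x$scale_c, x$c1, x$c2)
  )
}

#' Glance at a grid-search fit
#'
#' @inheritParams tidy.saxs_fit
#' @return A one-row tibble with the chi score and fit dimensions.
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(
    chi = x$chi, squared = x$squared,
    scale_c = x$scale_c, c1 = x$c1, c2 = x$c2,
    n_points = x$n_points, n_grid = nrow(x$grid)
  )
}
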