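# Real-space side of the scattering problem: the weighted pair-distance
# distribution p(r), the Fourier pair linking it to I(q), and Guinier
# analysis of the low-q region.

#' Weighted pair-distance distribution
#'
#' Histogram of all interatomic distances weighted by the zero-angle
#' form-factor products f_i(0) f_j(0) (both orderings of each pair, so
#' the off-diagonal mass is (sum f0)^2 - sum f0^2). Self-pairs (r = 0)
#' are excluded from the r > 0 profile and reported separately in the
#' `self_weight` attribute. The `rho` column is a density normalised so
#' that 4 pi * integral rho(r) dr equals the off-diagonal weight, which
#' makes [intensity_from_pr()] the exact transform mate of the
#' modulated Debye sum.
#'
#' @param structure A `saxs_structure` with >= 2 atoms.
#' @param bin_width Histogram bin width, Angstrom (default 0.25).
#' @param f0 Per-atom zero-angle weights; default is the vacuum factor at
#'   q = 0 (~ electron count Z + n_H).
#' @return A tibble of class `saxs_pr` with columns `r` (bin centers),
#'   `weight` (pair mass per bin) and `rho` (density); attributes
#'   `d_max`, `bin_width`, `self_weight`, `total_weight`.
#' @export
pair_distribution <- function(structure, bin_width = 0.25, f0 = NULL) {
  if (nrow(structure) < 2) stop("need at least 2 atoms", call. = FALSE)
  stopifnot(bin_width > 0)
  if (is.null(f0)) {
    tab0 <- form_factor_table(structure, q = 0)
    f0 <- as.vector(tab0$vacuum)
  }
  stopifnot(length(f0) == nrow(structure))
  d <- pair_distances_cpp(coords(structure))
  # pair weights for i < j; both orderings counted
  n <- nrow(structure)
  w <- numeric(length(d))
  k <- 1L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    w[k:(k + length(j) - 1)] <- 2 * f0[i] * f0[j]
    k <- k + length(j)
  }
  dmax <- max(d)
  n_bins <- max(1L, ceiling(dmax / bin_width - 1e-9))
  idx <- pmin(floor(d / bin_width), n_bins - 1)
  weight <- vapply(seq_len(n_bins) - 1L, function(b) sum(w[idx == b]),
                   numeric(1))
  out <- tibble::tibble(
    r = (seq_len(n_bins) - 0.5) * bin_width,
    weight = weight,
    rho = weight / (4 * pi * bin_width)
  )
  class(out) <- c("saxs_pr", class(tibble::tibble()))
  attr(out, "d_max") <- dmax
  attr(out, "bin_width") <- bin_width
  attr(out, "self_weight") <- sum(f0^2)
  attr(out, "total_weight") <- sum(w)
  out
}

#' Intensity from a pair distribution
#'
#' Numerical evaluation of I(q) = 4 pi * integral rho(r) sinc(qr) dr over
#' the binned density (midpoint rule on the uniform r-grid), optionally
#' adding the self-pair (diagonal) term so the result matches the full
#' Debye sum at the f(0) level of approximation.
#'
#' @param pr A `saxs_pr` (or a data frame with `r` and `rho` on a uniform
#'   grid).
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @param include_self Add the diagonal weight (attribute `self_weight`)
#'   to every q-point (default TRUE when present).
#' @return A `saxs_profile`.
#' @export
intensity_from_pr <- function(pr, q = default_q_grid(),
                              include_self = TRUE) {
  r <- pr$r
  dr <- if (length(r) > 1) r[2] - r[1] else attr(pr, "bin_width")
  if (is.null(dr)) stop("cannot infer r-grid spacing", call. = FALSE)
  qr <- outer(q, r)
  s <- ifelse(abs(qr) < 1e-6, 1 - qr^2 / 6, sin(qr) / qr)
  intensity <- 4 * pi * as.vector(s %*% pr$rho) * dr
  selfw <- attr(pr, "self_weight")
  if (include_self && !is.null(selfw)) intensity <- intensity + selfw
  saxs_profile(q, intensity, engine = "pr-transform")
}

#' Pair distribution from an intensity profile
#'
#' Inverse transform rho(r) = 1/(2 pi^2) * integral I(q) q r sin(qr) dq,
#' evaluated by the trapezoidal rule on the profile's q-grid. The profile
#' should extend far enough in q that the integrand has decayed; a
#' warning is raised otherwise.
#'
#' @param profile A `saxs_profile`.
#' @param r Real-space grid, Angstrom.
#' @return A tibble of class `saxs_pr` with columns `r` and `rho`.
#' @export
pr_from_intensity <- function(profile, r) {
  q <- profile$q
  iq <- profile$intensity
  tail_frac <- mean(abs(iq[q >= 0.9 * max(q)])) / max(abs(iq))
  if (is.finite(tail_frac) && tail_frac > 0.01) {
    warning("intensity has not decayed at q_max (tail ",
            sprintf("%.1f", 100 * tail_frac),
            "% of peak); the inverse transform will ring", call. = FALSE)
  }
  rho <- vapply(r, function(ri) {
    integrand <- iq * q * ri * sin(q * ri)
    sum(diff(q) * (integrand[-1] + integrand[-length(q)]) / 2)
  }, numeric(1)) / (2 * pi^2)
  out <- tibble::tibble(r = r, rho = rho)
  class(out) <- c("saxs_pr", class(tibble::tibble()))
  attr(out, "bin_width") <- if (length(r) > 1) r[2] - r[1] else NA_real_
  out
}

#' Operational d_max from a pair distribution
#'
#' First grid point after the global maximum of rho where the density
#' falls below `tol` of the total mass ("drops to zero" made concrete).
#'
#' @param pr A `saxs_pr`.
#' @param tol Relative cutoff (default 1e-9).
#' @return d_max estimate, Angstrom.
#' @export
pr_dmax <- function(pr, tol = 1e-9) {
  total <- sum(abs(pr$rho))
  peak <- which.max(pr$rho)
  below <- which(abs(pr$rho) < tol * total & seq_along(pr$rho) > peak)
  if (length(below) == 0) return(max(pr$r))
  pr$r[below[1]]
}

#' Guinier analysis
#'
#' Fits ln I = ln I(0) - (Rg^2 / 3) q^2 over the low-q window, iterating
#' the window so that q * Rg <= `qrg_limit` (default 1.3) at every point
#' used, and extrapolates the zero-angle intensity that the beamstop
#' hides from measurement.
#'
#' @param profile A `saxs_profile` with positive intensities at low q.
#' @param qrg_limit Upper limit on q * Rg in the fitted window.
#' @param min_points Minimum number of points in the window (default 5).
#' @return Object of class `saxs_guinier`: list with `i0`, `rg`,
#'   `fit_range`, `n_points`, `r_squared`.
#' @export
#' @examples
#' q <- seq(0.005, 0.2, by = 0.005)
#' p <- saxs_profile(q, 100 * exp(-q^2 * 20^2 / 3))
#' guinier_fit(p)
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5) {
  q <- profile$q
  iq <- profile$intensity
  use <- q > 0
  q <- q[use]; iq <- iq[use]
  if (length(q) < min_points) stop("too few points for a Guinier fit",
                                   call. = FALSE)
  window <- seq_len(min(length(q), max(min_points, 10)))
  rg <- NA_real_
  for (iter in 1:50) {
    qs <- q[window]; is <- iq[window]
    if (any(is <= 0)) {
      stop("non-positive intensities in the Guinier window", call. = FALSE)
    }
    fit <- stats::lm(log(is) ~ I(qs^2))
    slope <- stats::coef(fit)[2]
    if (slope >= 0) stop("no Guinier region: ln I does not decrease in q^2",
                         call. = FALSE)
    rg_new <- sqrt(-3 * slope)
    new_window <- which(q * rg_new <= qrg_limit)
    if (length(new_window) < min_points) {
      new_window <- seq_len(min_points)
    }
    if (!is.na(rg) && setequal(new_window, window)) break
    window <- new_window
    rg <- rg_new
  }
  qs <- q[window]; is <- iq[window]
  fit <- stats::lm(log(is) ~ I(qs^2))
  slope <- stats::coef(fit)[2]
  if (slope >= 0) stop("no Guinier region: ln I does not decrease in q^2",
                       call. = FALSE)
  y <- log(is)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  out <- list(
    i0 = exp(unname(stats::coef(fit)[1])),
    rg = sqrt(-3 * unname(slope)),
    fit_range = range(qs),
    n_points = length(qs),
    r_squared = r2
  )
  class(out) <- "saxs_guinier"
  out
}

#' Coordinate-space radius of gyration
#'
#' Rg^2 = sum w_i |r_i - rbar|^2 / sum w_i with weights `w` (default:
#' zero-angle form factors, i.e. electron counts). The direct-space
#' oracle for the Guinier estimate.
#'
#' @param structure A `saxs_structure`.
#' @param w Per-atom weights (default vacuum f(0)).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, w = NULL) {
  if (is.null(w)) {
    w <- as.vector(form_factor_table(structure, q = 0)$vacuum)
  }
  xyz <- coords(structure)
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' @export
print.saxs_guinier <- function(x, ...) {
  cat(sprintf(
    "<saxs_guinier> I(0) = %.6g, Rg = %.4g A (%d pts, q in [%.4g, %.4g], R^2 = %.4f)\n",
    x$i0, x$rg, x$n_points, x$fit_range[1], x$fit_range[2], x$r_squared))
  invisible(x)
}
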