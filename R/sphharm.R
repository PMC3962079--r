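# Multipole-expansion intensity: an independent O(N L^2) route to the
# orientationally averaged intensity, used to cross-check the Debye
# engines. Partial amplitudes
#   A_Lm(q) = 4 pi i^L sum_j f_j(q) j_L(q r_j) Y*_Lm(omega_j)
# are accumulated about an expansion origin; orthogonality of the
# harmonics then gives the intensity as the solid-angle average
#   I(q) = (1/4pi) sum_L sum_m |A_Lm(q)|^2 ,
# normalised so a single atom reproduces F^2(q) exactly (the identity
# sum_L (2L+1) j_L^2 = 1 fixes the 1/4pi factor).

# Spherical Bessel j_L(x), vectorised over x, via half-integer Bessel J
# with a series branch near x = 0 (j_L(0) = delta_L0).
.sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  if (any(small)) {
    xs <- x[small]
    if (l == 0) {
      out[small] <- 1 - xs^2 / 6
    } else {
      # x^l / (2l+1)!! with the next-order correction
      dfact <- prod(seq(1, 2 * l + 1, by = 2))
      out[small] <- xs^l / dfact * (1 - xs^2 / (2 * (2 * l + 3)))
    }
  }
  out
}

# Fully normalised associated Legendre functions Ptilde_l^m(cos theta)
# (Condon-Shortley phase, orthonormal convention) for all l <= lmax,
# m = 0..l, vectorised over the angle argument. Returns a list indexed
# [[l+1]] of matrices (n x (l+1)). The normalised three-term recurrences
# stay finite for l up to the order cap (no raw factorials).
.legendre_norm <- function(lmax, costheta) {
  n <- length(costheta)
  sintheta <- sqrt(pmax(0, 1 - costheta^2))
  out <- vector("list", lmax + 1)
  # P[l+1] holds columns m = 0..l
  pmm <- rep(1 / sqrt(4 * pi), n)   # Ptilde_0^0
  out[[1]] <- matrix(pmm, n, 1)
  for (l in seq_len(lmax)) out[[l + 1]] <- matrix(0, n, l + 1)
  for (m in 0:lmax) {
    if (m > 0) {
      pmm <- -sqrt((2 * m + 1) / (2 * m)) * sintheta * pmm
      out[[m + 1]][, m + 1] <- pmm
    }
    if (m + 1 <= lmax) {
      pm1 <- sqrt(2 * m + 3) * costheta * pmm
      out[[m + 2]][, m + 1] <- pm1
      pprev <- pmm; pcur <- pm1
      if (m + 2 <= lmax) {
        for (l in (m + 2):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          pnew <- a * (costheta * pcur - b * pprev)
          out[[l + 1]][, m + 1] <- pnew
          pprev <- pcur; pcur <- pnew
        }
      }
    }
  }
  out
}

#' Multipole partial amplitudes
#'
#' Accumulates the complex partial amplitudes A_Lm(q) of the structure's
#' scattering about an expansion origin, for L = 0..l_max and m = -L..L.
#' Atoms exactly at the origin contribute only to (0,0), the j_L(0) limit.
#'
#' @inheritParams debye_exact
#' @param l_max Expansion order (see [choose_order()]).
#' @param origin Expansion origin: `"cog"` (center of geometry, default)
#'   or a length-3 numeric.
#' @return Object of class `saxs_multipole`: list with `q`, `l_max`,
#'   `origin`, and `amps` (per-L complex matrices (2L+1) x nq, rows
#'   ordered m = -L..L).
#' @export
partial_amplitudes <- function(structure, q = default_q_grid(),
                               l_max = 15, solvent = solvent_model(),
                               table = NULL, origin = "cog") {
  stopifnot(l_max >= 0)
  table <- .table_or_build(structure, q, solvent, table)
  xyz <- coords(structure)
  o <- if (identical(origin, "cog")) colMeans(xyz) else as.numeric(origin)
  xyz <- sweep(xyz, 2, o)
  r <- sqrt(rowSums(xyz^2))
  costheta <- ifelse(r > 0, xyz[, 3] / r, 1)
  phi <- atan2(xyz[, 2], xyz[, 1])
  f <- table$combined                       # nq x N
  nq <- length(q)
  plm <- .legendre_norm(l_max, costheta)
  amps <- vector("list", l_max + 1)
  qr <- outer(q, r)                         # nq x N
  for (l in 0:l_max) {
    jl <- matrix(.sph_bessel(l, as.vector(qr)), nq)  # nq x N
    w <- f * jl                             # nq x N
    a <- matrix(0 + 0i, 2 * l + 1, nq)
    pref <- 4 * pi * (1i)^l
    for (m in 0:l) {
      ph <- exp(-1i * m * phi) * plm[[l + 1]][, m + 1]  # N complex
      alm <- pref * as.vector(w %*% ph)                 # length nq
      a[l + 1 + m, ] <- alm
      if (m > 0) a[l + 1 - m, ] <- (-1)^(l + m) * Conj(alm)
    }
    amps[[l + 1]] <- a
  }
  out <- list(q = q, l_max = l_max, origin = o, amps = amps)
  class(out) <- "saxs_multipole"
  out
}

#' Intensity from multipole amplitudes
#'
#' Sums |A_Lm(q)|^2 over all orders and averages over the solid angle:
#' I(q) = (1/4pi) sum_Lm |A_Lm|^2, which matches the Debye engines in the
#' converged limit (single atom at the origin gives exactly F^2(q)).
#'
#' @param amps A `saxs_multipole` from [partial_amplitudes()].
#' @param l_max Optionally truncate below the computed order.
#' @return A `saxs_profile`.
#' @export
intensity_sphharm <- function(amps, l_max = amps$l_max) {
  stopifnot(inherits(amps, "saxs_multipole"), l_max <= amps$l_max)
  nq <- length(amps$q)
  intensity <- numeric(nq)
  for (l in 0:l_max) {
    intensity <- intensity + colSums(Mod(amps$amps[[l + 1]])^2)
  }
  saxs_profile(amps$q, intensity / (4 * pi), engine = "sphharm")
}

#' Per-order intensity shares
#'
#' Diagnostic: the cumulative fraction of total intensity contributed by
#' each multipole order, useful for judging convergence of the expansion.
#'
#' @inheritParams intensity_sphharm
#' @return A tibble with columns `l`, `share` (fraction of the summed
#'   intensity over the whole q-grid) and `cumulative`.
#' @export
multipole_shares <- function(amps) {
  per_l <- vapply(0:amps$l_max, function(l) {
    sum(Mod(amps$amps[[l + 1]])^2)
  }, numeric(1))
  tot <- sum(per_l)
  tibble::tibble(l = 0:amps$l_max, share = per_l / tot,
                 cumulative = cumsum(per_l) / tot)
}

#' Choose the spherical-harmonic expansion order
#'
#' The angular bandwidth of the scattering integrand is about q * D, so
#' orders below the Nyquist bound q_max * d_max / 2 alias systematically.
#' The returned order is max(ceiling(q_max d_max / 2), floor), capped at
#' `cap` with a warning when the bound exceeds it.
#'
#' @param q_max Largest momentum transfer to evaluate, 1/Angstrom.
#' @param d_max Largest particle dimension, Angstrom.
#' @param floor_order Minimum order (default 15).
#' @param cap Maximum order (default 50).
#' @return Integer expansion order.
#' @export
#' @examples
#' choose_order(0.5, 40)   # Nyquist bound 10 -> floor 15
choose_order <- function(q_max, d_max, floor_order = 15, cap = 50) {
  stopifnot(q_max > 0, d_max > 0)
  nyquist <- ceiling(q_max * d_max / 2)
  order <- max(nyquist, floor_order)
  if (order > cap) {
    warning("Nyquist bound ", nyquist, " exceeds the order cap ", cap,
            "; truncating (expect systematic error at high q)",
            call. = FALSE)
    order <- cap
  }
  as.integer(order)
}

#' @export
print.saxs_multipole <- function(x, ...) {
  cat(sprintf(
    "<saxs_multipole> l_max = %d, %d q-points, origin (%.2f, %.2f, %.2f)\n",
    x$l_max, length(x$q), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}
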