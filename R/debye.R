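# Debye-equation scattering engines: exact double sum, row partial-sum
# decomposition, distance-binned evaluation, and zero-angle form-factor
# modulation. All engines evaluate
#   I(q) = sum_i sum_j F_i(q) F_j(q) sin(q r_ij) / (q r_ij)
# with the diagonal handled as the exact sinc limit 1, differing only in
# how the double sum is organised or approximated.

.table_or_build <- function(structure, q, solvent, table) {
  if (is.null(table)) {
    table <- form_factor_table(structure, q = q, solvent = solvent)
  } else {
    if (length(table$q) != length(q) || any(abs(table$q - q) > 1e-12)) {
      stop("form-factor table q-grid does not match the requested grid",
           call. = FALSE)
    }
    if (table$n_atoms != nrow(structure)) {
      stop("form-factor table was built for a different atom count",
           call. = FALSE)
    }
  }
  table
}

#' Exact Debye intensity
#'
#' The full O(N^2) double sum over all atom pairs with tabulated combined
#' form factors. This is the reference engine every approximation in the
#' package is tested against.
#'
#' @param structure A `saxs_structure` (volumes assigned; SASA too if the
#'   solvent model has c2 > 0).
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @param solvent A [solvent_model()].
#' @param table Optional precomputed [form_factor_table()] on `q`.
#' @return A `saxs_profile`.
#' @export
#' @examples
#' s <- make_toy("pair", scale = 5)
#' debye_exact(s, q = seq(0, 0.3, length.out = 31))
debye_exact <- function(structure, q = default_q_grid(),
                        solvent = solvent_model(), table = NULL) {
  if (nrow(structure) < 1) stop("structure has no atoms", call. = FALSE)
  table <- .table_or_build(structure, q, solvent, table)
  f <- table$combined
  intensity <- debye_cross_cpp(coords(structure), f, f, q)
  saxs_profile(q, intensity, engine = "debye")
}

#' Row partial sums of the Debye matrix
#'
#' Computes, for a block of row indices, the partial intensities
#' I_partial,i(q) = sum_j F_i F_j sinc(q r_ij). Partials over disjoint row
#' blocks are independent and order-free, so they can be evaluated in
#' parallel and accumulated with [combine_partials()]; summing over a
#' complete cover of rows 1..N reproduces [debye_exact()].
#'
#' @inheritParams debye_exact
#' @param rows Integer row indices in 1..N.
#' @return Matrix (length(q) x length(rows)) of partial intensities, with
#'   attributes `rows`, `q` and `n_atoms`.
#' @export
debye_partial_rows <- function(structure, rows, q = default_q_grid(),
                               solvent = solvent_model(), table = NULL) {
  n <- nrow(structure)
  rows <- as.integer(rows)
  if (any(rows < 1 | rows > n)) stop("row indices outside 1..N",
                                     call. = FALSE)
  if (anyDuplicated(rows)) stop("duplicated row indices in one block",
                                call. = FALSE)
  table <- .table_or_build(structure, q, solvent, table)
  out <- debye_rows_cpp(coords(structure), table$combined, q, rows)
  attr(out, "rows") <- rows
  attr(out, "q") <- q
  attr(out, "n_atoms") <- n
  out
}

#' Accumulate row partial sums into an intensity profile
#'
#' Errors when blocks overlap or the cover of rows 1..N is incomplete:
#' each row of the Debye matrix must be summed exactly once.
#'
#' @param ... Partial matrices from [debye_partial_rows()] (or a single
#'   list of them).
#' @return A `saxs_profile`.
#' @export
combine_partials <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.matrix(parts[[1]])) {
    parts <- parts[[1]]
  }
  rows <- unlist(lapply(parts, attr, "rows"))
  if (anyDuplicated(rows)) {
    stop("overlapping row blocks: rows ",
         paste(unique(rows[duplicated(rows)]), collapse = ", "),
         " appear more than once", call. = FALSE)
  }
  n <- attr(parts[[1]], "n_atoms")
  if (length(rows) != n || !setequal(rows, seq_len(n))) {
    stop("row blocks do not cover all ", n, " rows", call. = FALSE)
  }
  q <- attr(parts[[1]], "q")
  intensity <- Reduce(`+`, lapply(parts, rowSums))
  saxs_profile(q, intensity, engine = "debye-partial")
}

#' Histogram of pairwise distances
#'
#' All N(N-1)/2 pair distances binned into `n_bins` equal right-open bins
#' of width d_max / n_bins; the maximal distance lands in the last bin.
#' The bin populations m(r_k) drive the binned Debye engine.
#'
#' @param structure A `saxs_structure` with >= 2 atoms.
#' @param n_bins Number of bins (default 100, i.e. quantisation to
#'   multiples of d_max/100).
#' @return A tibble of class `saxs_disthist` with columns `r` (bin
#'   centers), `r_mean` (mean member distance per bin, the representative
#'   the binned engine evaluates at) and `count`, and attributes
#'   `bin_width`, `d_max`, `n_atoms`.
#' @export
build_distance_histogram <- function(structure, n_bins = 100) {
  if (nrow(structure) < 2) stop("need at least 2 atoms", call. = FALSE)
  stopifnot(n_bins >= 1)
  d <- pair_distances_cpp(coords(structure))
  dmax <- max(d)
  width <- dmax / n_bins
  idx <- pmin(floor(d / width), n_bins - 1)  # r = d_max -> last bin
  counts <- tabulate(idx + 1L, nbins = n_bins)
  # representative distance per bin: the mean of its members (falls back
  # to the bin center for empty bins). Using the member mean instead of
  # the raw center keeps the binned engine's error decreasing smoothly
  # as bins shrink instead of aliasing against the center grid.
  centers <- (seq_len(n_bins) - 0.5) * width
  sums <- rep(0, n_bins)
  agg <- tapply(d, idx, sum)
  sums[as.integer(names(agg)) + 1L] <- agg
  r_mean <- ifelse(counts > 0, sums / pmax(counts, 1L), centers)
  out <- tibble::tibble(r = centers, r_mean = r_mean, count = counts)
  class(out) <- c("saxs_disthist", class(tibble::tibble()))
  attr(out, "bin_width") <- width
  attr(out, "d_max") <- dmax
  attr(out, "n_atoms") <- nrow(structure)
  out
}

#' Distance-binned Debye intensity
#'
#' For a system of identical scatterers the form-factor product is a
#' constant per q and the double sum collapses onto the distance
#' histogram:
#' I(q) = N F^2(q) + 2 F^2(q) sum_k m(r_k) sinc(q r_k).
#' The diagonal term uses I_j(q) = F^2(q) per scatterer, consistent with
#' the zero-angle limit I(0) = N^2 F^2(0).
#'
#' @param histogram A `saxs_disthist` from [build_distance_histogram()].
#' @param f_common Common form factor: a function of q or a numeric vector
#'   on `q`.
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @param n_atoms Number of scatterers (default from the histogram).
#' @return A `saxs_profile`.
#' @export
debye_binned <- function(histogram, f_common, q = default_q_grid(),
                         n_atoms = attr(histogram, "n_atoms")) {
  fq <- if (is.function(f_common)) f_common(q) else f_common
  stopifnot(length(fq) == length(q))
  rk <- if ("r_mean" %in% names(histogram)) histogram$r_mean else
    histogram$r
  # sinc matrix: nq x nbins
  qr <- outer(q, rk)
  s <- ifelse(abs(qr) < 1e-6, 1 - qr^2 / 6, sin(qr) / qr)
  interference <- as.vector(s %*% histogram$count)
  intensity <- n_atoms * fq^2 + 2 * fq^2 * interference
  saxs_profile(q, intensity, engine = "debye-binned")
}

#' Form-factor-modulated Debye intensity
#'
#' Approximates every atom's factor by its zero-angle value times a shared
#' Gaussian modulation, f_i(q) = f_i(0) E(q) with E^2(q) = exp(-b q^2), so
#' the double sum is computed once from the f(0) weights and multiplied by
#' the modulation:
#' I(q) = exp(-b q^2) sum_ij f_i(0) f_j(0) sinc(q r_ij).
#'
#' @inheritParams debye_exact
#' @param b Modulation width, A^2 (default 0.23, calibrated against exact
#'   all-atom profiles).
#' @param f0 Optional per-atom zero-angle factors; defaults to the
#'   combined factor at q = 0.
#' @return A `saxs_profile`.
#' @export
debye_modulated <- function(structure, q = default_q_grid(), b = 0.23,
                            solvent = solvent_model(), f0 = NULL) {
  stopifnot(b >= 0)
  if (is.null(f0)) {
    tab0 <- form_factor_table(structure, q = 0, solvent = solvent)
    f0 <- as.vector(tab0$combined)
  }
  stopifnot(length(f0) == nrow(structure))
  fmat <- matrix(rep(f0, each = length(q)), nrow = length(q))
  base <- debye_cross_cpp(coords(structure), fmat, fmat, q)
  saxs_profile(q, exp(-b * q^2) * base, engine = "debye-modulated")
}
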