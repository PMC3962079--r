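# Atomic form factors and the physical constants of Thomson scattering.

# Table of constants used for the worked Thomson numbers (electron charge,
# rest mass, speed of light, vacuum permittivity). CODATA 2018 values are
# available behind use_codata = TRUE; the defaults reproduce the classic
# printed value r_e = 2.818e-15 m to 4 significant figures.
.phys_default <- list(q_e = 1.602e-19, m_e = 9.107e-31,
                      c = 2.998e8, eps0 = 8.854e-12)
.phys_codata  <- list(q_e = 1.602176634e-19, m_e = 9.1093837015e-31,
                      c = 2.99792458e8, eps0 = 8.8541878128e-12)

#' Thomson scattering length
#'
#' The classical electron radius r_e = e^2 / (4 pi eps0 m_e c^2), the
#' amplitude an isolated electron scatters relative to the incident wave.
#' Its smallness (~1e-15 m against a meters-scale sample-detector distance)
#' is why single-electron X-ray scattering is so weak.
#'
#' @param use_codata Use CODATA 2018 constants instead of the embedded
#'   4-digit teaching values.
#' @return Length in meters (~2.818e-15).
#' @export
#' @examples
#' thomson_length()
thomson_length <- function(use_codata = FALSE) {
  k <- if (use_codata) .phys_codata else .phys_default
  k$q_e^2 / (4 * pi * k$eps0 * k$m_e * k$c^2)
}

#' Scattered-to-incident amplitude ratio
#'
#' r_e / r at sample-to-detector distance `r`: order 1e-15 at the typical
#' 3 m distance of a SAXS camera.
#'
#' @param detector_distance Distance in meters (default 3).
#' @inheritParams thomson_length
#' @return Dimensionless amplitude ratio.
#' @export
amplitude_ratio <- function(detector_distance = 3, use_codata = FALSE) {
  stopifnot(detector_distance > 0)
  thomson_length(use_codata) / detector_distance
}

#' Electron density of water
#'
#' Converts a solvent mass density to electron density: 10 electrons per
#' water molecule, 18 g/mol, Avogadro's number, and cm^3 -> A^3. Pure water
#' at 1 g/cm^3 gives the standard bulk value 0.334 e/A^3.
#'
#' @param mass_density Mass density in g/cm^3 (default 1.0).
#' @return Electron density in e/A^3.
#' @export
#' @examples
#' water_electron_density()   # 0.334
water_electron_density <- function(mass_density = 1.0) {
  stopifnot(mass_density >= 0)
  avogadro <- 6.02e23
  avogadro * 10 / 18 * mass_density / 1e24
}

#' Momentum transfer from scattering angle
#'
#' q = 4 pi sin(theta) / lambda, where 2*theta is the scattering angle.
#' Profiles recorded on the s = 2 sin(theta)/lambda convention convert via
#' q = 2 pi s.
#'
#' @param theta Half the scattering angle, radians.
#' @param wavelength X-ray wavelength in Angstrom.
#' @return q in 1/Angstrom.
#' @export
q_from_angle <- function(theta, wavelength) {
  stopifnot(wavelength > 0)
  4 * pi * sin(theta) / wavelength
}

# Range guard for the 4-Gaussian Cromer-Mann fit: reliable to ~0.33 1/A,
# unusable above 6 1/A (wide-angle work needs the 6-Gaussian fit, which is
# not embedded).
.check_q_range <- function(q, warn = TRUE, allow_waxs = FALSE) {
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  if (!allow_waxs && any(q > 6.0)) {
    stop("q exceeds 6.0 1/A, beyond any validity of the embedded ",
         "4-Gaussian Cromer-Mann fit; set allow_waxs = TRUE to override",
         call. = FALSE)
  }
  if (warn && any(q > 0.33)) {
    warning("q extends beyond 0.33 1/A where the 4-Gaussian Cromer-Mann ",
            "fit starts to lose accuracy", call. = FALSE)
  }
  invisible(q)
}

# Raw Cromer-Mann evaluation for one element, vectorised over q.
.cm_eval <- function(element, q) {
  cm <- .cm_coeff(element)
  s2 <- (q / (4 * pi))^2
  f <- rep(cm$c, length(q))
  for (k in 1:4) f <- f + cm$a[k] * exp(-cm$b[k] * s2)
  f
}

#' Vacuum (Cromer-Mann) atomic form factor
#'
#' f_v(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c for the element, plus `n_h`
#' hydrogen factors in implicit-hydrogen mode. At q = 0 this equals the
#' electron count (Z + n_h) to within the fit accuracy of the coefficients.
#'
#' @param element Element symbol (see [supported_elements()]).
#' @param q Momentum transfer grid, 1/Angstrom.
#' @param n_h Number of implicit hydrogens folded into this atom.
#' @param warn Warn when q exceeds the 0.33 1/A Cromer-Mann comfort range.
#' @param allow_waxs Permit q above 6.0 1/A (normally an error).
#' @return Numeric vector of form-factor values (electrons).
#' @export
#' @examples
#' vacuum_ff("C", 0)          # ~6 electrons
#' vacuum_ff("O", c(0, 0.1, 0.3))
vacuum_ff <- function(element, q, n_h = 0, warn = TRUE, allow_waxs = FALSE) {
  .check_q_range(q, warn = warn, allow_waxs = allow_waxs)
  f <- .cm_eval(element, q)
  if (n_h > 0) f <- f + n_h * .cm_eval("H", q)
  f
}

#' Excluded-solvent (dummy atom) form factor
#'
#' Scattering of the solvent displaced by an atom, modelled as a Gaussian
#' sphere of the atom's van der Waals volume:
#' f_s(q) = rho0 * V * exp(-q^2 V^(2/3) / (4 pi)).
#' At q = 0 this is exactly rho0 * V, the displaced electron count.
#'
#' @param volume Displaced solvent volume V in A^3 (> 0).
#' @param q Momentum transfer grid, 1/Angstrom.
#' @param rho0 Bulk solvent electron density, e/A^3 (0.334 for water).
#' @return Numeric vector (electrons).
#' @export
excluded_ff <- function(volume, q, rho0 = 0.334) {
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  if (volume <= 0) stop("displaced volume must be positive", call. = FALSE)
  rho0 * volume * exp(-q^2 * volume^(2 / 3) / (4 * pi))
}

#' Water form factor
#'
#' f_w(q) = 2 f_H(q) + f_O(q): a water molecule as the sum of its atomic
#' vacuum factors, 10 electrons at zero angle.
#'
#' @inheritParams excluded_ff
#' @return Numeric vector (electrons).
#' @export
water_ff <- function(q) {
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  2 * .cm_eval("H", q) + .cm_eval("O", q)
}

#' Solvent model parameters
#'
#' Bundles the bulk solvent electron density rho0 with the two fitted scale
#' parameters of the combined form factor: c1 scales the excluded-volume
#' contrast and c2 scales the SASA-weighted hydration-shell term.
#'
#' @param rho0 Bulk solvent electron density, e/A^3.
#' @param c1 Excluded-volume scale (1 = plain contrast subtraction).
#' @param c2 Hydration-shell scale (0 = no shell).
#' @return An object of class `saxs_solvent`.
#' @export
solvent_model <- function(rho0 = 0.334, c1 = 1.0, c2 = 0.0) {
  stopifnot(rho0 > 0, c2 >= 0)
  structure(list(rho0 = rho0, c1 = c1, c2 = c2), class = "saxs_solvent")
}

#' @export
print.saxs_solvent <- function(x, ...) {
  cat(sprintf("<saxs_solvent> rho0 = %.4g e/A^3, c1 = %.4g, c2 = %.4g\n",
              x$rho0, x$c1, x$c2))
  invisible(x)
}

#' Combined per-atom form factor
#'
#' F(q) = f_v(q) - c1 f_s(q) + c2 S f_w(q): vacuum scattering minus the
#' scaled excluded-solvent term plus the hydration-shell term weighted by
#' the atom's solvent-accessible surface fraction S.
#'
#' @inheritParams vacuum_ff
#' @param volume Displaced solvent volume, A^3.
#' @param sasa_fraction Fractional solvent-accessible surface area in
#'   \[0, 1\].
#' @param solvent A [solvent_model()].
#' @return Numeric vector (electrons).
#' @export
combined_ff <- function(element, q, volume, sasa_fraction = 0,
                        solvent = solvent_model(), n_h = 0, warn = TRUE,
                        allow_waxs = FALSE) {
  if (is.na(sasa_fraction)) {
    if (solvent$c2 != 0) {
      stop("sasa_fraction is NA but the shell term is active (c2 != 0); ",
           "run compute_sasa() first", call. = FALSE)
    }
    sasa_fraction <- 0
  }
  fv <- vacuum_ff(element, q, n_h = n_h, warn = warn, allow_waxs = allow_waxs)
  fs <- excluded_ff(volume, q, rho0 = solvent$rho0)
  fv - solvent$c1 * fs + solvent$c2 * sasa_fraction * water_ff(q)
}

# Per-atom factor matrices (nq x N) for a structure: the building blocks
# of every scattering engine. Water scatterers (is_water) use the water
# factor with no excluded/shell term of their own.
.atom_factor_matrices <- function(structure, q, solvent, warn = FALSE) {
  atoms <- as.data.frame(structure)
  n <- nrow(atoms)
  nq <- length(q)
  .check_q_range(q, warn = warn)
  fw <- water_ff(q)
  fv <- matrix(0, nq, n)
  fs <- matrix(0, nq, n)
  sw <- matrix(0, nq, n)
  cache <- list()
  for (i in seq_len(n)) {
    if (isTRUE(atoms$is_water[i]) && isTRUE(atoms$is_shell[i])) {
      fv[, i] <- fw
      next
    }
    key <- paste0(.element_key(atoms$element[i]), ":", atoms$n_implicit_h[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- .cm_eval(atoms$element[i], q) +
        atoms$n_implicit_h[i] * .cm_eval("H", q)
    }
    fv[, i] <- cache[[key]]
    v <- atoms$displaced_volume[i]
    if (is.na(v) || v <= 0) {
      stop("atom ", i, " (", atoms$element[i],
           ") has no displaced volume; run assign_volumes() first",
           call. = FALSE)
    }
    fs[, i] <- solvent$rho0 * v * exp(-q^2 * v^(2 / 3) / (4 * pi))
    s <- atoms$sasa_fraction[i]
    if (!is.na(s) && s > 0) sw[, i] <- s * fw
  }
  list(vacuum = fv, excluded = fs, shell = sw)
}

#' Tabulate form factors for a structure on a q-grid
#'
#' Precomputes per-atom vacuum, excluded-solvent and shell factor matrices
#' and the combined factor F(q) = f_v - c1 f_s + c2 S f_w used by the
#' scattering engines.
#'
#' @param structure A `saxs_structure` (see [read_pdb()], [make_toy()]).
#' @param q Ascending momentum-transfer grid, 1/Angstrom.
#' @param solvent A [solvent_model()].
#' @param warn Warn when the grid exceeds the Cromer-Mann comfort range.
#' @return An object of class `saxs_fftable`: list with `q`, matrices
#'   `vacuum`, `excluded`, `shell`, `combined` (each nq x N), the water
#'   factor `water`, and the solvent model.
#' @export
form_factor_table <- function(structure, q = default_q_grid(),
                              solvent = solvent_model(), warn = FALSE) {
  stopifnot(is.numeric(q), !is.unsorted(q))
  mats <- .atom_factor_matrices(structure, q, solvent, warn = warn)
  combined <- mats$vacuum - solvent$c1 * mats$excluded +
    solvent$c2 * mats$shell
  out <- list(q = q, vacuum = mats$vacuum, excluded = mats$excluded,
              shell = mats$shell, combined = combined, water = water_ff(q),
              solvent = solvent, n_atoms = ncol(combined))
  class(out) <- "saxs_fftable"
  out
}

#' @export
print.saxs_fftable <- function(x, ...) {
  cat(sprintf(
    "<saxs_fftable> %d atoms, %d q-points in [%.3g, %.3g] 1/A; c1 = %.3g, c2 = %.3g\n",
    x$n_atoms, length(x$q), min(x$q), max(x$q), x$solvent$c1, x$solvent$c2))
  invisible(x)
}

#' Default momentum-transfer grid
#'
#' 101 points from 0 to 0.5 1/Angstrom inclusive, covering the usual SAXS
#' measurement window.
#'
#' @param q_max Upper grid limit, 1/Angstrom.
#' @param n Number of grid points.
#' @return Numeric vector.
#' @export
default_q_grid <- function(q_max = 0.5, n = 101) {
  if (q_max <= 0) stop("empty q-grid: q_max must be positive", call. = FALSE)
  seq(0, q_max, length.out = n)
}
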