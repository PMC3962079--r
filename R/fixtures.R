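# Deterministic synthetic structures and analytic oracles: every engine
# in the package can be exercised without downloading a single file.

# Minimal multiplicative congruential generator (MINSTD, Park-Miller
# 1988: s <- 16807 s mod (2^31 - 1)) so fixtures are reproducible from an
# explicit integer seed without touching R's global RNG state.
.lcg_new <- function(seed) {
  s <- as.double(seed %% 2147483647L)
  if (s <= 0) s <- s + 2147483646
  env <- new.env(parent = emptyenv())
  env$s <- s
  env
}

.lcg_unif <- function(rng, n = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    rng$s <- (16807 * rng$s) %% 2147483647
    out[i] <- rng$s / 2147483647
  }
  out
}

# Box-Muller normals from the MINSTD stream.
.lcg_norm <- function(rng, n = 1) {
  m <- ceiling(n / 2) * 2
  u <- matrix(.lcg_unif(rng, m), ncol = 2)
  u[u[, 1] == 0, 1] <- .Machine$double.eps
  r <- sqrt(-2 * log(u[, 1]))
  z <- c(r * cos(2 * pi * u[, 2]), r * sin(2 * pi * u[, 2]))
  z[seq_len(n)]
}

#' Generate a toy structure
#'
#' Deterministic synthetic scatterer geometries for testing and
#' benchmarking: `"pair"` (two atoms `scale` apart on x), `"line"`
#' (equally spaced along x with total length `scale`), `"ring"` (regular
#' polygon of radius `scale` in the xy-plane), `"spherical_shell"`
#' (Fibonacci points on a sphere of radius `scale`), and `"random_coil"`
#' (seeded walk with 3.8 Angstrom steps -- the C-alpha virtual bond
#' length -- and soft self-avoidance). The same (spec, seed) always
#' yields bit-identical coordinates; the generator never touches R's
#' global RNG.
#'
#' @param geometry One of `"pair"`, `"line"`, `"ring"`,
#'   `"spherical_shell"`, `"random_coil"`.
#' @param n_atoms Number of atoms (forced to 2 for `"pair"`).
#' @param scale Characteristic size, Angstrom (separation, length or
#'   radius depending on the geometry).
#' @param element Element symbol for every atom.
#' @param seed Integer seed (used by `"random_coil"` only).
#' @param calpha Flag all atoms as C-alpha (handy for shell filtering
#'   with coarse models).
#' @return A `saxs_structure` with volumes assigned and
#'   `sasa_fraction = 0`.
#' @export
#' @examples
#' make_toy("ring", n_atoms = 12, scale = 10)
make_toy <- function(geometry = c("pair", "line", "ring",
                                  "spherical_shell", "random_coil"),
                     n_atoms = 2, scale = 5, element = "C", seed = 1,
                     calpha = FALSE) {
  geometry <- match.arg(geometry)
  stopifnot(n_atoms >= 1, scale > 0)
  xyz <- switch(
    geometry,
    pair = {
      n_atoms <- 2
      rbind(c(0, 0, 0), c(scale, 0, 0))
    },
    line = cbind(seq(0, scale, length.out = max(n_atoms, 2))[seq_len(n_atoms)],
                 0, 0),
    ring = {
      a <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
      cbind(scale * cos(a), scale * sin(a), 0)
    },
    spherical_shell = {
      i <- seq_len(n_atoms) - 0.5
      phi <- acos(1 - 2 * i / n_atoms)
      th <- pi * (1 + sqrt(5)) * i
      cbind(scale * sin(phi) * cos(th), scale * sin(phi) * sin(th),
            scale * cos(phi))
    },
    random_coil = {
      rng <- .lcg_new(seed)
      step <- 3.8
      pts <- matrix(0, n_atoms, 3)
      for (i in seq_len(n_atoms)[-1]) {
        for (try in 1:30) {
          v <- .lcg_norm(rng, 3)
          v <- v / sqrt(sum(v^2)) * step
          cand <- pts[i - 1, ] + v
          prev <- pts[seq_len(i - 1), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (min(d2) > 3.0^2 || try == 30) break
        }
        pts[i, ] <- cand
      }
      pts
    }
  )
  n <- nrow(xyz)
  s <- saxs_structure(
    element = rep(element, n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    atom_name = if (calpha) "CA" else element,
    res_name = "TOY", res_id = seq_len(n),
    is_calpha = rep(calpha, n),
    sasa_fraction = 0,
    identifier = sprintf("toy-%s-n%d-s%g-seed%d", geometry, n, scale, seed)
  )
  s
}

#' Generate a backbone-like pseudo-protein
#'
#' A chemically heterogeneous test structure: a seeded random-coil
#' C-alpha trace (3.8 Angstrom steps) decorated with the four backbone
#' heavy atoms N, CA, C, O per residue at fixed local offsets, with the
#' standard implicit-hydrogen counts. The element mix (different
#' displaced volumes and electron counts) makes the solvent parameters
#' c1 and c2 identifiable in fitting tests, which a single-element toy
#' cannot do: for identical atoms a c1 change is nearly indistinguishable
#' from a rescale of the profile.
#'
#' @param n_residues Number of residues (4 heavy atoms each).
#' @param seed Integer seed for the trace.
#' @param sasa Compute SASA fractions (default TRUE).
#' @return A `saxs_structure` with volumes (and optionally SASA)
#'   assigned.
#' @export
make_pseudo_protein <- function(n_residues = 25, seed = 1, sasa = TRUE) {
  stopifnot(n_residues >= 1)
  trace <- make_toy("random_coil", n_atoms = max(n_residues, 2),
                    seed = seed)
  xyz <- coords(trace)[seq_len(n_residues), , drop = FALSE]
  offs <- rbind(N = c(-1.2, 0.3, 0), CA = c(0, 0, 0),
                C = c(1.2, 0.4, 0), O = c(1.6, 1.5, 0.3))
  el <- c("N", "C", "C", "O")
  nm <- rownames(offs)
  nh <- c(1L, 1L, 0L, 0L)
  pos <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    sweep(offs, 2, xyz[i, ], "+")
  }))
  s <- saxs_structure(
    element = rep(el, n_residues),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    atom_name = rep(nm, n_residues), res_name = "GLY",
    res_id = rep(seq_len(n_residues), each = 4),
    n_implicit_h = rep(nh, n_residues),
    sasa_fraction = 0,
    identifier = sprintf("pseudo-protein-%dres-seed%d", n_residues, seed)
  )
  if (sasa) s <- compute_sasa(s)
  s
}

#' Closed-form two-atom Debye intensity
#'
#' For two identical scatterers a distance d apart the double sum
#' collapses to I(q) = 2 f^2(q) (1 + sin(qd)/(qd)). Implemented directly
#' from this closed form (no engine code), as the independent oracle for
#' the N = 2 case.
#'
#' @param f Form factor: function of q or numeric vector on `q`.
#' @param d Separation, Angstrom (> 0).
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @return A `saxs_profile`.
#' @export
two_atom_oracle <- function(f, d, q = default_q_grid()) {
  stopifnot(d > 0)
  fq <- if (is.function(f)) f(q) else f
  stopifnot(length(fq) == length(q))
  x <- q * d
  s <- ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)
  saxs_profile(q, 2 * fq^2 * (1 + s), engine = "two-atom-oracle")
}

#' Add synthetic Gaussian noise to a profile
#'
#' Per-point noise with standard deviation sigma(q) = rel_sigma * I(q);
#' the sigma column of the returned profile records the noise level, so
#' the result plays the role of an experimental measurement in fitting
#' tests. Deterministic for a fixed seed; R's global RNG is untouched.
#'
#' @param profile A `saxs_profile`.
#' @param rel_sigma Relative noise level (> 0); 0.02 corresponds to a
#'   signal-to-noise ratio of 50.
#' @param seed Integer seed.
#' @return A `saxs_profile` with noisy `intensity` and `sigma` set.
#' @export
noisy_profile <- function(profile, rel_sigma, seed = 1) {
  stopifnot(rel_sigma > 0)
  rng <- .lcg_new(seed)
  z <- .lcg_norm(rng, nrow(profile))
  sigma <- rel_sigma * profile$intensity
  saxs_profile(profile$q, profile$intensity + sigma * z, sigma = sigma,
               engine = attr(profile, "engine"))
}
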