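---
title: "Computing SAXS profiles from atomic coordinates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing SAXS profiles from atomic coordinates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsim)
```

## The scattering model

Small-angle X-ray scattering measures the orientationally averaged
intensity `I(q)` of a particle in solution as a function of the momentum
transfer `q = 4π sin(θ)/λ` (with `2θ` the scattering angle). For a
structure of `N` atoms at positions `r_i` with per-atom form factors
`F_i(q)`, the orientational average of the interference terms collapses
to a sinc kernel, giving the Debye equation

    I(q) = Σ_i Σ_j F_i(q) F_j(q) · sin(q·r_ij)/(q·r_ij),

with `r_ij = |r_i − r_j|`. `debye_exact()` evaluates this double sum
exactly (compiled, O(N²) per q-point); it is the reference engine that
every other evaluation route in the package is tested against.

Each atom's factor combines three physical contributions,

    F_i(q) = f_v,i(q) − c1·f_s,i(q) + c2·S_i·f_w(q),

* `f_v,i` — vacuum scattering of the atom's electron cloud, the
  Cromer–Mann 4-Gaussian-plus-constant parameterisation
  `Σ_k a_k exp(−b_k (q/4π)²) + c`. At `q = 0` this equals the electron
  count; in the default implicit-hydrogen mode each heavy atom also
  carries the factors of its bonded hydrogens (standard per-atom-name
  counts, e.g. backbone N→1H, CA→1H). The 4-Gaussian fit is reliable to
  about `q = 0.33 Å⁻¹` and unusable past `6 Å⁻¹`; `vacuum_ff()` warns
  and errors accordingly.
* `f_s,i` — the solvent the atom displaces, modelled as a Gaussian
  sphere of the atom's van der Waals volume:
  `f_s(q) = ρ₀ V exp(−q² V^(2/3)/4π)`, with `ρ₀ = 0.334 e Å⁻³` for
  water (derivable from 10 electrons per 18 g/mol at 1 g/cm³;
  `water_electron_density()` performs the conversion). Radii default to
  a Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å).
* `S_i·f_w` — a hydration-shell term: the whole-molecule water factor
  `f_w = 2f_H + f_O` (10 electrons at zero angle) weighted by the
  atom's fractional solvent-accessible surface area `S_i ∈ [0, 1]`,
  computed by a Shrake–Rupley sweep (probe 1.4 Å, 960 deterministic
  spiral points per atom by default; fractions change by <1% when the
  point count doubles). The absolute exposed area is also stored, but
  the dimensionless fraction is what multiplies `f_w`: it keeps the
  shell weight bounded per atom and makes `c2` directly comparable
  across structures.

`c1` scales the excluded-volume contrast and `c2` the hydration-shell
density; both are fitted to experimental data (below).

## Fast evaluation routes and their accuracy

**Row partial sums** (`debye_partial_rows()` / `combine_partials()`).
The Debye matrix is split into disjoint row blocks whose partial sums
are computed independently and added in any order; a complete cover
reproduces the exact engine to ~1e-14 relative (tested over random
partitions). This is the contract a parallel (e.g. GPU) backend needs —
block independence and order-free accumulation — executed serially here.

**Distance binning** (`build_distance_histogram()` + `debye_binned()`).
When all scatterers share one form factor, `F_i F_j = F²` factors out
of the double sum and the `N(N−1)/2` distances collapse onto a
histogram: `I(q) = N F²(q) + 2F²(q) Σ_k m(r_k) sinc(q r_k)`. Distances
are assigned by `floor(r/width)` into right-open bins of width
`d_max/n_bins` (default 100 bins; `r = d_max` goes to the last bin).
The representative distance `r_k` of each bin is the mean of its
members rather than the geometric bin center: with raw centers the
quantisation error aliases against the bin grid and does not decrease
reliably with more bins, while the member mean gives a smooth O(width²)
error that falls monotonically over `n_bins ∈ {25, 50, 100, 200}` on
the test fixtures (max relative deviation ~0.5% at 100 bins, q ≤ 0.33).
The diagonal term uses `I_j = F²` per scatterer, which is the unique
choice consistent with the zero-angle limit `I(0) = N²F²(0)`.

**Zero-angle modulation** (`debye_modulated()`). All atoms share one
Gaussian modulation, `f_i(q) ≈ f_i(0)·E(q)` with `E²(q) = exp(−b q²)`,
so the double sum is computed once from the `f(0)` weights. The default
`b = 0.23` (units Å², since the exponent must carry q²) follows the
published calibration of this approximation against exact all-atom
profiles. The premise — a common shape for all atomic factors — holds
well for vacuum factors but fails for solvent-subtracted factors near
contrast matching, where `F(0)` of carbon is ~−0.9 electrons and tiny
shape differences are amplified; the cross-engine test therefore
compares this engine at `c1 = 0`. With `b = 0` and q-independent
factors the engine is algebraically identical to the Debye sum.

**Spherical harmonics** (`partial_amplitudes()` +
`intensity_sphharm()`). An independent O(N·L²) route: partial
amplitudes `A_Lm(q) = 4π i^L Σ_j f_j(q) j_L(q r_j) Y*_Lm(ω_j)` about an
expansion origin, then `I(q) = (1/4π) Σ_Lm |A_Lm|²`. Two conventions
needed pinning:

* *Normalisation.* Summing `|A_Lm|²` with the `4π i^L` prefactor gives
  `4π F²` for a single atom (via `Σ_L (2L+1) j_L² = 1`), so a `1/4π`
  solid-angle-average factor is applied to make the single-atom case
  equal `F²(q)` and the evaluator agree with the Debye engine. The
  agreement requirement, not notation, fixes this factor.
* *Conjugation symmetry.* With the `i^L` prefactor included the
  amplitudes of real scatterers satisfy
  `A_{L,−m} = (−1)^(L+m) conj(A_{L,m})` — the familiar `(−1)^m` rule
  picks up an extra `(−1)^L` from `i^L`; the tests assert the full sign.

The expansion origin defaults to the center of geometry (convergence
degrades as atoms move far from the origin, since `j_L(qr)` needs more
orders). The order is chosen by `choose_order()`: the angular bandwidth
of the integrand is about `q·D`, so orders below the Nyquist-type bound
`q_max·d_max/2` alias systematically; the default applies a floor of 15
and a cap of 50 (with a warning, since truncation at the cap produces
systematic high-q error for large particles). Associated Legendre
functions use the fully normalised three-term recurrence
(Condon–Shortley phase, no raw factorials, stable to the cap); spherical
Bessel functions come from half-integer `besselJ` with a series branch
below `x = 1e-4` (`j_L(0) = δ_L0`, so an atom exactly at the origin
excites only the monopole).

**Explicit hydration** (`build_fcc_lattice()`,
`filter_shell_waters()`, `debye_with_waters()`). A face-centered cubic
lattice (corner + face-center points, deduplicated on a 1e-6 Å snap
grid) is built over the structure's bounding box plus a 6.5 Å margin,
anchored at the box minimum; lattice points whose minimum distance to
any Cα lies in [3.5, 6.5] Å are kept as explicit waters carrying
`f_w(q)`, and the exact Debye sum runs over all `N + W` scatterers.
Each cell contributes `8·(1/8) + 6·(1/2) = 4` effective waters — 40
electrons — so the shell contrast is `δρ = 40/L_cell³`; the default
cell edge (`default_l_cell()`, ~11 Å) is chosen to give
`δρ ≈ 0.03 e Å⁻³`, a commonly assumed hydration-shell excess density.
The cell edge is the shell-thickness/density control and is exposed in
the configuration.

## Real-space quantities

`pair_distribution()` builds the `f(0)`-weighted pair histogram
`ρ(r) = Σ_{i≠j} f_i(0) f_j(0) δ(r − d_ij)` (both orderings counted;
self-pairs reported separately as the `self_weight` attribute). The
`rho` column is normalised as a density so that the printed transform
`I(q) = 4π ∫ ρ(r) sinc(qr) dr` (`intensity_from_pr()`, midpoint rule on
the uniform grid) reproduces the zero-angle-weighted Debye sum; its
inverse `ρ(r) = (1/2π²) ∫ I(q)·qr·sin(qr) dq` (`pr_from_intensity()`,
trapezoid on the profile grid) round-trips a band-limited synthetic
`p(r)` with relative L2 error below 1% when the intensity has decayed
by `q_max` (a warning fires otherwise — truncation ringing is the
dominant inverse-transform artifact). The operational `d_max` from a
distribution is the first grid point after the global maximum where the
density falls below a relative threshold (`pr_dmax()`, default 1e-9 for
exact histograms; ~1e-4 is appropriate for numerically
inverse-transformed densities).

`guinier_fit()` regresses `ln I` on `q²` over the low-q window,
iterated to self-consistency so that `q·Rg ≤ 1.3` at every point used
(the standard window rule; both the limit and the minimum point count
are arguments), giving `Rg = sqrt(−3·slope)` and the extrapolated
`I(0)` that the beamstop hides. On exact Gaussian input the recovery is
exact to numerical precision. On computed profiles of real shapes the
Guinier approximation carries a shape-dependent systematic error: it is
well under 5% for compact random coils but exceeds 10% for hollow
shells (strong negative kurtosis of the distance distribution), which
is a property of the approximation, not of the fit.

## Fitting experimental profiles

The discrepancy score is

    χ = sqrt( (1/M) Σ_i ((I_exp(q_i) − c·I(q_i)) / σ(q_i))² ).

The square root is applied by default — the bare mean of squared
weighted residuals is available via `squared = TRUE` — because the
score is used as an RMS-type quality measure; both conventions appear
in practice and the printed definition is ambiguous between them. The
scale `c` has the closed-form minimiser
`c = Σ(I_exp I/σ²) / Σ(I²/σ²)` (`optimal_scale()`).

`fit_grid()` searches `c1 ∈ [0.95, 1.12]` step 0.005 and
`c2 ∈ [0, 4]` step 0.1 (inclusive endpoints, 35 × 41 = 1435
combinations; grids are built by integer index × step to avoid
floating-point drift). Because `F_i` is affine in `(c1, c2)`, the
intensity is exactly quadratic in them: six cross-term Debye profiles
(vacuum/excluded/shell against each other) are computed once and
reassembled algebraically at every grid point, so the exhaustive search
costs one Debye evaluation instead of 1435. A test verifies the
reassembled intensity against a direct recomputation at grid points to
1e-9. Exact χ ties are broken toward the point nearest `(1, 0)`, the
physically neutral parameter choice. Computed profiles are linearly
interpolated onto the experimental grid; experimental points outside
the computed range are dropped with a warning, and 2-column profiles
read from disk get `σ = 0.01·I` with a loud warning since the score is
undefined without uncertainties.

### Identifiability of c1 and c2

For a structure of identical atoms, a change in `c1` rescales every
`F_i` by nearly the same factor, which the free scale `c` absorbs: the
χ surface is almost flat along that direction and noisy fits slide
along it. Identifiability comes from chemical heterogeneity — atoms
with different displaced volumes and electron counts respond to `c1`
differently, and the SASA spread does the same for `c2` — and improves
with size. The self-fit recovery tests therefore use
`make_pseudo_protein()`, a coil of N/CA/C/O backbone atoms with
standard implicit hydrogens: at 500 atoms and 2% Gaussian noise
(signal-to-noise 50), the grid fit typically recovers the generating
`(c1, c2)` within one grid step — the residual c1–scale degeneracy
still lets unlucky noise realisations land two to three steps off —
while a same-size single-element toy misses `c1` by many steps at any
realisation. This mirrors practice:
solvent parameters are fitted to real proteins, not homogeneous beads.

## Synthetic data

`make_toy()` provides deterministic geometries (atom pair, line, ring,
spherical shell via Fibonacci points, and a seeded random coil with
3.8 Å steps — the Cα virtual bond length — and soft self-avoidance);
`make_pseudo_protein()` adds the heterogeneous backbone decoration; and
`noisy_profile()` adds Gaussian noise with `σ(q) = rel_sigma·I(q)`.
Randomness uses a package-local MINSTD linear congruential generator
(Park–Miller, `s ← 16807·s mod 2³¹−1`) with Box–Muller normals, so
fixtures are bit-reproducible from explicit integer seeds and never
touch R's global RNG.

What these fixtures emulate is geometry and counting statistics only.
They do not contain side-chain chemistry, conformational ensembles,
inter-particle structure factor, buffer-subtraction artifacts, or
q-dependent instrumental smearing; consequently, passing tests
demonstrate the correctness of the scattering mathematics and the
fitting machinery, not the adequacy of the solvent model for any real
protein. The noise model (independent Gaussian, σ ∝ I) is idealised:
real SAXS errors are correlated at low q and include systematic
buffer-mismatch terms.

## Numerical choices and problem sizes

* `sinc(x)` uses the series `1 − x²/6` below `|x| = 1e-6`; the Debye
  diagonal is the exact limit 1, so coincident scatterers are legal.
* The default q-grid is 101 points on [0, 0.5] Å⁻¹; the Cromer–Mann
  warning threshold (0.33 Å⁻¹) is separate from the grid default
  because experimental profiles routinely extend to 0.5.
* Physical constants use 4-digit classic values (electron charge
  1.602e-19 C, rest mass 9.107e-31 kg, c 2.998e8 m/s, ε₀ 8.854e-12)
  to reproduce the standard worked numbers — the Thomson length
  2.818e-15 m and the ~1e-15 amplitude ratio at a 3 m detector —
  exactly; CODATA 2018 values sit behind `use_codata = TRUE`.
* Test and acceptance problem sizes — 100-atom oracle comparisons,
  50-atom spherical-harmonic sweeps, a 500-atom fit-recovery fixture —
  were chosen as the smallest sizes at which each property is
  non-trivially exercised (the fit fixture because identifiability
  plateaus there; see above).

## Known limitations

* Only the 4-Gaussian Cromer–Mann coefficients for H, C, N, O, S, P and
  common biological ions are embedded; wide-angle (6-Gaussian) work and
  anomalous scattering are out of scope.
* The hydration shell is either SASA-weighted (implicit) or an FCC
  point lattice (explicit); neither models curvature-dependent water
  ordering or charge effects.
* The spherical-harmonics evaluator shares the Debye engines' per-atom
  factors; envelope-based border-layer treatments are not implemented.
* `mmCIF`, crystallographic symmetry expansion and multi-model
  ensembles are not supported; only the first MODEL of a PDB file is
  read.
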