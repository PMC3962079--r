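# Structure reading/writing, volumes, SASA and d_max.

test_that("PDB write/read round trip preserves atoms, order and coordinates", {
  s <- make_toy("ring", n_atoms = 12, scale = 10, element = "N")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2), 12)
  expect_equal(s2$element, s$element)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
  # order preserved: residue ids were written sequentially
  expect_equal(s2$res_id, s$res_id)
})

test_that("a hand-written 3-record PDB yields 3 atoms with resolved elements", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$element, c("N", "C", "C"))
  expect_true(s$is_calpha[2])
  expect_equal(s$n_implicit_h, c(1L, 1L, 0L))
})

test_that("missing files and unknown elements raise informative errors", {
  expect_error(read_pdb("no-such-file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  U   UNK A   1       0.000   0.000   0.000  1.00  0.00           U",
    "END"), f)
  expect_error(read_pdb(f), "unknown element 'U'")
})

test_that("parsed distances match a brute-force pairwise computation", {
  s <- toy_coil(100, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  xyz <- coords(s2)
  d_pkg <- sort(saxsim:::pair_distances_cpp(xyz))
  d_brute <- sort(as.vector(dist(xyz)))
  expect_equal(d_pkg, d_brute, tolerance = 1e-12)
})

test_that("displaced volumes follow (4/3) pi r^3 with cubic scaling", {
  s <- make_toy("pair", scale = 5)
  s <- assign_volumes(s, radii = c(C = 1.70))
  expect_equal(s$displaced_volume[1], 4 / 3 * pi * 1.7^3, tolerance = 1e-12)
  expect_equal(s$displaced_volume[1], 20.58, tolerance = 1e-3)
  s0 <- assign_volumes(s, radii = c(C = 0))
  expect_equal(s0$displaced_volume, c(0, 0))
  s2 <- assign_volumes(s, radii = c(C = 3.40))
  expect_equal(s2$displaced_volume[1] / s$displaced_volume[1], 8,
               tolerance = 1e-12)
  expect_error(assign_volumes(s, radii = c(O = 1.52)),
               "no van der Waals radius.*C")
})

test_that("SASA: isolated atoms are fully exposed, enclosed atoms buried, symmetry holds", {
  one <- make_toy("pair", scale = 5)[1, ]
  class(one) <- c("saxs_structure", class(tibble::tibble()))
  expect_equal(compute_sasa(one)$sasa_fraction, 1)
  # atom centered in a dense enclosing shell
  shell <- make_toy("spherical_shell", n_atoms = 200, scale = 3)
  centred <- dplyr::bind_rows(
    tibble::as_tibble(make_toy("pair", scale = 1)[1, ]),
    tibble::as_tibble(shell))
  class(centred) <- c("saxs_structure", class(tibble::tibble()))
  expect_equal(compute_sasa(centred)$sasa_fraction[1], 0)
  # two identical atoms: equal fractions by symmetry
  pair <- compute_sasa(make_toy("pair", scale = 2 * 1.70))
  # the deterministic spiral point set is not mirror-symmetric, so the
  # two fractions agree only to the point-sampling resolution
  expect_equal(pair$sasa_fraction[1], pair$sasa_fraction[2],
               tolerance = 5e-3)
  expect_lt(pair$sasa_fraction[1], 1)
})

test_that("SASA fractions converge as the point count doubles", {
  s <- make_toy("random_coil", n_atoms = 30, seed = 6)
  a <- compute_sasa(s, n_sphere_points = 960)$sasa_fraction
  b <- compute_sasa(s, n_sphere_points = 1920)$sasa_fraction
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("d_max matches geometry and brute force, and is rigid-motion invariant", {
  expect_equal(d_max(make_toy("pair", scale = 5)), 5)
  expect_equal(d_max(make_toy("ring", n_atoms = 8, scale = 7)), 14,
               tolerance = 1e-12)
  s <- toy_coil(50, seed = 8)
  expect_equal(d_max(s), max(dist(coords(s))), tolerance = 1e-12)
  r <- rot3(c(1, 2, 3), 0.7)
  expect_equal(d_max(transform_structure(s, r, c(10, -5, 3))), d_max(s),
               tolerance = 1e-9)
  one <- s[1, ]
  class(one) <- c("saxs_structure", class(tibble::tibble()))
  expect_error(d_max(one), "at least 2")
})
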