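# FCC hydration shell: lattice geometry, shell filtering, contrast.

test_that("a single FCC unit cell has 8 corners + 6 face centers = 14 points", {
  lat <- build_fcc_lattice(rbind(c(0, 0, 0), c(9.9, 9.9, 9.9)), l_cell = 10)
  expect_equal(nrow(lat), 14)
  expect_equal(attr(lat, "k"), 1)
})

test_that("bulk point density tends to 4 / l_cell^3 and scales by 8 when halved", {
  # count in a half-open interior window aligned with cell boundaries:
  # each cell then contributes exactly its 4 effective points
  count_interior <- function(l_cell, box_edge) {
    lat <- build_fcc_lattice(rbind(c(0, 0, 0), rep(box_edge, 3)),
                             l_cell = l_cell)
    o <- attr(lat, "origin")
    side <- attr(lat, "k") * l_cell
    lo <- o + 0.25 * side; hi <- o + 0.75 * side
    eps <- 1e-9
    sum(lat$x >= lo[1] - eps & lat$x < hi[1] - eps &
          lat$y >= lo[2] - eps & lat$y < hi[2] - eps &
          lat$z >= lo[3] - eps & lat$z < hi[3] - eps)
  }
  n1 <- count_interior(5, 79)   # window = 8^3 cells of edge 5
  expect_equal(n1 / 40^3, 4 / 5^3, tolerance = 1e-12)
  n2 <- count_interior(2.5, 79) # same window, 16^3 cells of edge 2.5
  expect_equal(n2 / n1, 8, tolerance = 1e-12)
})

test_that("effective waters per cell and electrons per cell follow FCC sharing", {
  eff <- 8 * (1 / 8) + 6 * (1 / 2)
  expect_equal(eff, 4)
  expect_equal(eff * 10, 40)  # 10 electrons per water
  expect_equal(water_ff(0) * eff, 40, tolerance = 0.01)
})

test_that("shell contrast is 40 / l_cell^3 and decreases with the cell edge", {
  expect_equal(shell_contrast(10), 0.04)
  l <- seq(5, 15, by = 1)
  expect_true(all(diff(shell_contrast(l)) < 0))
  expect_equal(shell_contrast(default_l_cell(0.03)), 0.03, tolerance = 1e-12)
})

test_that("the shell filter keeps waters between 3.5 and 6.5 A of a C-alpha", {
  ca <- saxs_structure("C", 0, 0, 0, atom_name = "CA", is_calpha = TRUE)
  lat <- tibble::tibble(x = c(5, 2, 8, 3.5, 6.5), y = 0, z = 0)
  class(lat) <- c("saxs_fcc", class(tibble::tibble()))
  w <- filter_shell_waters(lat, ca)
  expect_equal(sort(w$x), c(3.5, 5, 6.5))
  expect_true(all(w$is_water & w$is_shell))
})

test_that("shell membership matches a brute-force spherical scan", {
  ca <- saxs_structure("C", 0, 0, 0, atom_name = "CA", is_calpha = TRUE)
  lat <- build_fcc_lattice(rbind(-rep(8, 3), rep(8, 3)), l_cell = 2)
  w <- filter_shell_waters(lat, ca)
  r <- sqrt(lat$x^2 + lat$y^2 + lat$z^2)
  expect_equal(nrow(w), sum(r >= 3.5 & r <= 6.5))
  expect_gt(nrow(w), 0)
})

test_that("structures without C-alpha atoms are rejected", {
  s <- make_toy("pair", scale = 5)
  lat <- build_fcc_lattice(s, l_cell = 5)
  expect_error(filter_shell_waters(lat, s), "C-alpha")
})

test_that("retained waters are invariant under a joint rigid transform", {
  s <- make_toy("random_coil", n_atoms = 10, seed = 3, calpha = TRUE)
  lat <- build_fcc_lattice(s, l_cell = 4)
  w1 <- filter_shell_waters(lat, s)
  r <- rot3(c(1, 0, 2), 0.9); tr <- c(7, -3, 11)
  lat2 <- lat
  xyz <- cbind(lat$x, lat$y, lat$z) %*% t(r)
  lat2$x <- xyz[, 1] + tr[1]; lat2$y <- xyz[, 2] + tr[2]
  lat2$z <- xyz[, 3] + tr[3]
  w2 <- filter_shell_waters(lat2, transform_structure(s, r, tr))
  expect_equal(nrow(w2), nrow(w1))
})

test_that("explicit-water Debye reduces correctly and matches brute force", {
  q <- seq(0, 0.3, length.out = 16)
  s <- toy_coil(8, seed = 6)
  # empty water set: identical to the plain engine
  expect_equal(debye_with_waters(s, NULL, q = q)$intensity,
               debye_exact(s, q = q)$intensity, tolerance = 1e-14)
  # a single lone water scatters f_w^2
  w1 <- saxs_structure("O", 1, 2, 3, res_name = "HOH", is_water = TRUE,
                       is_shell = TRUE)
  pw <- debye_with_waters(w1[0, ], w1, q = q)
  expect_equal(pw$intensity, water_ff(q)^2, tolerance = 1e-12)
  # protein + 10 fixed waters against the literal oracle
  wat <- make_toy("spherical_shell", n_atoms = 10, scale = 9)
  waters <- saxs_structure(rep("O", 10), wat$x, wat$y, wat$z,
                           res_name = "HOH", is_water = TRUE,
                           is_shell = TRUE)
  p <- debye_with_waters(s, waters, q = q)
  tabs <- form_factor_table(s, q = q)
  fmat <- cbind(tabs$combined,
                matrix(rep(water_ff(q), 10), ncol = 10))
  xyz <- rbind(coords(s), coords(waters))
  expect_equal(p$intensity, oracle_debye(xyz, fmat, q), tolerance = 1e-10)
})
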