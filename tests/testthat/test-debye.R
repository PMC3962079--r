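# Debye engines: exact, partial rows, binned, modulated.

q33 <- seq(0, 0.33, length.out = 34)

test_that("a single atom gives I(q) = F^2(q)", {
  s <- make_toy("pair", scale = 5)[1, ]
  class(s) <- c("saxs_structure", class(tibble::tibble()))
  p <- debye_exact(s, q = q33)
  f <- combined_ff("C", q33, volume = s$displaced_volume[1],
                   sasa_fraction = 0, warn = FALSE)
  expect_equal(p$intensity, f^2, tolerance = 1e-14)
})

test_that("two identical atoms match the closed form to 1e-12", {
  d <- 5
  s <- make_toy("pair", scale = d)
  p <- debye_exact(s, q = q33)
  f <- combined_ff("C", q33, volume = s$displaced_volume[1],
                   sasa_fraction = 0, warn = FALSE)
  closed <- 2 * f^2 * (1 + ifelse(q33 == 0, 1, sin(q33 * d) / (q33 * d)))
  expect_equal(p$intensity, closed, tolerance = 1e-12)
})

test_that("the engine matches a literal triple-loop oracle on 30 atoms", {
  s <- toy_coil(30, seed = 3)
  tab <- form_factor_table(s, q = q33)
  p <- debye_exact(s, q = q33, table = tab)
  ora <- oracle_debye(coords(s), tab$combined, q33)
  expect_equal(p$intensity, ora, tolerance = 1e-10)
})

test_that("intensity is invariant under rigid motion and I(0) = (sum F(0))^2", {
  s <- toy_coil(25, seed = 5)
  p <- debye_exact(s, q = q33)
  s2 <- transform_structure(s, rot3(c(0, 1, 1), 1.1), c(-20, 4, 9))
  p2 <- debye_exact(s2, q = q33)
  expect_lt(max(abs(p2$intensity - p$intensity) / p$intensity), 1e-9)
  f0 <- form_factor_table(s, q = 0)$combined
  expect_equal(p$intensity[1], sum(f0)^2, tolerance = 1e-12)
})

test_that("row partial sums reproduce the exact engine for any disjoint partition", {
  s <- toy_coil(40, seed = 7)
  exact <- debye_exact(s, q = q33)
  # one block covering all rows
  all_rows <- debye_partial_rows(s, seq_len(40), q = q33)
  p_all <- combine_partials(all_rows)
  expect_equal(p_all$intensity, exact$intensity, tolerance = 1e-12)
  # two disjoint blocks
  p_two <- combine_partials(debye_partial_rows(s, 1:13, q = q33),
                            debye_partial_rows(s, 14:40, q = q33))
  expect_equal(p_two$intensity, exact$intensity, tolerance = 1e-12)
  # ten random partitions (fixed seed), arbitrary block count and order
  set.seed(42)
  for (k in 1:10) {
    perm <- sample(40)
    cuts <- sort(sample(39, sample(1:5, 1)))
    blocks <- split(perm, findInterval(seq_len(40), cuts + 1))
    parts <- lapply(sample(blocks), function(b) {
      debye_partial_rows(s, b, q = q33)
    })
    p_k <- combine_partials(parts)
    expect_equal(p_k$intensity, exact$intensity, tolerance = 1e-12)
  }
})

test_that("overlapping or incomplete row blocks are rejected", {
  s <- toy_coil(10, seed = 1)
  a <- debye_partial_rows(s, 1:6, q = q33)
  b <- debye_partial_rows(s, 5:10, q = q33)
  expect_error(combine_partials(a, b), "overlapping")
  expect_error(combine_partials(a), "do not cover")
  expect_error(debye_partial_rows(s, c(3, 3), q = q33), "duplicated")
})

test_that("distance histograms conserve pair counts and the mean distance", {
  s2 <- make_toy("pair", scale = 5)
  h2 <- build_distance_histogram(s2, n_bins = 10)
  expect_equal(sum(h2$count), 1)
  s10 <- toy_coil(10, seed = 2)
  h10 <- build_distance_histogram(s10, n_bins = 20)
  expect_equal(sum(h10$count), 45)  # N(N-1)/2
  d <- as.vector(dist(coords(s10)))
  mean_hist <- sum(h10$r * h10$count) / sum(h10$count)
  expect_lt(abs(mean_hist - mean(d)), attr(h10, "bin_width") / 2)
  # the maximal distance lands in the last bin
  expect_gt(h10$count[nrow(h10)], 0)
  expect_error(build_distance_histogram(s2[1, ]), "at least 2")
})

test_that("binned engine: total-charge limit at q = 0 and near-exact two-atom case", {
  fq <- combined_ff("C", q33, volume = 4 / 3 * pi * 1.7^3,
                    sasa_fraction = 0, warn = FALSE)
  s2 <- make_toy("pair", scale = 5)
  h <- build_distance_histogram(s2, n_bins = 500)
  b <- debye_binned(h, fq, q = q33)
  expect_equal(b$intensity[1], 4 * fq[1]^2, tolerance = 1e-12)
  o <- two_atom_oracle(fq, 5, q33)
  expect_lt(max(abs(b$intensity - o$intensity) / o$intensity), 1e-3)
})

test_that("binned engine converges monotonically to the exact engine", {
  s <- toy_coil(100, seed = 2)
  fq <- combined_ff("C", q33, volume = s$displaced_volume[1],
                    sasa_fraction = 0, warn = FALSE)
  exact <- debye_exact(s, q = q33)
  errs <- vapply(c(25, 50, 100, 200), function(nb) {
    b <- debye_binned(build_distance_histogram(s, n_bins = nb), fq,
                      q = q33)
    max(abs(b$intensity - exact$intensity) / exact$intensity)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # documented accuracy at the default 100 bins
  expect_lt(errs[3], 0.005)
})

test_that("modulated engine: zero-angle limit, b = 0 equivalence, and b refit", {
  s <- toy_coil(20, seed = 9)
  f0 <- as.vector(form_factor_table(s, q = 0)$vacuum)
  m <- debye_modulated(s, q = q33, b = 0.23, f0 = f0)
  expect_equal(m$intensity[1], sum(f0)^2, tolerance = 1e-10)
  # with b = 0 and q-independent factors the modulated sum IS the Debye sum
  m0 <- debye_modulated(s, q = q33, b = 0, f0 = f0)
  fmat <- matrix(rep(f0, each = length(q33)), nrow = length(q33))
  expect_equal(m0$intensity, oracle_debye(coords(s), fmat, q33),
               tolerance = 1e-10)
  # golden-section refit of b against the exact engine lands inside the
  # bracket with a positive optimum
  exact <- debye_exact(s, q = q33)
  obj <- function(b) {
    m <- debye_modulated(s, q = q33, b = b, f0 = f0)
    sum((log(m$intensity) - log(exact$intensity))^2)
  }
  opt <- optimize(obj, c(0, 1))
  expect_gt(opt$minimum, 0)
  expect_lt(opt$minimum, 1)
  expect_lt(obj(opt$minimum), obj(0))
})
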