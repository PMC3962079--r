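# chi scoring, scale optimisation and the (c1, c2) grid search.

test_that("chi is zero for a perfectly scaled profile and exact for one point", {
  q <- seq(0.01, 0.3, length.out = 30)
  base <- 100 * exp(-q^2 * 50)
  i_exp <- saxs_profile(q, 3 * base, sigma = rep(1, 30))
  i_calc <- saxs_profile(q, base)
  expect_equal(chi_score(i_exp, i_calc, scale = 3), 0)
  one_exp <- saxs_profile(0.1, 10, sigma = 1)
  one_calc <- saxs_profile(0.1, 8)
  expect_equal(chi_score(one_exp, one_calc, scale = 1), 2)
})

test_that("chi matches a literal transcription of the formula on random profiles", {
  set.seed(7)
  q <- seq(0.01, 0.4, length.out = 40)
  for (k in 1:50) {
    ie <- runif(40, 1, 100)
    ic <- runif(40, 1, 100)
    sg <- runif(40, 0.5, 5)
    sc <- runif(1, 0.5, 2)
    pkg <- chi_score(saxs_profile(q, ie, sigma = sg),
                     saxs_profile(q, ic), scale = sc)
    expect_equal(pkg, oracle_chi(ie, ic, sg, sc), tolerance = 1e-12)
  }
})

test_that("chi is invariant under joint rescaling of I_exp and sigma", {
  set.seed(8)
  q <- seq(0.01, 0.4, length.out = 25)
  ie <- runif(25, 1, 50); ic <- runif(25, 1, 50); sg <- runif(25, 0.5, 2)
  a <- chi_score(saxs_profile(q, ie, sigma = sg), saxs_profile(q, ic),
                 scale = 1.3)
  b <- chi_score(saxs_profile(q, 10 * ie, sigma = 10 * sg),
                 saxs_profile(q, ic), scale = 13)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("optimal scale is exact, stationary, and reduces to the plain ratio", {
  q <- seq(0.01, 0.3, length.out = 20)
  base <- 50 * exp(-q^2 * 30)
  i_exp <- saxs_profile(q, 3 * base, sigma = 0.05 * base)
  i_calc <- saxs_profile(q, base)
  expect_equal(optimal_scale(i_exp, i_calc), 3, tolerance = 1e-12)
  # stationarity on random profiles
  set.seed(9)
  for (k in 1:5) {
    ie <- runif(20, 1, 100); sg <- runif(20, 0.5, 3)
    pe <- saxs_profile(q, ie, sigma = sg)
    pc <- saxs_profile(q, base)
    c0 <- optimal_scale(pe, pc)
    chi0 <- chi_score(pe, pc, scale = c0)
    eps <- 1e-4 * c0
    expect_gte(chi_score(pe, pc, scale = c0 + eps), chi0)
    expect_gte(chi_score(pe, pc, scale = c0 - eps), chi0)
  }
  # equal sigma: weighted form collapses to dot products
  pe <- saxs_profile(q, runif(20, 1, 10), sigma = rep(2, 20))
  pc <- saxs_profile(q, base)
  expect_equal(optimal_scale(pe, pc),
               sum(pe$intensity * base) / sum(base^2), tolerance = 1e-12)
  expect_error(optimal_scale(pe, saxs_profile(q, rep(0, 20))),
               "identically zero")
})

test_that("sigma validation rejects non-positive or missing uncertainties", {
  q <- seq(0.01, 0.1, length.out = 5)
  p <- saxs_profile(q, rep(1, 5))
  expect_error(chi_score(p, p), "sigma")
  bad <- saxs_profile(q, rep(1, 5), sigma = c(1, 1, 0, 1, 1))
  expect_error(chi_score(bad, p), "positive")
})

test_that("the default grid enumerates 35 x 41 = 1435 endpoint-inclusive points", {
  expect_equal(length(saxsim:::.param_grid(c(0.95, 1.12), 0.005)), 35)
  expect_equal(length(saxsim:::.param_grid(c(0, 4.0), 0.1)), 41)
  s <- make_pseudo_protein(5, seed = 1)
  q <- seq(0.01, 0.2, length.out = 10)
  iexp <- debye_exact(s, q = q)
  iexp <- saxs_profile(q, iexp$intensity, sigma = rep(1, 10))
  fit <- fit_grid(s, iexp)
  expect_equal(nrow(fit$grid), 1435)
  # returned chi is the global minimum over the evaluated grid
  expect_true(all(fit$chi <= fit$grid$chi + 1e-12))
})

test_that("self-fit recovers the generating grid point with chi ~ 0", {
  s <- make_pseudo_protein(10, seed = 4)
  q <- seq(0.005, 0.4, length.out = 40)
  pts <- list(c(0.95, 0), c(1.0, 1.0), c(1.05, 2.0), c(1.12, 4.0),
              c(0.985, 0.3))
  for (pt in pts) {
    truth <- debye_exact(s, q = q,
                         solvent = solvent_model(c1 = pt[1], c2 = pt[2]))
    iexp <- saxs_profile(q, truth$intensity, sigma = rep(1, 40))
    fit <- fit_grid(s, iexp)
    expect_equal(c(fit$c1, fit$c2), pt, tolerance = 1e-9)
    expect_lt(fit$chi, 1e-6)
    expect_equal(fit$scale_c, 1, tolerance = 1e-6)
  }
})

test_that("the grid-search decomposition equals a direct Debye recomputation", {
  s <- make_pseudo_protein(8, seed = 6)
  q <- seq(0.01, 0.45, length.out = 20)
  iexp <- saxs_profile(q, rep(1, 20), sigma = rep(1, 20))
  fit <- fit_grid(s, iexp, c1_range = c(0.97, 1.03), c1_step = 0.03,
                  c2_range = c(0, 2), c2_step = 1)
  for (i in seq_len(nrow(fit$grid))) {
    direct <- debye_exact(s, q = q, solvent = solvent_model(
      c1 = fit$grid$c1[i], c2 = fit$grid$c2[i]))
    pc <- saxs_profile(q, direct$intensity)
    expect_equal(fit$grid$scale_c[i], optimal_scale(iexp, pc),
                 tolerance = 1e-9)
    expect_equal(fit$grid$chi[i],
                 chi_score(iexp, pc, scale = fit$grid$scale_c[i]),
                 tolerance = 1e-9)
  }
})

test_that("a single-point grid degenerates to chi of the optimal scale", {
  s <- make_pseudo_protein(6, seed = 2)
  q <- seq(0.01, 0.3, length.out = 15)
  truth <- debye_exact(s, q = q, solvent = solvent_model(c1 = 1.0, c2 = 0.5))
  iexp <- saxs_profile(q, 2 * truth$intensity,
                       sigma = 0.02 * truth$intensity)
  fit <- fit_grid(s, iexp, c1_range = c(1.0, 1.0), c1_step = 0,
                  c2_range = c(0.5, 0.5), c2_step = 0)
  expect_equal(nrow(fit$grid), 1)
  pc <- saxs_profile(q, truth$intensity)
  expect_equal(fit$scale_c, optimal_scale(iexp, pc), tolerance = 1e-10)
  expect_equal(fit$chi, chi_score(iexp, pc), tolerance = 1e-10)
})

test_that("noisy self-fits recover parameters within one grid step", {
  # parameter identifiability needs a chemically heterogeneous structure
  # of realistic size; see the methods vignette
  s <- make_pseudo_protein(125, seed = 5)  # 500 atoms
  q <- default_q_grid()
  truth <- debye_exact(s, q = q, solvent = solvent_model(c1 = 1.0, c2 = 1.0))
  iexp <- noisy_profile(truth, rel_sigma = 0.02, seed = 77)  # SNR 50
  fit <- fit_grid(s, iexp)
  expect_lte(abs(fit$c1 - 1.0), 0.005 + 1e-9)
  expect_lte(abs(fit$c2 - 1.0), 0.1 + 1e-9)
})

test_that("tidy and glance expose fit and Guinier results as tibbles", {
  s <- make_pseudo_protein(5, seed = 1)
  q <- seq(0.01, 0.3, length.out = 20)
  iexp <- saxs_profile(q, debye_exact(s, q = q)$intensity,
                       sigma = rep(1, 20))
  fit <- fit_grid(s, iexp, c1_range = c(1, 1), c1_step = 0,
                  c2_range = c(0, 0.2), c2_step = 0.1)
  td <- tidy(fit)
  expect_equal(td$term, c("scale_c", "c1", "c2"))
  gl <- glance(fit)
  expect_equal(gl$n_grid, 3)
  g <- guinier_fit(saxs_profile(q, 10 * exp(-q^2 * 100 / 3)))
  expect_equal(tidy(g)$term, c("i0", "rg"))
  expect_equal(glance(g)$rg, 10, tolerance = 1e-3)
})
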