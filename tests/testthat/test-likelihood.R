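test_that("constant-N sister-branch prior has the closed uniform-plus-mass form", {
  expect_equal(phi_density_constantN(100, 400, 100, 1e4), 1.25e-3)
  expect_equal(phi_point_mass_constantN(400, 100, 1e4), 0.5)
  expect_equal(phi_density_constantN(c(-1, 500), 400, 100, 1e4), c(0, 0))
  # degenerate branch forces a single sister
  expect_equal(phi_point_mass_constantN(1e-9, 100, 1e4), 1, tolerance = 1e-8)
  # density * t_c + mass = 1 for any parameters
  for (tc in c(3, 300, 3e4)) for (n in c(2, 50, 1000)) for (N in c(1e3, 1e5)) {
    expect_equal(phi_density_constantN(0, tc, n, N) * tc +
                   phi_point_mass_constantN(tc, n, N), 1)
  }
})

test_that("hazard-based prior reduces to the constant-N closed form and normalizes", {
  dem <- demography_constant(1e4)
  phis <- seq(0, 399, length.out = 41)
  expect_equal(phi_density_numeric(phis, 400, 100, dem),
               phi_density_constantN(phis, 400, 100, 1e4), tolerance = 1e-9)
  expect_equal(phi_point_mass_numeric(400, 100, dem),
               phi_point_mass_constantN(400, 100, 1e4), tolerance = 1e-9)
  r <- log(5e5 / 1e4) / 200
  grow <- demography_piecewise(c(0, 200), c(5e5, 1e4), c(r, 0))
  for (tc in c(60, 150, 5000)) {
    int <- stats::integrate(function(p) phi_density_numeric(p, tc, 100, grow),
                            0, tc, rel.tol = 1e-9)$value
    expect_equal(int + phi_point_mass_numeric(tc, 100, grow), 1,
                 tolerance = 1e-6)
  }
  # during recent growth the hazard is higher at the old end of the branch
  # (smaller historical N), so more sister-branch mass sits at small phi than
  # under a constant population of the final size
  for (tc in c(60, 150)) {
    q <- tc / 4
    p_growth <- stats::integrate(function(p) {
      phi_density_numeric(p, tc, 100, grow)
    }, 0, q)$value
    p_const <- phi_density_constantN(0, tc, 100, 5e5) * q
    expect_gt(p_growth, p_const)
  }
})

test_that("closed-form likelihood matches quadrature of the integral form", {
  dem <- demography_constant(1e4)
  for (tc in 10^c(1, 3, 5)) {
    for (chi in 10^seq(-6, 0, by = 2)) {
      for (m in 0:2) {
        beta <- c(1, 2e-8, 4e-16)[m + 1]
        closed <- loglik_msh(chi, beta, tc, 100, dem, m)
        quad <- loglik_msh(chi, beta, tc, 100, dem, m, method = "quadrature")
        expect_equal(closed, quad, tolerance = 1e-7)
      }
    }
  }
})

test_that("infinite-population limit recovers the single-sister forms", {
  big <- demography_constant(1e12)
  tc <- 1000
  expect_equal(loglik_msh(4e-3, 4e-16, tc, 100, big, 2),
               log(4e-16) + 2 * log(2 * tc) - 2 * 4e-3 * tc, tolerance = 1e-6)
  expect_equal(loglik_msh(3e-3, 2e-8, tc, 100, big, 1),
               log(2e-8) + log(2 * tc) - 2 * 3e-3 * tc, tolerance = 1e-6)
})

test_that("likelihood is strictly decreasing in chi at fixed t_c", {
  chis <- 10^seq(-5, -1, length.out = 30)
  for (m in 1:2) {
    ll <- loglik_msh(chis, 1e-8, 500, 100, demography_constant(1e4), m)
    expect_true(all(diff(ll) < 0))
  }
})

test_that("singleton mutation factor behaves across scales", {
  expect_equal(singleton_mutation_factor(log(2) * 1e8, 1e-8), 0.5)
  expect_equal(singleton_mutation_factor(10, 1e-8), 1e-7, tolerance = 1e-3)
  expect_equal(singleton_mutation_factor(1e12, 1e-8), 1)
  expect_equal(singleton_mutation_factor(1e4, 1e-8, log = TRUE),
               log(singleton_mutation_factor(1e4, 1e-8)))
})

test_that("composite likelihood pools copies and keeps argmax invariants", {
  params <- tc_params(mu = 1e-8, n = 100, demography = 1e4,
                      mutation_factor = FALSE)
  obs1 <- tibble::tibble(chi = 2e-3, beta = 4e-16, kernel = 2L, k = 2L)
  # k = 1 composite equals the single-copy log-likelihood
  expect_equal(composite_loglik(obs1, 750, params),
               loglik_msh(2e-3, 4e-16, 750, 100, 1e4, 2))
  # identical copies: same argmax as a single copy
  e1 <- estimate_tc(obs1, params)
  e2 <- estimate_tc(dplyr::bind_rows(obs1, obs1), params)
  expect_equal(log10(e2$t_c), log10(e1$t_c), tolerance = 1e-3)
  # different chi values: composite MLE lies between the single-copy MLEs
  obsA <- tibble::tibble(chi = 5e-4, beta = 4e-16, kernel = 2L, k = 2L)
  obsB <- tibble::tibble(chi = 2e-2, beta = 4e-16, kernel = 2L, k = 2L)
  eA <- estimate_tc(obsA, params); eB <- estimate_tc(obsB, params)
  eAB <- estimate_tc(dplyr::bind_rows(obsA, obsB), params)
  expect_gt(eAB$t_c, min(eA$t_c, eB$t_c))
  expect_lt(eAB$t_c, max(eA$t_c, eB$t_c))
  expect_error(composite_loglik(obs1[0, ], 100, params), "no observations")
})

test_that("optimizer matches a dense grid search and scales inversely with tracts", {
  set.seed(21)
  params <- tc_params(mu = 1e-8, n = 100, demography = 1e4)
  grid <- 10^seq(0, 7, length.out = 2000)
  for (i in 1:40) {
    msum <- 10^runif(1, 3, 6.5)
    kern <- sample(1:2, 1)
    beta <- if (kern == 2L) 4e-16 else 2e-8
    obs <- tibble::tibble(chi = 2e-8 * msum, beta = beta, kernel = kern,
                          k = 1L)
    est <- estimate_tc(obs, params)
    gl <- vapply(grid, function(g) composite_loglik(obs, g, params),
                 numeric(1))
    t_grid <- grid[which.max(gl)]
    expect_equal(log10(est$t_c), log10(t_grid), tolerance = log10(1.01))
    expect_gte(est$loglik, max(gl) - 1e-6)
  }
  # doubling both tracts roughly halves the estimate (rate-scale duality)
  obs <- tibble::tibble(chi = 2e-8 * 2e5, beta = 4e-16, kernel = 2L, k = 2L)
  obs2 <- tibble::tibble(chi = 2e-8 * 4e5, beta = 4e-16, kernel = 2L, k = 2L)
  p0 <- tc_params(mu = 1e-8, n = 100, demography = 1e4,
                  mutation_factor = FALSE)
  e1 <- estimate_tc(obs, p0); e2 <- estimate_tc(obs2, p0)
  expect_equal(e1$t_c / e2$t_c, 2, tolerance = 0.2)
  # estimates decrease monotonically in chi
  chis <- 2e-8 * 10^seq(3.5, 6, length.out = 10)
  ests <- vapply(chis, function(ch) {
    estimate_tc(tibble::tibble(chi = ch, beta = 4e-16, kernel = 2L, k = 2L),
                p0)$t_c
  }, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("composite likelihood is unimodal in t_c on random observation sets", {
  set.seed(33)
  params <- tc_params(mu = 1e-8, n = 100, demography = 1e4)
  grid <- seq(0, 7, length.out = 300)
  for (i in 1:15) {
    kk <- sample(1:4, 1)
    obs <- tibble::tibble(chi = 2e-8 * 10^runif(kk, 3, 6.5),
                          beta = 4e-16, kernel = 2L, k = kk)
    ll <- vapply(grid, function(l) composite_loglik(obs, 10^l, params),
                 numeric(1))
    sign_changes <- sum(diff(sign(diff(ll))) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("batch estimation agrees with per-group Brent optimization", {
  set.seed(55)
  params <- tc_params(mu = 1e-8, n = 100, demography = 1e4)
  nobs <- 30
  obs <- tibble::tibble(
    chi = 2e-8 * 10^runif(nobs, 3, 6.5),
    beta = ifelse(runif(nobs) < 0.8, 4e-16, 2e-8),
    kernel = ifelse(runif(nobs) < 0.8, 2L, 1L),
    k = sample(c(1L, 1L, 2L, 5L), nobs, replace = TRUE),
    group = rep(1:12, length.out = nobs)
  )
  batch <- estimate_tc_batch(obs, params)
  for (gidx in unique(obs$group)) {
    single <- estimate_tc(obs[obs$group == gidx, ], params)
    got <- batch$t_c[batch$group == gidx]
    expect_equal(log10(got), log10(single$t_c), tolerance = 5e-3)
  }
})

test_that("estimates are nearly invariant to the assumed population size", {
  sim <- small_sim()
  map <- genetic_map(rate = 1e-8)
  obs <- compose_chi(msh_table(sim$hm), map, 1e-8)
  obs$group <- obs$site
  e4 <- estimate_tc_batch(obs, tc_params(mu = 1e-8, n = 20, demography = 1e4))
  e5 <- estimate_tc_batch(obs, tc_params(mu = 1e-8, n = 20, demography = 1e5))
  expect_gte(stats::cor(log10(e4$t_c), log10(e5$t_c)), 0.99)
})
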