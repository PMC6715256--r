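test_that("simulations are seed-reproducible and respect mu = 0", {
  a <- simulate_sample("constant", n = 6, L_bp = 1e5, mu = 2e-8, rho = 1e-8,
                       seed = 3)
  b <- simulate_sample("constant", n = 6, L_bp = 1e5, mu = 2e-8, rho = 1e-8,
                       seed = 3)
  expect_identical(a$hm$alleles, b$hm$alleles)
  expect_identical(a$truth, b$truth)
  none <- simulate_sample("constant", n = 6, L_bp = 1e5, mu = 0, rho = 1e-8,
                          seed = 3)
  expect_equal(ncol(none$hm$alleles), 0L)
  expect_error(simulate_sample("constant", n = 7, L_bp = 1e5, mu = 1e-8,
                               rho = 0, seed = 1))
})

test_that("segregating-site counts agree with the neutral expectation", {
  sim <- simulate_sample("constant", n = 20, L_bp = 1e6, mu = 1e-8,
                         rho = 1e-8, seed = 19)
  w <- watterson_segsites(20, 1e6, 1e-8, 1e4)
  expect_equal(w$mean, 400 * sum(1 / (1:19)), tolerance = 1e-12)
  expect_lt(abs(ncol(sim$hm$alleles) - w$mean), 3 * w$sd)
})

test_that("growth and out-of-Africa demographies run and shift coalescent times", {
  grow <- simulate_sample("growth", n = 10, L_bp = 2e5, mu = 1e-8,
                          rho = 1e-8, seed = 8)
  ooa <- simulate_sample("ooa", n = 10, L_bp = 2e5, mu = 1e-8,
                         rho = 1e-8, seed = 8)
  expect_gt(nrow(grow$truth), 0)
  expect_gt(nrow(ooa$truth), 0)
  expect_true(all(grow$truth$phi <= grow$truth$tc + 1e-9))
})

test_that("first coalescence and sister length read correctly off hand trees", {
  # two leaves joined at T: t_c = phi = T for either tip
  two <- ape::read.tree(text = "(a:700,b:700);")
  got <- true_tc_phi(two, "a")
  expect_equal(got$t_c, 700)
  expect_equal(got$phi, 700)
  # ((a,b) at T1, c) at T2: focal a -> (T1, T1); focal c -> (T2, T2 - T1)
  T1 <- 300; T2 <- 1000
  three <- ape::read.tree(
    text = sprintf("((a:%d,b:%d):%d,c:%d);", T1, T1, T2 - T1, T2))
  ga <- true_tc_phi(three, "a")
  expect_equal(ga$t_c, T1); expect_equal(ga$phi, T1)
  gc <- true_tc_phi(three, "c")
  expect_equal(gc$t_c, T2); expect_equal(gc$phi, T2 - T1)
  # carrier clade {a, b}: first coalescence with a non-carrier is at T2
  gab <- true_tc_phi(three, "a", carrier_tips = c("a", "b"))
  expect_equal(gab$t_c, T2)
})

test_that("simulated truth satisfies 0 <= phi <= t_c and matches the ape reader", {
  sim <- small_sim()
  expect_true(all(sim$truth$tc > 0))
  expect_true(all(sim$truth$phi >= 0 & sim$truth$phi <= sim$truth$tc + 1e-9))
  # cross-check the backend's traversal against the R-side tree reader
  tr <- sim$truth[sim$truth$pos %in% sim$trees$pos, ]
  tr <- tr[seq_len(min(nrow(tr), 80)), ]
  for (i in seq_len(nrow(tr))) {
    tree <- marginal_tree(sim, tr$pos[i])
    carriers <- sim$truth$row[sim$truth$pos == tr$pos[i]]
    got <- true_tc_phi(tree, sprintf("n%d", tr$row[i] - 1L),
                       carrier_tips = sprintf("n%d", carriers - 1L))
    expect_equal(got$t_c, tr$tc[i], tolerance = 1e-6)
    expect_equal(got$phi, tr$phi[i], tolerance = 1e-6)
  }
})

test_that("x_AS is the per-direction distance to the nearest A/S mutation", {
  got <- extract_xas(10000, mut_pos_A = c(10500, 12000),
                     mut_pos_S = 8000, window = c(1, 50000))
  expect_equal(got$xas3, 500)
  expect_equal(got$xas5, 2000)
  expect_false(got$cens5 || got$cens3)
  cens <- extract_xas(10000, window = c(1, 50000))
  expect_true(cens$cens5 && cens$cens3)
  expect_equal(cens$xas5, 9999)
  expect_equal(cens$xas3, 40000)
})

test_that("without recombination the msh is bounded by x_AS and usually equals it", {
  sim <- simulate_sample("constant", n = 30, L_bp = 3e5, mu = 2e-8, rho = 0,
                         seed = 23, N0 = 1e5)
  tr <- sim$truth[sim$truth$k == 1L & is.finite(sim$truth$xas5), ]
  expect_gt(nrow(tr), 30)
  obs <- msh_table(sim$hm, singletons_only = TRUE)
  j <- dplyr::inner_join(obs, tr, by = c("pos", "row"))
  # a mutation on the focal branch differentiates the focal chromosome from
  # every other sample, so no tract can pass it (strict bound)
  a5 <- !j$censa5; a3 <- !j$censa3
  expect_true(all(j$msh5_bp[a5] <= j$xa5[a5]))
  expect_true(all(j$msh3_bp[a3] <= j$xa3[a3]))
  # a mutation on the sister branch stops comparisons with the sisters but
  # not with more distant relatives, so x_AS bounds the msh only with high
  # probability, and most tracts are terminated exactly at x_AS
  ok5 <- !j$cens5; ok3 <- !j$cens3
  within <- c(j$msh5_bp[ok5] <= j$xas5[ok5], j$msh3_bp[ok3] <= j$xas3[ok3])
  expect_gt(mean(within), 0.8)
  eq <- c(j$msh5_bp[ok5] == j$xas5[ok5], j$msh3_bp[ok3] == j$xas3[ok3])
  expect_gt(mean(eq), 0.7)
})

test_that("the two-sister race probability matches its closed form", {
  expect_equal(prob_msh_not_xas(100, 0), 1 / 3)
  expect_equal(prob_msh_not_xas(100, 50), 1 / 10)
  expect_equal(prob_msh_not_xas(100, 100), 0)
  expect_lt(prob_msh_not_xas(100, 99.9), 1e-5)
  expect_error(prob_msh_not_xas(100, 120), "phi")
  mc <- simulate_msh_xas_race(1000, 250, reps = 2e4, seed = 7)
  expect_lt(abs(mc$p_hat - prob_msh_not_xas(1000, 250)), 3 * mc$se)
})
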