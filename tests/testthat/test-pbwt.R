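test_that("prefix/divergence arrays match a hand-run of the update recurrence", {
  # single sequence: trivial permutation, divergence = empty-match sentinel
  one <- build_pbwt(matrix(c(0L, 1L, 0L), 1, 3))
  expect_equal(one$a, matrix(1L, 1, 4))
  expect_equal(one$d, matrix(1:4, 1, 4))
  # 3 x 2 fixture worked through the recurrence by hand
  X <- matrix(c(0L, 0L, 1L,
                0L, 1L, 0L), nrow = 3)
  pb <- build_pbwt(X)
  expect_equal(pb$a, matrix(c(1L, 2L, 3L,
                              1L, 2L, 3L,
                              1L, 3L, 2L), 3, 3))
  expect_equal(pb$d, matrix(c(1L, 1L, 1L,
                              2L, 1L, 2L,
                              3L, 2L, 3L), 3, 3))
})

test_that("consecutive chromosomes in a-order share the suffix their divergence claims", {
  for (seed in c(4, 5, 6)) {
    hm <- random_hm(12, 30, seed)
    pb <- build_pbwt(hm)
    for (t in c(5, 15, 31)) {
      a <- pb$a[, t]; d <- pb$d[, t]
      for (i in 2:12) {
        lo <- d[i]
        if (lo < t) {
          expect_identical(hm$alleles[a[i - 1], lo:(t - 1)],
                           hm$alleles[a[i], lo:(t - 1)])
        }
        if (lo > 1) {
          expect_false(isTRUE(hm$alleles[a[i - 1], lo - 1] ==
                                hm$alleles[a[i], lo - 1]))
        }
      }
    }
  }
})

test_that("singleton msh finds tracts and boundary truncation on small fixtures", {
  pos <- c(10, 20, 30, 40, 50)
  # rows 1-2 identical except the focal singleton; rows 3-4 differ at the ends
  X <- rbind(c(0, 1, 1, 1, 0),
             c(0, 1, 0, 1, 0),
             c(1, 1, 0, 1, 1),
             c(1, 0, 0, 1, 1))
  hm <- haplotype_matrix(X, pos)
  obs <- msh_singleton(hm, 3)
  expect_true(obs$eoc5 && obs$eoc3)        # best match (row 2) is identical
  expect_equal(obs$partner5, 2L)
  expect_equal(obs$msh5_bp, 30 - 10)       # to the assayed-region bound
  expect_equal(obs$msh3_bp, 50 - 30)

  # same fixture but every other row now differs at 50: 3' tract ends there
  X2 <- X; X2[2, 5] <- 1
  hm2 <- haplotype_matrix(X2, pos)
  obs2 <- msh_singleton(hm2, 3)
  expect_true(obs2$eoc5)
  expect_false(obs2$eoc3)
  expect_equal(obs2$msh3_bp, 20)
  expect_equal(obs2$ter3_pos, 50)

  # two rows differing only at the singleton: both directions truncated
  hm3 <- haplotype_matrix(rbind(c(1, 1, 0), c(1, 0, 0)), c(5, 15, 25))
  obs3 <- msh_singleton(hm3, 2)
  expect_true(obs3$eoc5 && obs3$eoc3)
  expect_error(msh_singleton(hm3, 1), "not a singleton")
})

test_that("multi-copy msh maximizes per direction over non-carriers only", {
  pos <- c(100, 200, 300, 400, 500)
  # doubleton at site 3 (rows 1, 2); fixture symmetric for the two carriers
  X <- rbind(c(0, 0, 1, 0, 0),
             c(0, 0, 1, 0, 0),
             c(0, 0, 0, 0, 0),
             c(1, 0, 0, 0, 1))
  hm <- haplotype_matrix(X, pos)
  obs <- msh_table(hm, sites = 3)
  expect_equal(nrow(obs), 2L)
  expect_equal(obs$msh5_bp[1], obs$msh5_bp[2])
  expect_equal(obs$msh3_bp[1], obs$msh3_bp[2])
  expect_equal(obs$partner5, c(3L, 3L))  # carriers never matched to each other

  # best 5' partner and best 3' partner are different non-carriers
  Y <- rbind(c(0, 0, 1, 1, 0),   # carrier
             c(1, 0, 1, 0, 1),   # carrier
             c(0, 0, 0, 1, 1),   # matches row 1 on the 5' side
             c(1, 0, 0, 1, 0))   # matches row 1 on the 3' side
  hmY <- haplotype_matrix(Y, pos)
  oY <- msh_multicopy(hmY, 3)
  expect_equal(oY$partner5[1], 3L)
  expect_equal(oY$partner3[1], 4L)
  expect_error(msh_multicopy(haplotype_matrix(rbind(c(1), c(1)), 10), 1),
               "non-carrier")
})

test_that("PBWT msh equals the brute-force oracle on random panels", {
  set.seed(42)
  checked <- 0L
  for (rep in 1:60) {
    hm <- random_hm(sample(2:30, 1), sample(2:60, 1), seed = 1000 + rep)
    tb <- msh_table(hm)
    if (!nrow(tb)) next
    take <- seq_len(min(nrow(tb), 40))
    for (i in take) {
      expect_true(oracle_matches(hm, tb[i, ]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 500L)
})

test_that("adding a chromosome never shortens an existing row's msh", {
  set.seed(7)
  for (rep in 1:20) {
    hm <- random_hm(sample(3:15, 1), sample(5:40, 1), seed = 2000 + rep)
    s <- which(variant_sites(hm)$k == 1L)
    if (!length(s)) next
    s <- s[1]
    before <- msh_singleton(hm, s)
    extra <- rbind(hm$alleles, rbinom(ncol(hm$alleles), 1, 0.5))
    extra[nrow(extra), s] <- 0L
    hm2 <- haplotype_matrix(extra, hm$positions)
    after <- msh_singleton(hm2, s)
    expect_gte(after$msh5_bp, before$msh5_bp)
    expect_gte(after$msh3_bp, before$msh3_bp)
  }
})

test_that("the focal column itself never terminates a tract", {
  # non-carrier differs ONLY at the focal column: it is a perfect match
  X <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 1))
  hm <- haplotype_matrix(X, c(10, 20, 30))
  obs <- msh_singleton(hm, 2)
  expect_true(obs$eoc5 && obs$eoc3)
  expect_equal(obs$partner5, 2L)
  # immediately adjacent mismatch: zero-margin tract is permitted
  X2 <- rbind(c(1, 1, 0), c(0, 0, 0))
  hm2 <- haplotype_matrix(X2, c(10, 20, 30))
  o2 <- msh_singleton(hm2, 2)
  expect_equal(o2$msh5_bp, 10)
  expect_equal(o2$ter5_pos, 10)
})

test_that("msh_at measures tracts for arbitrary rows and positions", {
  X <- rbind(c(0, 1, 0, 1),
             c(0, 1, 0, 0),
             c(1, 0, 1, 0))
  hm <- haplotype_matrix(X, c(100, 200, 300, 400))
  # row 1 at an off-site position 250: matches row 2 over sites 1-3
  o <- msh_at(hm, rows = 1L, positions = 250)
  expect_true(o$eoc5)
  expect_equal(o$msh3_bp, 150)   # first 3' mismatch vs row 2 at 400
  expect_equal(o$partner3, 2L)
})
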