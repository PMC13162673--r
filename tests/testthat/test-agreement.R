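test_that("mean/sd summary matches a two-pass computation", {
  expect_equal(summarize_mean_sd(c(2, 2, 2)), c(mean = 2, sd = 0))
  expect_equal(summarize_mean_sd(c(1, 3)), c(mean = 2, sd = sqrt(2)))
  set.seed(41)
  v <- rpois(20, 30)
  two_pass <- c(mean = sum(v) / 20,
                sd = sqrt(sum((v - sum(v) / 20)^2) / 19))
  expect_equal(summarize_mean_sd(v), two_pass, tolerance = 1e-12)
  expect_error(summarize_mean_sd(5), "at least 2")
})

test_that("sign-flip permutation test: exhaustive cases and conventions", {
  tab <- paired_abundance(c("a", "b"), c(3, 5), c(3, 5))
  expect_equal(permutation_test_l1(tab)$p, 1)

  # d = (+1, -1): all four flips give |T*| in {0, 0, 2, 2} >= 0
  r <- permutation_test_l1(paired_abundance(c("a", "b"), c(2, 1), c(1, 2)))
  expect_equal(r$p, 1)
  expect_equal(r$method, "exact")

  # d = (+5, +4, +3): two of eight sign patterns reach |T*| >= 12
  r <- permutation_test_l1(paired_abundance(c("a", "b", "c"),
                                            c(10, 9, 8), c(5, 5, 5)))
  expect_equal(r$p, 2 / 8)

  # exhaustive mode agrees with the explicit sign-pattern oracle
  set.seed(42)
  for (rep in 1:5) {
    h <- rpois(6, 20); m <- rpois(6, 20)
    got <- permutation_test_l1(h, m)$p
    expect_equal(got, oracle_signflip_p(h - m), tolerance = 1e-12)
  }

  # sampled mode uses the add-one convention
  set.seed(43)
  h <- rpois(20, 50); m <- rpois(20, 50)
  r <- permutation_test_l1(h, m, n_perm = 99, seed = 7)
  expect_equal(r$method, "sampled")
  expect_true(r$p >= 1 / 100 && r$p <= 1)

  # the within-pair-swap L1 statistic is degenerate and refused
  expect_error(permutation_test_l1(h, m, statistic = "per_category_l1"),
               "degenerate")
})

test_that("signed-rank test agrees with exhaustive enumeration, n <= 8", {
  # single pair: extreme W still gives two-sided p = 1
  expect_equal(wilcoxon_signed_rank(c(5), c(4))$p, 1)
  # symmetric +/-c differences sit at the null center
  r <- wilcoxon_signed_rank(c(3, 1, 3, 1), c(1, 3, 1, 3))
  expect_equal(r$p, 1)
  expect_error(wilcoxon_signed_rank(c(2, 2), c(2, 2)), "undefined")

  set.seed(44)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    h <- rpois(n, 15)
    m <- rpois(n, 15)
    if (all(h == m)) h[1] <- h[1] + 1L
    got <- wilcoxon_signed_rank(h, m)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_signrank_p(h - m), tolerance = 1e-12)
  }
})

test_that("zero differences are dropped before ranking", {
  r <- wilcoxon_signed_rank(c(4, 4, 9, 2), c(4, 4, 5, 1))
  expect_equal(r$n_used, 2L)
})

test_that("rank-sum test: closed cases and enumeration oracle, n,m <= 6", {
  x <- c(1, 2, 3)
  r <- mann_whitney_u(x, x)
  expect_equal(r$U, 9 / 2) # identical multisets: U = nm/2
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)

  set.seed(45)
  for (rep in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- rpois(n, 10); y <- rpois(m, 10)
    got <- mann_whitney_u(x, y)
    want <- oracle_ranksum(x, y)
    expect_equal(got$U, want$U, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("pearson_r: exact cases and affine invariance", {
  h <- c(1, 2, 3)
  expect_equal(pearson_r(h, h), 1)
  expect_equal(pearson_r(h, -h + 10), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)),
               cor(c(1, 2, 3), c(1, 2, 4)))
  set.seed(46)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(pearson_r(x, y), pearson_r(3 * x + 2, y), tolerance = 1e-9)
  expect_equal(pearson_r(x, y), pearson_r(x, 0.5 * y - 7), tolerance = 1e-9)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Bland-Altman in log2 space: identity, ratio, exclusions", {
  tab <- paired_abundance(letters[1:3], c(2, 4, 8), c(2, 4, 8))
  ba <- bland_altman_log2(tab)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$lower, ba$upper), c(0, 0))

  tab2 <- paired_abundance(letters[1:3], c(2, 4, 8), c(1, 2, 4))
  ba2 <- bland_altman_log2(tab2)
  expect_equal(ba2$bias, 1)
  expect_equal(c(ba2$lower, ba2$upper), c(1, 1))

  tab3 <- paired_abundance(letters[1:4], c(2, 4, 8, 5), c(1, 2, 0, 4))
  ba3 <- bland_altman_log2(tab3)
  expect_equal(ba3$excluded, "c")
  expect_equal(nrow(ba3$points), 3L)
  # limits symmetric about the bias
  expect_equal(ba3$upper - ba3$bias, ba3$bias - ba3$lower, tolerance = 1e-12)
})

test_that("Bland-Altman bias is scale-equivariant in the machine counts", {
  set.seed(47)
  h <- rpois(8, 40) + 1
  m <- rpois(8, 40) + 1
  b1 <- bland_altman_log2(paired_abundance(letters[1:8], h, m))$bias
  b2 <- bland_altman_log2(paired_abundance(letters[1:8], h, 2 * m))$bias
  expect_equal(b2 - b1, -1, tolerance = 1e-9)
})

test_that("category breakdown fractions always sum to one", {
  tab <- paired_abundance(letters[1:3], c(10, 10, 10), c(10, 5, 15))
  expect_equal(unname(category_breakdown(tab)), c(1, 1, 1) / 3)
  expect_equal(unname(category_breakdown(tab, tol = 10)), c(1, 0, 0))
  ident <- paired_abundance(letters[1:4], 1:4, 1:4)
  expect_equal(unname(category_breakdown(ident)), c(1, 0, 0))
  set.seed(48)
  for (rep in 1:5) {
    t2 <- paired_abundance(letters[1:6], rpois(6, 20), rpois(6, 20))
    expect_equal(sum(category_breakdown(t2, tol = runif(1, 0, 5))), 1,
                 tolerance = 1e-9)
  }
})

test_that("areal conversion implements the net-mouth geometry", {
  # pi * 0.1875^2 ~ 0.110447 m^2, so ~110.45 counted organisms over the
  # full sample is one thousand specimens per m^2
  expect_equal(counts_to_areal(110.447, 1, 0.375), 1, tolerance = 1e-3)
  expect_equal(counts_to_areal(50, 0.5), 2 * counts_to_areal(50, 1),
               tolerance = 1e-12)
  expect_equal(counts_to_areal(0), 0)
  expect_error(counts_to_areal(-1), "negative")
  expect_error(counts_to_areal(10, 0), "counted_fraction")
})

test_that("the full agreement report assembles every component", {
  scen <- default_count_scenario()
  tab <- generate_paired_counts(scen$truth, scen$bias, seed = 9)
  rep <- agreement_report(tab, n_perm = 499, seed = 2)
  expect_s3_class(rep, "agreement_report")
  expect_true(rep$perm_p > 0 && rep$perm_p <= 1)
  expect_true(rep$pearson_r >= -1 && rep$pearson_r <= 1)
  expect_equal(sum(rep$breakdown), 1, tolerance = 1e-9)
  expect_output(print(rep), "Pearson")
})
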