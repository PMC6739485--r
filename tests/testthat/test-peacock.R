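test_that("degenerate samples give the boundary statistic values", {
  s <- cbind(c(0, 1, 2), c(0, 1, 0))
  expect_equal(peacock_statistic(s, s), 0)
  expect_equal(peacock_statistic(cbind(0, 0), cbind(10, 10)), 1)
  expect_equal(brute_force_statistic(cbind(0, 0), cbind(0, 0)), 0)
  expect_equal(brute_force_statistic(cbind(0, 0), cbind(3, 1)), 1)
  expect_error(peacock_statistic(matrix(0, 0, 2), s),
               class = "spclone_empty_error")
})

test_that("the lattice statistic equals the brute-force oracle exactly", {
  s1 <- cbind(c(0, 1, 2), c(0, 1, 0))
  s2 <- cbind(c(0, 2, 1), c(1, 2, 0))
  expect_equal(peacock_statistic(s1, s2), brute_force_statistic(s1, s2),
               tolerance = 1e-12)
  withr::with_seed(101, {
    for (i in 1:100) {
      n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
      if (i %% 2 == 0) {  # tied integer data
        a <- cbind(sample(0:3, n1, TRUE), sample(0:3, n1, TRUE))
        b <- cbind(sample(0:3, n2, TRUE), sample(0:3, n2, TRUE))
      } else {            # continuous data
        a <- cbind(rnorm(n1), rnorm(n1))
        b <- cbind(rnorm(n2), rnorm(n2))
      }
      expect_equal(peacock_statistic(a, b), brute_force_statistic(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("the statistic is symmetric and monotone-transform invariant", {
  withr::with_seed(102, {
    for (i in 1:20) {
      a <- cbind(rnorm(15), rnorm(15))
      b <- cbind(rnorm(12, 0.5), rnorm(12))
      expect_identical(peacock_statistic(a, b), peacock_statistic(b, a))
      tr <- function(s) cbind(exp(s[, 1]), s[, 2]^3)
      expect_equal(peacock_statistic(tr(a), tr(b)), peacock_statistic(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("the permutation p-value respects its attainable range", {
  s <- cbind(rep(0:2, 10), rep(0:1, 15))
  pt <- peacock_test(s, s, n_perm = 99, seed = 1)
  expect_equal(pt$p.value, 1)    # D = 0 is never exceeded strictly
  far <- peacock_test(matrix(0, 20, 2), matrix(10, 20, 2),
                      n_perm = 199, seed = 1)
  expect_gte(far$p.value, 1 / 200)
  expect_lte(far$p.value, 0.01)
  expect_error(peacock_test(s, s, n_perm = 50),
               class = "spclone_config_error")
  # determinism under a fixed seed
  a <- cbind(rpois(40, 2), rpois(40, 2))
  b <- cbind(rpois(40, 3), rpois(40, 2))
  expect_identical(peacock_test(a, b, n_perm = 199, seed = 9),
                   peacock_test(a, b, n_perm = 199, seed = 9))
})

test_that("null permutation p-values are approximately uniform at working scale", {
  # at the cohort sizes the test is used for (~1000 clones per condition)
  # the tie-induced discreteness of D is negligible and p is uniform;
  # smaller samples are conservative, never anti-conservative
  withr::with_seed(103, {
    pvals <- vapply(1:500, function(i) {
      a <- cbind(rpois(1000, 2), rpois(1000, 1.5))
      b <- cbind(rpois(1000, 2), rpois(1000, 1.5))
      peacock_test(a, b, n_perm = 199)$p.value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  # validity at small n: rejection rate never exceeds the nominal level
  withr::with_seed(106, {
    small <- vapply(1:400, function(i) {
      a <- cbind(rnorm(30), rnorm(30))
      b <- cbind(rnorm(30), rnorm(30))
      peacock_test(a, b, n_perm = 99)$p.value
    }, numeric(1))
  })
  expect_lte(mean(small <= 0.05), 0.065)
})

test_that("the test detects a one-standard-deviation shift at n = 200", {
  withr::with_seed(104, {
    hits <- vapply(1:500, function(i) {
      a <- cbind(rpois(200, 4), rpois(200, 4))
      b <- cbind(rpois(200, 6), rpois(200, 4))  # x shifted by ~1 SD
      peacock_test(a, b, n_perm = 99)$p.value <= 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.9)
})

test_that("the asymptotic approximation is labelled and ordered sensibly", {
  withr::with_seed(105, {
    a <- cbind(rnorm(100), rnorm(100))
    b <- cbind(rnorm(100, 1.5), rnorm(100))
    same <- peacock_test(a, a, method = "asymptotic")
    diff <- peacock_test(a, b, method = "asymptotic")
    expect_equal(same$method, "asymptotic")
    expect_gt(same$p.value, 0.5)
    expect_lt(diff$p.value, 0.01)
  })
  t1 <- tidy(peacock_test(a <- cbind(1:5, 1:5), a, n_perm = 99, seed = 2))
  expect_named(t1, c("statistic", "p.value", "method", "n_perm"))
})
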