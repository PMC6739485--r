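test_that("clone-size histograms are normalised relative frequencies", {
  tbl <- clone_tbl(c(1, 1, 0, 2), c(0, 0, 1, 1))
  h <- clone_size_histogram(tbl)
  expect_equal(h$f["1", "0"], 0.5)
  expect_equal(h$f["0", "1"], 0.25)
  expect_equal(h$f["2", "1"], 0.25)
  expect_equal(sum(h$f), 1, tolerance = 1e-9)
  expect_equal(h$n_clones, 4L)
  expect_error(clone_size_histogram(tbl[0, ]), class = "spclone_empty_error")
})

test_that("overflow policy clips to the edge or drops large clones", {
  tbl <- clone_tbl(c(5, 1), c(0, 0))
  clip <- clone_size_histogram(tbl, m_cap = 2, n_cap = 2)
  expect_equal(clip$f["2", "0"], 0.5)   # (5,0) clipped to (2,0)
  expect_equal(sum(clip$f), 1)
  drop <- clone_size_histogram(tbl, m_cap = 2, n_cap = 2, overflow = "drop")
  expect_equal(drop$f["1", "0"], 1)
  expect_equal(drop$n_clones, 1L)
  # floating clones excluded on request
  nf <- clone_size_histogram(clone_tbl(c(0, 1), c(2, 1)),
                             include_floating = FALSE)
  expect_equal(nf$n_clones, 1L)
  expect_equal(sum(nf$f[1, ]), 0)
})

test_that("residual maps are zero-sum, antisymmetric differences", {
  h1 <- clone_size_histogram(clone_tbl(c(1, 1), c(0, 1)), m_cap = 3, n_cap = 3)
  h2 <- clone_size_histogram(clone_tbl(c(1, 2), c(0, 2)), m_cap = 3, n_cap = 3)
  expect_equal(residual_map(h1, h1)$f, h1$f * 0)
  r12 <- residual_map(h1, h2)
  expect_equal(sum(r12$f), 0, tolerance = 1e-9)
  expect_equal(r12$f, -residual_map(h2, h1)$f)
  h3 <- clone_size_histogram(clone_tbl(1, 1), m_cap = 5, n_cap = 5)
  expect_error(residual_map(h1, h3), class = "spclone_dimension_error")
  # worked example: f(1,0) 0.5 vs 0.3 gives residual -0.2
  a <- clone_size_histogram(clone_tbl(c(1, 1, 2, 3), c(0, 0, 1, 1)))
  b <- clone_size_histogram(clone_tbl(c(1, 2, 3, 2, 3, 2, 4, 1, 5, 6),
                                      c(0, 1, 1, 0, 0, 2, 1, 1, 0, 0)))
  expect_equal(residual_map(a, b)$f["1", "0"], 0.1 - 0.5)
})

test_that("geometric median matches symmetry and the exhaustive grid oracle", {
  expect_equal(geometric_median(clone_tbl(3, 2))[, c("m", "n")],
               tibble::tibble(m = 3, n = 2))
  sq <- geometric_median(clone_tbl(c(0, 0, 4, 4), c(0, 4, 0, 4)))
  expect_equal(c(sq$m, sq$n), c(2, 2), tolerance = 1e-6)
  # collinear even-count set: every point of the segment [1, 2] x {0}
  # minimises the distance sum, so compare objective values
  pts <- cbind(c(0, 1, 2, 10), c(0, 0, 0, 0))
  gm <- geometric_median(pts)
  expect_equal(gm$n, 0, tolerance = 1e-6)
  expect_true(gm$m >= 1 - 5e-3 && gm$m <= 2 + 5e-3)
  expect_true(median_matches_oracle(pts))
  # duplicated points collapse to that point
  dup <- geometric_median(cbind(c(2, 2, 2), c(1, 1, 1)))
  expect_equal(c(dup$m, dup$n), c(2, 1))
  withr::with_seed(8, {
    for (i in 1:10) {
      pts <- random_integer_points(sample(3:30, 1), 3, 2)
      expect_true(median_matches_oracle(pts))
    }
  })
})

test_that("floating fraction counts clones with no basal cells", {
  expect_equal(floating_fraction(clone_tbl(c(0, 1, 3, 0),
                                           c(2, 1, 0, 1)))$floating_pct, 50)
  expect_equal(floating_fraction(clone_tbl(c(1, 2), c(0, 0)))$floating_pct, 0)
  expect_error(floating_fraction(clone_tbl(integer(0), integer(0))),
               class = "spclone_empty_error")
})

test_that("summary statistics average clone composition correctly", {
  s <- summary_stats(clone_tbl(c(1, 1), c(0, 2)))
  expect_equal(s$mean_total_size, 2)
  expect_equal(s$mean_basal_fraction, (1 + 1 / 3) / 2)
  wt <- summary_stats(clone_tbl(c(2, 1), c(0, 0), genotype = c("WT", "WT")))
  expect_equal(wt$mutant_basal_pct, 0)
  mix <- summary_stats(clone_tbl(c(2, 2), c(0, 0),
                                 genotype = c("WT", "p53mut")))
  expect_equal(mix$mutant_basal_pct, 50)
})

test_that("EdU readouts pool labels and flag undefined ratios", {
  tbl <- clone_tbl(c(3, 1), c(2, 2), edu_basal = c(2L, 0L),
                   edu_suprabasal = c(1L, 1L))
  e <- edu_readouts(tbl)
  expect_equal(e$edu_suprabasal_pct, 50)
  expect_equal(e$edu_total, 4L)
  none <- clone_tbl(c(1, 1), c(0, 0), edu_basal = c(0L, 0L),
                    edu_suprabasal = c(0L, 0L))
  expect_warning(res <- edu_readouts(none), "undefined")
  expect_true(is.na(res$edu_suprabasal_pct))
  expect_error(edu_readouts(clone_tbl(1, 1)), class = "spclone_schema_error")
})

test_that("density ratios scale with counts and propagate field variance", {
  flds <- c(100L, 110L, 90L)
  expect_equal(density_estimate(flds, flds)$ratio, 1)
  expect_equal(density_estimate(2L * flds, flds)$ratio, 2)
  expect_error(density_estimate(flds, c(0L, 0L)),
               class = "spclone_domain_error")
  expect_error(density_estimate(integer(0), flds),
               class = "spclone_empty_error")
})

test_that("statistics are invariant to clone order and relabelling", {
  withr::with_seed(12, {
    tbl <- full_clone_tbl(40)
    perm <- tbl[sample(nrow(tbl)), ]
    perm$clone_id <- paste0("relabel", seq_len(nrow(perm)))
    expect_equal(clone_size_histogram(tbl)$f, clone_size_histogram(perm)$f)
    expect_equal(floating_fraction(tbl), floating_fraction(perm))
    expect_equal(summary_stats(tbl), summary_stats(perm))
    gm1 <- geometric_median(tbl); gm2 <- geometric_median(perm)
    expect_equal(c(gm1$m, gm1$n), c(gm2$m, gm2$n), tolerance = 1e-6)
  })
})
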