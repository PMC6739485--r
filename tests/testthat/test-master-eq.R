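test_that("the generator has zero row sums and the expected transitions", {
  tr <- truncation(3, 3, 3)
  zero <- build_generator(fate_params(0, 1/3, 1/3, 1/3, 0, 0), tr)
  expect_equal(Matrix::norm(zero$Q, "F"), 0)

  rho_only <- build_generator(fate_params(0, 1/3, 1/3, 1/3, 0, 0, rho = 2.4),
                              tr)
  i <- spclone:::state_index(1L, 0L, 0L, tr)
  j <- spclone:::state_index(0L, 1L, 0L, tr)
  expect_equal(rho_only$Q[i, j], 2.4 / 24)  # per-hour rate
  expect_equal(sum(rho_only$Q[i, ] != 0), 2)  # one transition + diagonal

  full <- build_generator(fate_params(0.5, 0.2, 0.5, 0.3, 0.7, 0.4,
                                      rho = 0.1), tr)
  expect_lt(max(abs(Matrix::rowSums(full$Q))), 1e-12)
})

test_that("evolution preserves mass and matches the exponential closed form", {
  p <- base_params()
  d0 <- initial_distribution()
  expect_equal(master_evolve(p, t_h = 0)$p, d0$p)

  # single progenitor with only rho active: P(converted) = 1 - exp(-rho t)
  rho_only <- fate_params(0, 1/3, 1/3, 1/3, 0, 0, rho = 1)
  d <- master_evolve(rho_only, t_h = 36)
  tr <- d$trunc
  p_conv <- d$p[spclone:::state_index(0L, 1L, 0L, tr)]
  expect_equal(p_conv, 1 - exp(-1.5), tolerance = 1e-8)
  expect_equal(sum(d$p), 1, tolerance = 1e-9)

  d2 <- master_evolve(p, t_h = 240)
  expect_equal(sum(d2$p), 1, tolerance = 1e-9)
  expect_lt(leak_mass(d2), 1e-6)
})

test_that("balanced dynamics keep the mean progenitor count at one, exactly", {
  p <- base_params()
  for (t in c(24, 120, 240)) {
    expect_equal(mean_progenitors(master_evolve(p, t_h = t)), 1,
                 tolerance = 1e-6)
  }
})

test_that("truncation leak is monotone in time and triggers enlargement", {
  p <- apply_tilt(balanced_fate_params(r = 0.1, lambda = 1), 0.8)
  tr <- truncation(6, 6, 8)
  leaks <- vapply(c(120, 360, 720), function(t) {
    leak_mass(spclone:::evolve_schedule(p, t, initial_distribution(tr), tr))
  }, numeric(1))
  expect_true(all(diff(leaks) > 0))
  w <- capture_warnings(master_evolve(p, t_h = 360, trunc = tr,
                                      max_enlarge = 1))
  expect_true(any(grepl("leak", w)))
})

test_that("the clone-size marginal maps states to (m, n) and normalises", {
  d0 <- initial_distribution()
  h <- clone_size_marginal(d0)
  expect_equal(h$f["1", "0"], 1)
  expect_equal(sum(h$f), 1)
  d <- master_evolve(base_params(), t_h = 240)
  expect_equal(sum(clone_size_marginal(d)$f), 1, tolerance = 1e-6)
  obs <- clone_size_marginal(d, observed_only = TRUE)
  expect_equal(sum(obs$f), 1, tolerance = 1e-9)
  expect_equal(obs$f["0", "0"], 0)
})

test_that("the simulator and the master equation agree on clone sizes", {
  p <- base_params()
  co <- simulate_cohort(10000, p, sample_times_h = 240, seed = 301)
  h_emp <- clone_size_histogram(co, m_cap = 40, n_cap = 30)
  h_or <- clone_size_marginal(master_evolve(p, t_h = 240))
  expect_lt(tv_distance(h_emp, h_or), 0.05)
})

test_that("log-likelihood is exact at t = 0 and invariant to clone order", {
  tbl <- clone_tbl(1, 0, time_h = 0)
  expect_equal(log_likelihood(tbl, base_params()), 0)
  withr::with_seed(302, {
    co <- simulate_cohort(300, base_params(), sample_times_h = c(48, 240),
                          seed = 303)
    co <- co[co$observable, ]
    ll1 <- log_likelihood(co, base_params())
    ll2 <- log_likelihood(co[sample(nrow(co)), ], base_params())
    expect_equal(ll1, ll2)
  })
  expect_warning(
    ll0 <- log_likelihood(clone_tbl(2, 0, time_h = 0), base_params(),
                          conditioning = "none"),
    "zero-probability")
  expect_identical(ll0, -Inf)
})

test_that("tilt recovery finds the generating fate bias", {
  base <- base_params()
  co <- simulate_cohort(1000, apply_tilt(base, -0.2), sample_times_h = 720,
                        seed = 304)
  fit <- fit_tilt(co[co$observable, ], base)
  expect_lt(abs(fit$estimate - (-0.2)), 0.1)
  expect_true(fit$conf.low < fit$estimate & fit$estimate < fit$conf.high)
  expect_true(fit$identifiable)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_equal(gl$n_clones, sum(co$observable))
  # determinism: same table, same fit
  expect_identical(fit$estimate,
                   fit_tilt(co[co$observable, ], base)$estimate)
})

test_that("a design with no post-induction information is flagged", {
  tbl <- clone_tbl(rep(1L, 20), rep(0L, 20), time_h = 0)
  expect_warning(fit <- fit_tilt(tbl, base_params(),
                                 delta_grid = seq(-0.3, 0.3, 0.1)),
                 "identifiable")
  expect_false(fit$identifiable)
})
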