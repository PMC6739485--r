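test_that("a clone with all rates zero stays a single progenitor", {
  p <- fate_params(0, 1/3, 1/3, 1/3, 0, 0, 0)
  tr <- simulate_clone(p, t_end_h = 240, seed = 1)
  expect_true(all(tr$n_p == 1 & tr$n_d == 0 & tr$n_s == 0 & tr$n_shed == 0))
})

test_that("induced differentiation alone follows the exponential waiting time", {
  # single progenitor, only rho active: P(converted by t) = 1 - exp(-rho t)
  rho_day <- 1
  p <- fate_params(0, 1/3, 1/3, 1/3, 0, 0, rho = rho_day)
  co <- simulate_cohort(20000, p, sample_times_h = 24, seed = 7)
  frac <- mean(co$n_d == 1)
  expected <- 1 - exp(-rho_day)
  se <- sqrt(expected * (1 - expected) / nrow(co))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("identical seeds reproduce identical cohorts", {
  p <- base_params()
  a <- simulate_cohort(500, p, sample_times_h = c(24, 48), seed = 99,
                       edu_pulse_h = 10)
  b <- simulate_cohort(500, p, sample_times_h = c(24, 48), seed = 99,
                       edu_pulse_h = 10)
  expect_identical(a, b)
  c2 <- simulate_cohort(500, p, sample_times_h = c(24, 48), seed = 100)
  expect_false(identical(a$m_basal, c2$m_basal))
})

test_that("cell flux is conserved: founders + divisions = live + shed", {
  withr::with_seed(5, {
    for (i in 1:5) {
      pr <- c(runif(1, 0, 0.3), 0, 0)
      pr[2] <- runif(1, 0, 1 - pr[1]); pr[3] <- 1 - pr[1] - pr[2]
      p <- fate_params(runif(1, 0.1, 1), pr[1], pr[2], pr[3],
                       runif(1, 0.2, 1), runif(1, 0.2, 1),
                       rho = runif(1, 0, 0.3))
      co <- simulate_cohort(200, p, sample_times_h = c(48, 240),
                            seed = 1000 + i)
      expect_true(all(1 + co$n_div == co$n_p + co$n_d + co$n_s + co$n_shed))
      expect_true(all(co$edu_basal <= co$m_basal))
      expect_true(all(co$edu_suprabasal <= co$n_suprabasal))
    }
  })
})

test_that("balanced clones keep a unit mean progenitor number", {
  co <- simulate_cohort(20000, base_params(), sample_times_h = c(24, 240),
                        seed = 11)
  for (t in c(24, 240)) {
    np <- co$n_p[co$time_h == t]
    expect_lt(abs(mean(np) - 1), 3 * sd(np) / sqrt(length(np)))
  }
})

test_that("floating fraction rises with induced differentiation and falls with tilt", {
  float_at <- function(p, t, seed) {
    co <- simulate_cohort(10000, p, sample_times_h = t, seed = seed)
    floating_fraction(co[co$observable, ])$floating_pct
  }
  base <- base_params()
  f_rho <- vapply(c(0, 0.5, 1.5), function(r) {
    float_at(fate_params(base$lambda, 0.1, 0.8, 0.1, base$gamma, base$mu, r),
             48, 21)
  }, numeric(1))
  expect_true(all(diff(f_rho) > 0))
  f_delta <- vapply(c(-0.4, 0, 0.4), function(d) {
    float_at(apply_tilt(base, d), 240, 22)
  }, numeric(1))
  expect_true(all(diff(f_delta) < 0))
})

test_that("EdU labels are inherited, never created from unlabelled cells", {
  # lambda = 0: nothing cycles, so the pulse labels nothing
  p0 <- fate_params(0, 1/3, 1/3, 1/3, 0.5, 0.5, rho = 1)
  co0 <- simulate_cohort(500, p0, sample_times_h = 48, seed = 3,
                         edu_pulse_h = 0)
  expect_equal(sum(co0$edu_basal) + sum(co0$edu_suprabasal), 0)

  # forced labelling (lambda tau_S / 24 >= 1) with no divisions afterwards:
  # every cell descends from a labelled founder, so labels track the cells
  sch <- dplyr::bind_rows(
    constant_schedule(fate_params(3, 0.1, 0.8, 0.1, 0, 0), t_end_h = 1e-6),
    schedule_modify(
      constant_schedule(fate_params(0, 0.1, 0.8, 0.1, 0.5, 0.3, rho = 2),
                        t_end_h = 200, t_start_h = 1e-6),
      1e-6, 200, identity)
  )
  co <- simulate_cohort(400, sch, sample_times_h = 100, seed = 4,
                        edu_pulse_h = 0)
  expect_true(all(co$edu_basal == co$m_basal))
  expect_true(all(co$edu_suprabasal == co$n_suprabasal))
})

test_that("a differentiation wave does not change the total EdU+ cell count", {
  # conversion P -> D relocates labelled cells without creating or
  # destroying them, so total EdU+ cells match the unperturbed cohort
  base <- base_params()
  wave <- fate_params(base$lambda, 0.1, 0.8, 0.1, base$gamma, base$mu,
                      rho = 0.5)
  co_ctrl <- simulate_cohort(50000, base, sample_times_h = 24, seed = 31,
                             edu_pulse_h = 0)
  co_wave <- simulate_cohort(50000, wave, sample_times_h = 24, seed = 32,
                             edu_pulse_h = 0)
  tot <- function(co) mean(co$edu_basal + co$edu_suprabasal + co$edu_shed)
  expect_lt(abs(tot(co_wave) / tot(co_ctrl) - 1), 0.1)
  # but the wave shifts labelled cells toward the suprabasal compartment
  supra_pct <- function(co) edu_readouts(co)$edu_suprabasal_pct
  expect_gt(supra_pct(co_wave), supra_pct(co_ctrl))
})

test_that("neutral genotypes drift without systematic change in mutant fraction", {
  p <- base_params()
  changes <- vapply(1:30, function(i) {
    sim <- simulate_tissue(80, 20, p, p, t_end_h = 240, sample_times_h = 240,
                           seed = 500 + i)
    s <- summary_stats(sim$clones[sim$clones$observable, ])
    s$mutant_basal_pct - 20
  }, numeric(1))
  expect_lt(abs(mean(changes)), 3 * sd(changes) / sqrt(length(changes)))
})

test_that("a wild-type-only differentiation wave expands the mutant fraction", {
  p <- base_params()
  wt_sch <- schedule_modify(constant_schedule(p, 720), 0, 24,
                            function(row) { row$rho <- 0.5; row })
  sim <- simulate_tissue(425, 75, wt_sch, constant_schedule(p, 720),
                         t_end_h = 720, sample_times_h = 720, seed = 77)
  s <- summary_stats(sim$clones[sim$clones$observable, ])
  expect_gt(s$mutant_basal_pct, 15)
  # and the reverse: a mutant-only negative tilt depletes the mutant pool
  mut_sch <- schedule_modify(constant_schedule(p, 720), 0, 240,
                             function(row) {
                               pr <- spclone:::shift_symmetric_probs(
                                 row$p_pp, row$p_dd, -0.5)
                               row$p_pp <- pr$p_pp; row$p_dd <- pr$p_dd
                               row
                             })
  sim2 <- simulate_tissue(425, 75, constant_schedule(p, 720), mut_sch,
                          t_end_h = 720, sample_times_h = 720, seed = 78)
  s2 <- summary_stats(sim2$clones[sim2$clones$observable, ])
  expect_lt(s2$mutant_basal_pct, s$mutant_basal_pct)
})

test_that("tissue simulation rejects a non-positive reference density", {
  p <- base_params()
  expect_error(
    simulate_tissue(10, 0, p, p, t_end_h = 24, sample_times_h = 24,
                    feedback = feedback_rule(b0 = -5)),
    class = "spclone_config_error")
})
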