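# ---------------------------------------------------------------------------
# Exact stochastic simulation of single-progenitor clones.
#
# Internal state representation: an integer matrix with one row per clone and
# columns n_p, n_d, n_s, n_shed, edu_p, edu_d, edu_s, edu_shed, n_div. The
# CTMC is advanced by sim_step_cpp() with rates constant over each step;
# steps end at schedule boundaries, feedback updates, EdU pulses and sample
# times, so piecewise-constant rates are honoured exactly (memorylessness).
# ---------------------------------------------------------------------------

STATE_COLS <- c("n_p", "n_d", "n_s", "n_shed",
                "edu_p", "edu_d", "edu_s", "edu_shed", "n_div")

new_state_matrix <- function(n_clones) {
  m <- matrix(0L, nrow = n_clones, ncol = length(STATE_COLS),
              dimnames = list(NULL, STATE_COLS))
  m[, "n_p"] <- 1L
  m
}

# advance all clones by dt hours under one parameter row (per-day rates)
step_states <- function(states, row, dt_h) {
  if (dt_h <= 0) return(states)
  out <- sim_step_cpp(states,
                      lambda = row$lambda / 24, p_pp = row$p_pp,
                      p_pd = row$p_pd, p_dd = row$p_dd,
                      gamma = row$gamma / 24, mu = row$mu / 24,
                      rho = row$rho / 24, dt = dt_h)
  dimnames(out) <- dimnames(states)
  out
}

states_to_tibble <- function(states, time_h, genotype, clone_id) {
  tibble(
    clone_id = clone_id,
    genotype = genotype,
    time_h = time_h,
    n_p = states[, "n_p"], n_d = states[, "n_d"], n_s = states[, "n_s"],
    n_shed = states[, "n_shed"], n_div = states[, "n_div"],
    m_basal = states[, "n_p"] + states[, "n_d"],
    n_suprabasal = states[, "n_s"],
    edu_basal = states[, "edu_p"] + states[, "edu_d"],
    edu_suprabasal = states[, "edu_s"],
    edu_shed = states[, "edu_shed"],
    observable = (states[, "n_p"] + states[, "n_d"] + states[, "n_s"]) >= 1L
  )
}

#' EdU pulse-labelling probability
#'
#' A 1 h EdU pulse labels progenitors that are in S phase. The simplest
#' proliferation-proportional model labels each progenitor independently
#' with probability `min(1, lambda * tau_s / 24)`, i.e. the fraction of
#' the day a cycling cell spends in S phase. Labels are inherited by both
#' daughters at division and never removed (dilution is ignored, which is
#' adequate for chases of 48 h or less).
#'
#' @param lambda Division rate per day at the time of the pulse.
#' @param tau_s_h S-phase duration in hours (default 8).
#' @return Labelling probability in `[0, 1]`.
#' @export
edu_label_prob <- function(lambda, tau_s_h = 8) {
  if (tau_s_h <= 0) abort("tau_s_h must be positive",
                          class = "spclone_config_error")
  min(1, lambda * tau_s_h / 24)
}

# label progenitors in a state matrix (binomial thinning); prior labels kept
pulse_states <- function(states, p_label) {
  add <- rbinom(nrow(states), states[, "n_p"] - states[, "edu_p"], p_label)
  states[, "edu_p"] <- states[, "edu_p"] + as.integer(add)
  states
}

#' Apply an EdU pulse to a cohort snapshot
#'
#' Labels progenitors of each clone independently with the S-phase
#' probability [edu_label_prob()]. Intended for cohort tables holding the
#' internal compartment counts (`n_p` etc.), e.g. rows produced by
#' [simulate_cohort()] at the pulse time.
#'
#' @param data A tibble with columns `n_p` and `edu_basal` (clone states).
#' @param lambda Division rate per day at the pulse.
#' @param tau_s_h S-phase duration, hours.
#' @param seed Optional integer seed.
#' @return `data` with `edu_basal` increased by the newly labelled
#'   progenitors.
#' @export
apply_edu_pulse <- function(data, lambda, tau_s_h = 8, seed = NULL) {
  stopifnot("n_p" %in% names(data))
  p <- edu_label_prob(lambda, tau_s_h)
  run <- function() {
    add <- rbinom(nrow(data), data$n_p, p)
    data$edu_basal <- (data$edu_basal %||% 0L) + as.integer(add)
    data
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort of independent clones
#'
#' Runs the exact continuous-time Markov simulation of `n_clones`
#' independent clones, each founded by a single progenitor, under a
#' piecewise-constant parameter schedule. One record per clone per sample
#' time is returned; fully shed clones (`m + n = 0`) are retained and
#' flagged `observable = FALSE`, since microscopy cannot see them.
#'
#' Identical `seed` and schedule reproduce the identical table.
#'
#' @param n_clones Number of clones (founders).
#' @param schedule A `fate_schedule` (or a `fate_params`, taken as
#'   constant over the horizon).
#' @param sample_times_h Times (hours) at which clone states are recorded.
#' @param seed Optional integer seed.
#' @param edu_pulse_h Optional EdU pulse time (hours).
#' @param tau_s_h S-phase duration for the pulse, hours.
#' @param genotype Genotype label stored in the output.
#' @return A tibble with one row per clone per sample time: compartment
#'   counts (`n_p`, `n_d`, `n_s`, `n_shed`, `n_div`), observed sizes
#'   (`m_basal`, `n_suprabasal`), EdU counts and the `observable` flag.
#' @export
#' @examples
#' simulate_cohort(50, balanced_fate_params(), sample_times_h = c(24, 48),
#'                 seed = 1)
simulate_cohort <- function(n_clones, schedule, sample_times_h, seed = NULL,
                            edu_pulse_h = NULL, tau_s_h = 8,
                            genotype = "WT") {
  if (n_clones < 1) abort("n_clones must be >= 1",
                          class = "spclone_config_error")
  if (inherits(schedule, "fate_params")) {
    schedule <- constant_schedule(schedule,
                                  t_end_h = max(sample_times_h, edu_pulse_h, 1))
  }
  t_max <- max(sample_times_h, edu_pulse_h %||% -Inf)
  schedule <- validate_schedule(schedule, t_end_h = t_max)
  run <- function() {
    t0 <- schedule$t_start_h[1]
    breaks <- sort(unique(c(
      t0, sample_times_h, edu_pulse_h,
      schedule$t_start_h[schedule$t_start_h > t0 & schedule$t_start_h <= t_max]
    )))
    states <- new_state_matrix(n_clones)
    out <- list()
    record <- function(t) {
      out[[length(out) + 1]] <<-
        states_to_tibble(states, t, genotype, seq_len(n_clones))
    }
    if (breaks[1] %in% sample_times_h) record(breaks[1])
    if (!is.null(edu_pulse_h) && isTRUE(all.equal(breaks[1], edu_pulse_h))) {
      row <- schedule_piece_at(schedule, breaks[1])
      states <- pulse_states(states, edu_label_prob(row$lambda, tau_s_h))
    }
    for (k in seq_len(length(breaks) - 1)) {
      t_a <- breaks[k]; t_b <- breaks[k + 1]
      row <- schedule_piece_at(schedule, t_a)
      states <- step_states(states, row, t_b - t_a)
      if (!is.null(edu_pulse_h) && isTRUE(all.equal(t_b, edu_pulse_h))) {
        states <- pulse_states(states, edu_label_prob(row$lambda, tau_s_h))
      }
      if (any(abs(t_b - sample_times_h) < 1e-9)) record(t_b)
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a single clone trajectory
#'
#' Thin wrapper around [simulate_cohort()] for one founder, recording the
#' state on a regular time grid.
#'
#' @param schedule A `fate_schedule` or `fate_params`.
#' @param t_end_h End of the trajectory, hours.
#' @param seed Optional integer seed.
#' @param at Sample times; default 49 evenly spaced points plus 0.
#' @return A tibble of clone states over time.
#' @export
simulate_clone <- function(schedule, t_end_h, seed = NULL,
                           at = seq(0, t_end_h, length.out = 49)) {
  simulate_cohort(1, schedule, sample_times_h = at, seed = seed)
}

#' Simulate competing genotypes under shared density feedback
#'
#' Wild-type and mutant clones evolve under genotype-specific schedules
#' while sharing one basal-density pool: at every feedback update the
#' total basal cell count `B(t)` over all clones sets a common fate tilt
#' via the [feedback_rule()], which is added to each genotype's scheduled
#' division-outcome probabilities. A genotype that resists a
#' differentiation wave therefore expands at the expense of the one that
#' differentiates, reproducing clonal competition through the shared
#' niche.
#'
#' @param n_wt,n_mut Number of wild-type and mutant founder clones.
#' @param schedule_wt,schedule_mut Genotype-specific `fate_schedule`s.
#' @param t_end_h Simulation horizon, hours.
#' @param sample_times_h Clone-recording times, hours.
#' @param feedback A [feedback_rule()]; its `b0` defaults to the initial
#'   total basal count.
#' @param seed Optional integer seed.
#' @param edu_pulse_h Optional EdU pulse time, hours.
#' @param tau_s_h S-phase duration for the pulse, hours.
#' @return An object of class `tissue_sim`: list with `clones` (tibble as
#'   in [simulate_cohort()], plus `genotype`), `density` (tibble of
#'   `time_h`, `basal_total`, `rel_density`, `delta_fb`) and `b0`.
#' @export
simulate_tissue <- function(n_wt, n_mut, schedule_wt, schedule_mut,
                            t_end_h, sample_times_h,
                            feedback = feedback_rule(), seed = NULL,
                            edu_pulse_h = NULL, tau_s_h = 8) {
  stopifnot(n_wt >= 0, n_mut >= 0, n_wt + n_mut >= 1)
  if (inherits(schedule_wt, "fate_params"))
    schedule_wt <- constant_schedule(schedule_wt, t_end_h)
  if (inherits(schedule_mut, "fate_params"))
    schedule_mut <- constant_schedule(schedule_mut, t_end_h)
  schedule_wt <- validate_schedule(schedule_wt, t_end_h = t_end_h)
  schedule_mut <- validate_schedule(schedule_mut, t_end_h = t_end_h)
  run <- function() {
    t0 <- min(schedule_wt$t_start_h[1], schedule_mut$t_start_h[1])
    # homeostatic basal density per founder is 1 + lambda/gamma: each
    # progenitor is accompanied, at stationarity, by lambda/gamma basal
    # differentiating cells awaiting stratification
    row0 <- schedule_piece_at(if (n_wt > 0) schedule_wt else schedule_mut, t0)
    b0 <- feedback$b0 %||% ((n_wt + n_mut) * (1 + row0$lambda / row0$gamma))
    if (b0 <= 0) abort("reference basal density must be positive",
                       class = "spclone_config_error")
    breaks <- sort(unique(c(
      t0, t_end_h, sample_times_h, edu_pulse_h,
      seq(t0, t_end_h, by = feedback$update_h),
      schedule_wt$t_start_h, schedule_mut$t_start_h
    )))
    breaks <- breaks[breaks >= t0 & breaks <= t_end_h]
    st <- list(WT = if (n_wt > 0) new_state_matrix(n_wt) else NULL,
               mut = if (n_mut > 0) new_state_matrix(n_mut) else NULL)
    sch <- list(WT = schedule_wt, mut = schedule_mut)
    geno_label <- c(WT = "WT", mut = "p53mut")
    clones <- list(); density <- list()
    basal_total <- function() {
      sum(vapply(st, function(s) {
        if (is.null(s)) 0 else sum(s[, "n_p"]) + sum(s[, "n_d"])
      }, numeric(1)))
    }
    record_clones <- function(t) {
      offset <- 0L
      for (g in names(st)) {
        if (is.null(st[[g]])) next
        ids <- offset + seq_len(nrow(st[[g]]))
        clones[[length(clones) + 1]] <<-
          states_to_tibble(st[[g]], t, geno_label[[g]], ids)
        offset <- offset + nrow(st[[g]])
      }
    }
    if (breaks[1] %in% sample_times_h) record_clones(breaks[1])
    for (k in seq_len(length(breaks) - 1)) {
      t_a <- breaks[k]; t_b <- breaks[k + 1]
      b <- basal_total()
      d_fb <- feedback_delta(feedback, b, b0)
      density[[length(density) + 1]] <-
        tibble(time_h = t_a, basal_total = b,
               rel_density = b / b0, delta_fb = d_fb)
      lam_mult <- feedback_lambda_mult(feedback, b, b0)
      for (g in names(st)) {
        if (is.null(st[[g]])) next
        row <- schedule_piece_at(sch[[g]], t_a)
        pr <- shift_symmetric_probs(row$p_pp, row$p_dd, d_fb)
        row$p_pp <- pr$p_pp; row$p_dd <- pr$p_dd
        row$lambda <- row$lambda * lam_mult
        st[[g]] <- step_states(st[[g]], row, t_b - t_a)
        if (!is.null(edu_pulse_h) && isTRUE(all.equal(t_b, edu_pulse_h))) {
          st[[g]] <- pulse_states(st[[g]],
                                  edu_label_prob(row$lambda, tau_s_h))
        }
      }
      if (any(abs(t_b - sample_times_h) < 1e-9)) record_clones(t_b)
    }
    b <- basal_total()
    density[[length(density) + 1]] <-
      tibble(time_h = t_end_h, basal_total = b, rel_density = b / b0,
             delta_fb = feedback_delta(feedback, b, b0))
    structure(list(clones = dplyr::bind_rows(clones),
                   density = dplyr::bind_rows(density), b0 = b0),
              class = "tissue_sim")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.tissue_sim <- function(x, ...) {
  cat(sprintf("<tissue_sim> %d clone records, B0 = %g, %d density points\n",
              nrow(x$clones), x$b0, nrow(x$density)))
  invisible(x)
}

#' Sample division outcomes
#'
#' Draws `n_draws` independent division outcomes from the outcome
#' probabilities of `params` and reports the realised fraction of
#' progenitor daughters (out of `2 n_draws` daughters). Under balanced
#' parameters this fraction converges to 50%.
#'
#' @param params A `fate_params` object.
#' @param n_draws Number of divisions to sample.
#' @param seed Optional integer seed.
#' @return A tibble with outcome counts and
#'   `progenitor_daughter_fraction`.
#' @export
sample_division_outcomes <- function(params, n_draws, seed = NULL) {
  stopifnot(inherits(params, "fate_params"), n_draws >= 1)
  run <- function() {
    k <- sample.int(3L, n_draws, replace = TRUE,
                    prob = c(params$p_pp, params$p_pd, params$p_dd))
    n_pp <- sum(k == 1L); n_pd <- sum(k == 2L); n_dd <- sum(k == 3L)
    tibble(n_pp = n_pp, n_pd = n_pd, n_dd = n_dd,
           progenitor_daughter_fraction = (2 * n_pp + n_pd) / (2 * n_draws))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
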