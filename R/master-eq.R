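# ---------------------------------------------------------------------------
# Truncated master equation for the single-progenitor CTMC.
#
# The state space is (n_P <= p_max, n_D <= d_max, n_S <= s_max) plus one
# absorbing "leak" state that accumulates probability flowing across the
# truncation boundary; total mass is conserved exactly. The equation
# d p/dt = p Q is solved by uniformisation (Poisson-weighted powers of the
# discrete skeleton), which is unconditionally stable and conserves mass
# to the Poisson tail tolerance (< 1e-12). The solver serves both as an
# exact oracle for the stochastic simulator and as the likelihood engine
# for fate-bias inference.
# ---------------------------------------------------------------------------

#' Truncation bounds for the master equation
#'
#' @param p_max,d_max,s_max Caps on progenitor, basal-differentiating and
#'   suprabasal counts.
#' @return A named list.
#' @export
truncation <- function(p_max = 20, d_max = 20, s_max = 30) {
  stopifnot(p_max >= 1, d_max >= 1, s_max >= 1)
  list(p_max = as.integer(p_max), d_max = as.integer(d_max),
       s_max = as.integer(s_max))
}

state_index <- function(a, b, c, tr) {
  a * (tr$d_max + 1L) * (tr$s_max + 1L) + b * (tr$s_max + 1L) + c + 1L
}

state_grid <- function(tr) {
  g <- expand.grid(c = 0:tr$s_max, b = 0:tr$d_max, a = 0:tr$p_max,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("a", "b", "c")]
}

#' Build the truncated generator of the clone process
#'
#' Off-diagonal rates (per hour): division `lambda * n_P` split by the
#' three outcome probabilities, induced differentiation `rho * n_P`,
#' stratification `gamma * n_D`, shedding `mu * n_S`. Transitions leaving
#' the truncated box are routed to an absorbing leak state so that every
#' row of the generator sums to zero.
#'
#' @param params A `fate_params` (rates per day; converted internally).
#' @param trunc A [truncation()] list.
#' @return A list with the sparse generator `Q` (rows = origin states,
#'   last row/column = leak), the uniformisation skeleton, the state
#'   grid, and the truncation.
#' @export
build_generator <- function(params, trunc = truncation()) {
  stopifnot(inherits(params, "fate_params"))
  tr <- trunc
  g <- state_grid(tr)
  n_states <- nrow(g)
  leak <- n_states + 1L
  a <- g$a; b <- g$b; c <- g$c
  lam <- params$lambda / 24; gam <- params$gamma / 24
  mu <- params$mu / 24; rho <- params$rho / 24
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(r, a2, b2, c2) {
    keep <- r > 0
    if (!any(keep)) return(invisible())
    inside <- keep & a2 <= tr$p_max & b2 <= tr$d_max & c2 <= tr$s_max &
      a2 >= 0 & b2 >= 0 & c2 >= 0
    tgt <- ifelse(inside, state_index(pmax(a2, 0), pmax(b2, 0), pmax(c2, 0), tr),
                  leak)
    from <<- c(from, which(keep))
    to <<- c(to, tgt[keep])
    rate <<- c(rate, r[keep])
  }
  add(lam * a * params$p_pp, a + 1L, b, c)        # PP division
  add(lam * a * params$p_pd, a, b + 1L, c)        # PD division
  add(lam * a * params$p_dd, a - 1L, b + 2L, c)   # DD division
  add(rho * a, a - 1L, b + 1L, c)                 # induced P -> D
  add(gam * b, a, b - 1L, c + 1L)                 # stratification
  add(mu * c, a, b, c - 1L)                       # shedding
  q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                            dims = c(leak, leak))
  out_rate <- Matrix::rowSums(q)
  q <- q - Matrix::Diagonal(leak, out_rate)
  lambda_u <- max(out_rate)
  skeleton_t <- if (lambda_u > 0) {
    Matrix::t(Matrix::Diagonal(leak) + q / lambda_u)
  } else NULL
  list(Q = q, skeleton_t = skeleton_t, lambda_u = lambda_u,
       states = g, trunc = tr, params = params)
}

new_state_distribution <- function(p, trunc, time_h) {
  structure(list(p = p, trunc = trunc, time_h = time_h), class = "state_distribution")
}

#' Initial distribution: one founding progenitor
#'
#' @param trunc A [truncation()] list.
#' @return A `state_distribution` concentrated on state (1, 0, 0).
#' @export
initial_distribution <- function(trunc = truncation()) {
  n <- (trunc$p_max + 1) * (trunc$d_max + 1) * (trunc$s_max + 1)
  p <- numeric(n + 1)
  p[state_index(1L, 0L, 0L, trunc)] <- 1
  new_state_distribution(p, trunc, time_h = 0)
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("<state_distribution> t = %g h, mass = %.9f, leak = %.3g\n",
              x$time_h, sum(x$p), leak_mass(x)))
  invisible(x)
}

#' Truncation leak of a state distribution
#' @param dist A `state_distribution`.
#' @return Probability mass absorbed at the truncation boundary.
#' @export
leak_mass <- function(dist) dist$p[length(dist$p)]

# advance a distribution by dt hours under one generator (uniformisation)
evolve_dist <- function(dist, gen, dt_h, tail_tol = 1e-13) {
  if (dt_h < 0) abort("cannot evolve backwards in time",
                      class = "spclone_numeric_error")
  if (dt_h == 0 || gen$lambda_u == 0) {
    dist$time_h <- dist$time_h + dt_h
    return(dist)
  }
  lt <- gen$lambda_u * dt_h
  k_max <- max(1, qpois(1 - tail_tol, lt) + 5)
  w <- dpois(0:k_max, lt)
  v <- dist$p
  acc <- w[1] * v
  for (k in seq_len(k_max)) {
    v <- as.numeric(gen$skeleton_t %*% v)
    acc <- acc + w[k + 1] * v
  }
  acc <- acc / sum(w)  # remove Poisson tail (< tail_tol) to conserve mass
  if (any(!is.finite(acc))) {
    abort("master-equation integration failed",
          class = "spclone_numeric_error")
  }
  new_state_distribution(acc, dist$trunc, dist$time_h + dt_h)
}

#' Evolve the clone-state distribution
#'
#' Solves the master equation from `dist0` (default: one founding
#' progenitor at t = 0) to time `t_h` under constant parameters or a
#' piecewise-constant schedule. When the probability leaked through the
#' truncation boundary exceeds `leak_warn`, the truncation is enlarged
#' by 50% per axis and the evolution restarted (up to `max_enlarge`
#' times), with a warning.
#'
#' @param params A `fate_params` or `fate_schedule`.
#' @param t_h Target time, hours.
#' @param dist0 Optional starting `state_distribution`.
#' @param trunc A [truncation()].
#' @param leak_warn Leak threshold that triggers enlargement.
#' @param max_enlarge Maximum number of automatic enlargements.
#' @return A `state_distribution` at `t_h`.
#' @export
#' @examples
#' d <- master_evolve(balanced_fate_params(), t_h = 48)
#' sum(d$p)
master_evolve <- function(params, t_h, dist0 = NULL, trunc = truncation(),
                          leak_warn = 1e-6, max_enlarge = 2) {
  for (round in 0:max_enlarge) {
    d0 <- dist0 %||% initial_distribution(trunc)
    if (!is.null(dist0) && !identical(dist0$trunc, trunc)) {
      d0 <- embed_distribution(dist0, trunc)
    }
    if (leak_mass(d0) >= 1e-6) {
      abort("starting distribution already has leak >= 1e-6",
            class = "spclone_numeric_error")
    }
    dist <- evolve_schedule(params, t_h, d0, trunc)
    if (leak_mass(dist) <= leak_warn || round == max_enlarge) {
      if (leak_mass(dist) > leak_warn) {
        warn(sprintf("truncation leak %.3g exceeds %.3g after %d enlargements",
                     leak_mass(dist), leak_warn, max_enlarge))
      }
      return(dist)
    }
    warn(sprintf("truncation leak %.3g > %.3g; enlarging state space",
                 leak_mass(dist), leak_warn))
    trunc <- truncation(ceiling(trunc$p_max * 1.5),
                        ceiling(trunc$d_max * 1.5),
                        ceiling(trunc$s_max * 1.5))
  }
}

evolve_schedule <- function(params, t_h, dist, trunc) {
  if (inherits(params, "fate_params")) {
    gen <- build_generator(params, trunc)
    return(evolve_dist(dist, gen, t_h - dist$time_h))
  }
  sch <- validate_schedule(params, t_start_h = dist$time_h, t_end_h = t_h)
  for (i in seq_len(nrow(sch))) {
    t_a <- max(sch$t_start_h[i], dist$time_h)
    t_b <- min(sch$t_end_h[i], t_h)
    if (t_b <= t_a) next
    row <- sch[i, ]
    gen <- build_generator(
      fate_params(row$lambda, row$p_pp, row$p_pd, row$p_dd,
                  row$gamma, row$mu, row$rho), trunc)
    dist <- evolve_dist(dist, gen, t_b - t_a)
  }
  dist
}

# re-embed a distribution on a larger truncation (used by auto-enlarge)
embed_distribution <- function(dist, trunc_new) {
  tr_old <- dist$trunc
  g <- state_grid(tr_old)
  p_new <- numeric((trunc_new$p_max + 1) * (trunc_new$d_max + 1) *
                     (trunc_new$s_max + 1) + 1)
  idx_new <- state_index(g$a, g$b, g$c, trunc_new)
  p_new[idx_new] <- dist$p[seq_len(nrow(g))]
  p_new[length(p_new)] <- leak_mass(dist)
  new_state_distribution(p_new, trunc_new, dist$time_h)
}

#' Clone-size marginal of a state distribution
#'
#' Maps the state probabilities to the observable clone size
#' `(m, n) = (n_P + n_D, n_S)`. With `observed_only = TRUE` the marginal
#' is renormalised over visible clones (`m + n >= 1`), matching what
#' microscopy can count.
#'
#' @param dist A `state_distribution` (leak should be small; it is
#'   excluded from the marginal).
#' @param observed_only Condition on `m + n >= 1`?
#' @return A `clone_histogram` over the full truncated grid.
#' @export
clone_size_marginal <- function(dist, observed_only = FALSE) {
  tr <- dist$trunc
  g <- state_grid(tr)
  m <- g$a + g$b
  n <- g$c
  f <- matrix(0, nrow = tr$p_max + tr$d_max + 1, ncol = tr$s_max + 1,
              dimnames = list(m = 0:(tr$p_max + tr$d_max), n = 0:tr$s_max))
  p <- dist$p[seq_len(nrow(g))]
  agg <- rowsum(p, group = m * (tr$s_max + 1L) + n)
  key <- as.integer(rownames(agg))
  f[cbind(key %/% (tr$s_max + 1L) + 1L, key %% (tr$s_max + 1L) + 1L)] <- agg[, 1]
  if (observed_only) {
    f[1, 1] <- 0
    if (sum(f) <= 0) abort("no observable mass", class = "spclone_numeric_error")
    f <- f / sum(f)
  }
  new_histogram2d(f, n_clones = NA_integer_)
}

#' Mean progenitor number of a state distribution
#'
#' @param dist A `state_distribution`.
#' @return `E[n_P]` over the truncated states (leak excluded).
#' @export
mean_progenitors <- function(dist) {
  g <- state_grid(dist$trunc)
  sum(g$a * dist$p[seq_len(nrow(g))])
}

#' Log-likelihood of a clone table under the model
#'
#' Sums `log f_{m,n}(t)` over clones, with the clone-size distribution
#' obtained from the master equation at each observation time. With
#' `conditioning = "observed"` (default) the distribution is conditioned
#' on the clone being visible (`m + n >= 1`), matching microscopy.
#' Clones outside the truncated grid contribute through the clipped edge
#' cell, with a warning.
#'
#' @param data Clone table with `m_basal`, `n_suprabasal`, `time_h`.
#' @param params A `fate_params` or `fate_schedule`.
#' @param conditioning `"observed"` or `"none"`.
#' @param trunc A [truncation()].
#' @return The log-likelihood (scalar). `-Inf`, with a warning, if an
#'   observation has probability zero under `"none"` conditioning.
#' @export
log_likelihood <- function(data, params,
                           conditioning = c("observed", "none"),
                           trunc = truncation()) {
  conditioning <- match.arg(conditioning)
  require_clones(data)
  if (!"time_h" %in% names(data)) {
    abort("data must contain time_h", class = "spclone_schema_error")
  }
  log_f <- loglik_tables(params, sort(unique(data$time_h)), conditioning, trunc)
  ll_of <- function(m, n, t) {
    lf <- log_f[[as.character(t)]]
    mi <- pmin(m, nrow(lf) - 1L); ni <- pmin(n, ncol(lf) - 1L)
    if (any(m > nrow(lf) - 1L | n > ncol(lf) - 1L)) {
      warn("clones larger than the truncated grid contribute via the edge cell")
    }
    lf[cbind(mi + 1L, ni + 1L)]
  }
  ll <- 0
  for (t in unique(data$time_h)) {
    sub <- data[data$time_h == t, ]
    ll <- ll + sum(ll_of(sub$m_basal, sub$n_suprabasal, t))
  }
  if (!is.finite(ll)) warn("zero-probability observation: log-likelihood is -Inf")
  ll
}

# per-time log f_{m,n} lookup tables under the given conditioning
loglik_tables <- function(params, times, conditioning, trunc) {
  out <- list()
  dist <- initial_distribution(trunc)
  constant <- inherits(params, "fate_params")
  for (t in times) {
    dist <- if (constant) {
      evolve_schedule(params, t, dist, trunc)   # continue from previous time
    } else {
      evolve_schedule(params, t, initial_distribution(trunc), trunc)
    }
    f <- clone_size_marginal(dist, observed_only = (conditioning == "observed"))
    out[[as.character(t)]] <- log(f$f)
  }
  out
}

# ---- fate-bias inference --------------------------------------------------

#' Profile-likelihood tables for a tilt grid
#'
#' Precomputes, for each candidate tilt, the log clone-size distribution
#' at each observation time. Useful when many cohorts are fitted under
#' the same design (the tables are shared across fits).
#'
#' @param base_params Balanced `fate_params` whose tilt is profiled.
#' @param delta_grid Candidate tilt values.
#' @param times Observation times (hours).
#' @param conditioning `"observed"` or `"none"`.
#' @param trunc A [truncation()].
#' @return A named list of per-delta log-probability tables.
#' @export
tilt_marginal_grid <- function(base_params, delta_grid, times,
                               conditioning = "observed",
                               trunc = truncation()) {
  setNames(lapply(delta_grid, function(d) {
    loglik_tables(apply_tilt(base_params, d), times, conditioning, trunc)
  }), as.character(delta_grid))
}

#' Recover the fate tilt from a clone table
#'
#' Profiles the log-likelihood of the observed clone sizes over a grid
#' of tilt values `delta`, with the remaining rates fixed at
#' `base_params` (joint fitting from single-time clone data is weakly
#' identified). The estimate is the grid maximiser refined by quadratic
#' interpolation; the confidence interval is the profile likelihood-ratio
#' set at the requested level. Deterministic given the table.
#'
#' @param data Clone table (observable clones) with `m_basal`,
#'   `n_suprabasal`, `time_h`.
#' @param base_params Balanced `fate_params` (fixed baseline rates).
#' @param delta_grid Grid of candidate tilts.
#' @param level Confidence level of the profile interval.
#' @param conditioning `"observed"` (default) or `"none"`.
#' @param trunc A [truncation()].
#' @param marginals Optional precomputed [tilt_marginal_grid()].
#' @return An object of class `tilt_fit`.
#' @export
fit_tilt <- function(data, base_params,
                     delta_grid = seq(-0.6, 0.6, by = 0.025),
                     level = 0.95,
                     conditioning = c("observed", "none"),
                     trunc = truncation(), marginals = NULL) {
  conditioning <- match.arg(conditioning)
  require_clones(data)
  times <- sort(unique(data$time_h))
  if (is.null(marginals)) {
    marginals <- tilt_marginal_grid(base_params, delta_grid, times,
                                    conditioning, trunc)
  }
  if (length(marginals) != length(delta_grid)) {
    abort("marginals do not match delta_grid", class = "spclone_config_error")
  }
  counts <- dplyr::count(data, .data$time_h, .data$m_basal, .data$n_suprabasal)
  ll <- vapply(marginals, function(tabs) {
    s <- 0
    for (t in times) {
      lf <- tabs[[as.character(t)]]
      sub <- counts[counts$time_h == t, ]
      mi <- pmin(sub$m_basal, nrow(lf) - 1L)
      ni <- pmin(sub$n_suprabasal, ncol(lf) - 1L)
      s <- s + sum(sub$n * lf[cbind(mi + 1L, ni + 1L)])
    }
    s
  }, numeric(1))
  ll <- unname(ll)
  j <- which.max(ll)
  identifiable <- (max(ll) - min(ll)) > 1e-6
  if (!identifiable) warn("flat likelihood: tilt is not identifiable")
  # quadratic refinement at an interior maximum
  est <- delta_grid[j]
  ll_max <- ll[j]
  if (j > 1 && j < length(ll)) {
    h1 <- delta_grid[j] - delta_grid[j - 1]
    h2 <- delta_grid[j + 1] - delta_grid[j]
    denom <- ll[j + 1] - 2 * ll[j] + ll[j - 1]
    if (is.finite(denom) && denom < 0 && abs(h1 - h2) < 1e-9) {
      est <- delta_grid[j] - 0.5 * h1 * (ll[j + 1] - ll[j - 1]) / denom
      ll_max <- ll[j] - (ll[j + 1] - ll[j - 1])^2 / (8 * denom)
    }
  }
  thr <- ll_max - qchisq(level, df = 1) / 2
  lo <- min(delta_grid); hi <- max(delta_grid)
  below <- ll < thr
  if (any(below[seq_len(j)])) {
    k <- max(which(below[seq_len(j)]))
    lo <- delta_grid[k] + (thr - ll[k]) / (ll[k + 1] - ll[k]) *
      (delta_grid[k + 1] - delta_grid[k])
  }
  if (any(below[j:length(ll)])) {
    k <- j - 1L + min(which(below[j:length(ll)]))
    lo_k <- k - 1L
    hi <- delta_grid[lo_k] + (thr - ll[lo_k]) / (ll[k] - ll[lo_k]) *
      (delta_grid[k] - delta_grid[lo_k])
  }
  structure(list(
    estimate = est, conf.low = lo, conf.high = hi, level = level,
    loglik = ll_max, n_clones = nrow(data),
    profile = tibble(delta = delta_grid, loglik = ll),
    conditioning = conditioning, identifiable = identifiable
  ), class = "tilt_fit")
}

#' @export
print.tilt_fit <- function(x, ...) {
  cat(sprintf("<tilt_fit> delta = %.4f [%.4f, %.4f] (%.0f%% profile CI), n = %d clones\n",
              x$estimate, x$conf.low, x$conf.high, 100 * x$level, x$n_clones))
  if (!x$identifiable) cat("  WARNING: flat likelihood (non-identifiable)\n")
  invisible(x)
}

#' @rdname fit_tilt
#' @param x A `tilt_fit`.
#' @param ... Unused.
#' @export
tidy.tilt_fit <- function(x, ...) {
  tibble(term = "delta", estimate = x$estimate,
         conf.low = x$conf.low, conf.high = x$conf.high)
}

#' @rdname fit_tilt
#' @export
glance.tilt_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_clones = x$n_clones, level = x$level,
         conditioning = x$conditioning, identifiable = x$identifiable)
}
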