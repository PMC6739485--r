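#' Piecewise-constant parameter schedules
#'
#' A `fate_schedule` is a tibble of contiguous, non-overlapping time
#' intervals (in hours) with one set of fate parameters per interval. It
#' encodes the time-varying response of a genotype to an exposure
#' protocol: e.g. a 24 h induced-differentiation wave after each
#' irradiation. Rates are stored per day; the simulator converts to per
#' hour internally.
#'
#' @param params A `fate_params` object applying over the whole interval.
#' @param t_end_h End of the covered horizon, hours.
#' @param t_start_h Start of the covered horizon, hours.
#' @return A `fate_schedule` tibble with columns `t_start_h`, `t_end_h`,
#'   `lambda`, `p_pp`, `p_pd`, `p_dd`, `gamma`, `mu`, `rho`.
#' @export
#' @examples
#' constant_schedule(balanced_fate_params(), t_end_h = 240)
constant_schedule <- function(params, t_end_h, t_start_h = 0) {
  stopifnot(inherits(params, "fate_params"), t_end_h > t_start_h)
  out <- tibble(
    t_start_h = t_start_h, t_end_h = t_end_h,
    lambda = params$lambda, p_pp = params$p_pp, p_pd = params$p_pd,
    p_dd = params$p_dd, gamma = params$gamma, mu = params$mu, rho = params$rho
  )
  class(out) <- c("fate_schedule", class(out))
  out
}

#' Validate a schedule against a simulation horizon
#'
#' Checks that the intervals are contiguous, non-overlapping and cover
#' `[t_start_h, t_end_h]`, and that every row is a valid parameter set.
#'
#' @param schedule A `fate_schedule` tibble.
#' @param t_start_h,t_end_h Horizon that must be covered, hours.
#' @return The schedule, invisibly, ordered by `t_start_h`.
#' @export
validate_schedule <- function(schedule, t_start_h = min(schedule$t_start_h),
                              t_end_h = max(schedule$t_end_h)) {
  req <- c("t_start_h", "t_end_h", "lambda", "p_pp", "p_pd", "p_dd",
           "gamma", "mu", "rho")
  if (!all(req %in% names(schedule))) {
    abort("schedule is missing required columns",
          class = "spclone_config_error")
  }
  sch <- dplyr::arrange(schedule, .data$t_start_h)
  if (any(sch$t_end_h <= sch$t_start_h)) {
    abort("schedule has empty or reversed intervals",
          class = "spclone_config_error")
  }
  if (nrow(sch) > 1 &&
      any(abs(sch$t_start_h[-1] - sch$t_end_h[-nrow(sch)]) > 1e-9)) {
    abort("schedule has a gap or overlap between intervals",
          class = "spclone_config_error")
  }
  if (sch$t_start_h[1] > t_start_h + 1e-9 ||
      sch$t_end_h[nrow(sch)] < t_end_h - 1e-9) {
    abort("schedule does not cover the simulation horizon",
          class = "spclone_config_error")
  }
  for (i in seq_len(nrow(sch))) {
    fate_params(sch$lambda[i], sch$p_pp[i], sch$p_pd[i], sch$p_dd[i],
                sch$gamma[i], sch$mu[i], sch$rho[i])
  }
  invisible(sch)
}

#' Modify a schedule over a time window
#'
#' Splits the schedule at `from` and `to` (hours) and applies `f` to the
#' parameter columns of every piece inside the window. Used to build
#' perturbation responses, e.g. setting `rho` for 24 h after an exposure
#' or tilting the fate balance over an antioxidant window.
#'
#' @param schedule A `fate_schedule`.
#' @param from,to Window bounds in hours.
#' @param f A function taking and returning a one-row schedule tibble.
#' @return The modified `fate_schedule`.
#' @export
schedule_modify <- function(schedule, from, to, f) {
  stopifnot(to > from)
  pieces <- list()
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    cuts <- sort(unique(pmin(pmax(c(from, to), row$t_start_h), row$t_end_h)))
    bounds <- sort(unique(c(row$t_start_h, cuts, row$t_end_h)))
    for (k in seq_len(length(bounds) - 1)) {
      piece <- row
      piece$t_start_h <- bounds[k]
      piece$t_end_h <- bounds[k + 1]
      if (piece$t_end_h <= piece$t_start_h) next
      if (piece$t_start_h >= from - 1e-9 && piece$t_end_h <= to + 1e-9) {
        piece <- f(piece)
      }
      pieces[[length(pieces) + 1]] <- piece
    }
  }
  out <- dplyr::bind_rows(pieces)
  class(out) <- c("fate_schedule", class(out))
  out
}

# parameter row covering time t (left-closed pieces; last piece
# right-closed)
schedule_piece_at <- function(schedule, t) {
  i <- which(schedule$t_start_h - 1e-9 <= t & t < schedule$t_end_h - 1e-9)
  if (length(i) == 0) i <- nrow(schedule)
  schedule[i[1], ]
}

#' Density-feedback rule
#'
#' Competition between clones is mediated by a shared basal-density pool:
#' when total basal density `B(t)` falls below its homeostatic reference
#' `B0`, every progenitor's division balance is tilted toward renewal,
#' `delta(t) = clamp(k_fb (1 - B(t)/B0), -delta_max, +delta_max)`, and back
#' to zero once density recovers. This implements the compensatory
#' proliferation that restores the tissue to homeostasis after a
#' differentiation wave.
#'
#' Density loss is also compensated through the division rate: while the
#' tissue is below reference density the division rate is multiplied by
#' `1 + k_lambda * max(0, 1 - B/B0)` (capped at `lambda_mult_max`),
#' reflecting the delayed proliferative burst that follows a
#' differentiation wave and restores density within days rather than
#' weeks.
#'
#' @param k_fb Dimensionless feedback gain on the fate tilt.
#' @param delta_max Cap on the applied tilt magnitude.
#' @param update_h Interval (hours) at which the feedback is recomputed;
#'   rates are constant between updates.
#' @param b0 Reference basal cell count; `NULL` means "use the
#'   homeostatic basal count of the simulated tissue".
#' @param k_lambda Gain of the division-rate compensation (only active
#'   below reference density).
#' @param lambda_mult_max Cap on the division-rate multiplier.
#' @return An object of class `feedback_rule`.
#' @export
feedback_rule <- function(k_fb = 6, delta_max = 0.8, update_h = 6, b0 = NULL,
                          k_lambda = 12, lambda_mult_max = 4) {
  if (!is.null(b0) && b0 <= 0) {
    abort("reference basal density b0 must be positive",
          class = "spclone_config_error")
  }
  stopifnot(k_fb >= 0, delta_max >= 0, update_h > 0,
            k_lambda >= 0, lambda_mult_max >= 1)
  structure(list(k_fb = k_fb, delta_max = delta_max,
                 update_h = update_h, b0 = b0,
                 k_lambda = k_lambda, lambda_mult_max = lambda_mult_max),
            class = "feedback_rule")
}

#' @export
print.feedback_rule <- function(x, ...) {
  cat(sprintf("<feedback_rule> k_fb = %.3g, delta_max = %.3g, update every %g h, B0 = %s\n",
              x$k_fb, x$delta_max, x$update_h,
              if (is.null(x$b0)) "initial basal count" else format(x$b0)))
  invisible(x)
}

feedback_delta <- function(rule, b, b0) {
  d <- rule$k_fb * (1 - b / b0)
  pmin(pmax(d, -rule$delta_max), rule$delta_max)
}

feedback_lambda_mult <- function(rule, b, b0) {
  min(1 + rule$k_lambda * max(0, 1 - b / b0), rule$lambda_mult_max)
}
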