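#' Fate parameters of the single-progenitor model
#'
#' A progenitor (P) divides at rate `lambda`; the division produces two
#' progenitors (probability `p_pp`), one progenitor and one differentiating
#' cell (`p_pd`), or two differentiating cells (`p_dd`). Differentiating
#' basal cells (D) stratify into the suprabasal compartment (S) at rate
#' `gamma`, and suprabasal cells are shed from the tissue surface at rate
#' `mu`. `rho` is a division-independent induced-differentiation channel
#' (P turns directly into D), zero in unperturbed tissue; it models the
#' transient differentiation wave that follows an oxidative challenge.
#'
#' All rates are per cell per day. The clone is homeostatic ("balanced")
#' when `p_pp == p_dd` and `rho == 0`: the average division then produces
#' one progenitor and one differentiating daughter, making progenitor
#' number a critical branching process.
#'
#' @param lambda Division rate (per progenitor per day).
#' @param p_pp,p_pd,p_dd Probabilities of the three division outcomes;
#'   must be in `[0, 1]` and sum to 1.
#' @param gamma Stratification rate (per basal differentiating cell per day).
#' @param mu Shedding rate (per suprabasal cell per day).
#' @param rho Induced differentiation rate (per progenitor per day).
#'
#' @return An object of class `fate_params`.
#' @seealso [balanced_fate_params()], [apply_tilt()]
#' @export
#' @examples
#' fate_params(lambda = 2 / 7, p_pp = 0.1, p_pd = 0.8, p_dd = 0.1,
#'             gamma = 0.5, mu = 0.5)
fate_params <- function(lambda, p_pp, p_pd, p_dd, gamma, mu, rho = 0) {
  probs <- c(p_pp = p_pp, p_pd = p_pd, p_dd = p_dd)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("division-outcome probabilities must lie in [0, 1]",
          class = "spclone_domain_error")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort("p_pp + p_pd + p_dd must equal 1 (tolerance 1e-12)",
          class = "spclone_domain_error")
  }
  rates <- c(lambda = lambda, gamma = gamma, mu = mu, rho = rho)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("rates must be finite and non-negative",
          class = "spclone_domain_error")
  }
  structure(
    list(lambda = lambda, p_pp = p_pp, p_pd = p_pd, p_dd = p_dd,
         gamma = gamma, mu = mu, rho = rho),
    class = "fate_params"
  )
}

#' Balanced (homeostatic) fate parameters
#'
#' Builds `fate_params` with symmetric-division probability `r` on both
#' symmetric outcomes (`p_pp = p_dd = r`, `p_pd = 1 - 2r`) and `rho = 0`,
#' so that each division generates, on average, 50% progenitor and 50%
#' differentiating daughters.
#'
#' Defaults are order-of-magnitude calibration choices for mouse
#' esophageal epithelium that keep a simulated tissue statistically
#' stationary in basal density; they are configurable, not measured
#' constants.
#'
#' @param r Symmetric-division probability, in `[0, 0.5]`.
#' @inheritParams fate_params
#' @return A balanced `fate_params` object.
#' @export
#' @examples
#' balanced_fate_params(r = 0.1, lambda = 0.3)
balanced_fate_params <- function(r = 0.1, lambda = 2 / 7, gamma = 0.5, mu = 0.5) {
  if (!is.finite(r) || r < 0 || r > 0.5) {
    abort("r must lie in [0, 0.5]", class = "spclone_domain_error")
  }
  fate_params(lambda = lambda, p_pp = r, p_pd = 1 - 2 * r, p_dd = r,
              gamma = gamma, mu = mu, rho = 0)
}

#' Tilt the division-outcome balance of a clone
#'
#' Applies a relative fate bias `delta` to balanced parameters:
#' `p_pp = r (1 + delta)`, `p_dd = r (1 - delta)`, `p_pd` unchanged.
#' The expected net progenitor gain per division is `2 r delta`; positive
#' tilt drives clonal expansion, negative tilt drives clone loss by
#' differentiation and shedding.
#'
#' @param params A balanced `fate_params` object.
#' @param delta Relative fate bias in `[-1, 1]`.
#' @return A `fate_params` object with the tilted outcome probabilities.
#' @export
#' @examples
#' apply_tilt(balanced_fate_params(r = 0.1), delta = 0.3)
apply_tilt <- function(params, delta) {
  stopifnot(inherits(params, "fate_params"))
  if (abs(params$p_pp - params$p_dd) > 1e-12) {
    abort("apply_tilt() requires balanced parameters (p_pp == p_dd)",
          class = "spclone_domain_error")
  }
  if (!is.finite(delta) || abs(delta) > 1) {
    abort("delta must lie in [-1, 1]", class = "spclone_domain_error")
  }
  r <- params$p_pp
  fate_params(lambda = params$lambda,
              p_pp = r * (1 + delta), p_pd = params$p_pd,
              p_dd = r * (1 - delta),
              gamma = params$gamma, mu = params$mu, rho = params$rho)
}

#' @export
print.fate_params <- function(x, ...) {
  cat("<fate_params>  (rates per day)\n")
  cat(sprintf("  lambda = %.4g   p_pp/p_pd/p_dd = %.3g/%.3g/%.3g\n",
              x$lambda, x$p_pp, x$p_pd, x$p_dd))
  cat(sprintf("  gamma = %.4g   mu = %.4g   rho = %.4g%s\n",
              x$gamma, x$mu, x$rho,
              if (is_balanced(x)) "   [balanced]" else ""))
  invisible(x)
}

#' Is a parameter set homeostatic?
#'
#' @param params A `fate_params` object.
#' @return `TRUE` when `p_pp == p_dd` and `rho == 0`.
#' @export
is_balanced <- function(params) {
  stopifnot(inherits(params, "fate_params"))
  abs(params$p_pp - params$p_dd) <= 1e-12 && params$rho == 0
}

#' @export
as.data.frame.fate_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

# additive tilt used by the density feedback: shifts probability mass
# between the symmetric outcomes of a possibly already-tilted parameter
# row, clamped so both stay in [0, 1]. Operates on plain numeric fields.
shift_symmetric_probs <- function(p_pp, p_dd, delta_fb) {
  r_eff <- (p_pp + p_dd) / 2
  shift <- r_eff * delta_fb
  shift <- pmin(shift, p_dd)   # cannot push p_dd below 0
  shift <- pmax(shift, -p_pp)  # cannot push p_pp below 0
  list(p_pp = p_pp + shift, p_dd = p_dd - shift)
}
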