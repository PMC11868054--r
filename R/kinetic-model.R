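#' Perfusion model parameters
#'
#' Bundle the unknowns of the ASL inverse problem — cerebral blood flow (CBF),
#' bolus arrival time (AT) and blood longitudinal relaxation time (T1b) —
#' together with the fixed bolus duration \eqn{\tau}. CBF is expressed in
#' normalised signal units per second (dimensionless after signal
#' normalisation); all times are in seconds.
#'
#' @param cbf Perfusion amplitude, > 0.
#' @param at Bolus arrival time in seconds, >= 0.
#' @param t1b Blood longitudinal relaxation time in seconds, > 0.
#' @param tau Bolus duration in seconds, > 0. Fixed at 0.9 s (900 ms) for the
#'   pulsed-labelling acquisition this package models.
#'
#' @return An object of class `perfusion_params`: a named list with fields
#'   `cbf`, `at`, `t1b`, `tau`.
#' @examples
#' p <- perfusion_params(cbf = 0.4, at = 0.5, t1b = 1.8)
#' pwi_signal(seq(0, 3.6, by = 0.3), p)
#' @export
perfusion_params <- function(cbf, at, t1b, tau = 0.9) {
  for (nm in c("cbf", "at", "t1b", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (cbf <= 0) rlang::abort("`cbf` must be positive.")
  if (at < 0) rlang::abort("`at` must be non-negative.")
  if (t1b <= 0) rlang::abort("`t1b` must be positive.")
  if (tau <= 0) rlang::abort("`tau` must be positive.")
  structure(list(cbf = cbf, at = at, t1b = t1b, tau = tau),
            class = "perfusion_params")
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf(
    "<perfusion_params> CBF = %.4g, AT = %.4g s, T1b = %.4g s, tau = %.4g s\n",
    x$cbf, x$at, x$t1b, x$tau))
  invisible(x)
}

as_perfusion_params <- function(x) {
  if (inherits(x, "perfusion_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (is.null(x$tau)) x$tau <- 0.9
    return(perfusion_params(x$cbf, x$at, x$t1b, x$tau))
  }
  rlang::abort("Cannot interpret `params`; use perfusion_params().")
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    rlang::abort("`t` must be numeric and finite.")
  }
  if (any(t < 0)) rlang::abort("`t` must be non-negative.")
  invisible(t)
}

#' Analytical ASL perfusion-weighted signal
#'
#' The closed-form single-compartment PWI signal for a top-hat arterial input
#' of duration `tau` arriving at time `at`, with label decay governed by
#' `t1b`:
#' \deqn{S(t) = 0 \quad (t < AT)}
#' \deqn{S(t) = CBF\,(t - AT)\,e^{-t/T1b} \quad (AT \le t < AT+\tau)}
#' \deqn{S(t) = CBF\,\tau\,e^{-t/T1b} \quad (t \ge AT+\tau)}
#'
#' @param t Acquisition time(s) in seconds; vectorised.
#' @param params A [perfusion_params()] object (or coercible list).
#' @return Signal values, same length as `t`.
#' @seealso [ode_rhs()] for the time derivative, [smoothed_ode_rhs()] for the
#'   differentiable surrogate used in PINN training.
#' @export
pwi_signal <- function(t, params) {
  params <- as_perfusion_params(params)
  check_times(t)
  s <- numeric(length(t))
  decay <- exp(-t / params$t1b)
  during <- t >= params$at & t < params$at + params$tau
  after <- t >= params$at + params$tau
  s[during] <- params$cbf * (t[during] - params$at) * decay[during]
  s[after] <- params$cbf * params$tau * decay[after]
  s
}

#' Three-branch ODE right-hand side of the perfusion model
#'
#' Time derivative of [pwi_signal()]. The right-hand side depends on `t` and
#' the parameters only, not on the signal itself:
#' \deqn{dS/dt = 0 \quad (t < AT)}
#' \deqn{dS/dt = CBF\,e^{-t/T1b}\,(1 - (t-AT)/T1b) \quad (AT \le t < AT+\tau)}
#' \deqn{dS/dt = -CBF\,e^{-t/T1b}\,\tau/T1b \quad (t \ge AT+\tau)}
#'
#' @inheritParams pwi_signal
#' @return dS/dt values, same length as `t`.
#' @export
ode_rhs <- function(t, params) {
  params <- as_perfusion_params(params)
  check_times(t)
  ds <- numeric(length(t))
  decay <- exp(-t / params$t1b)
  during <- t >= params$at & t < params$at + params$tau
  after <- t >= params$at + params$tau
  ds[during] <- params$cbf * decay[during] *
    (1 - (t[during] - params$at) / params$t1b)
  ds[after] <- -params$cbf * decay[after] * params$tau / params$t1b
  ds
}

#' Hyperbolic-tangent switch
#'
#' Smooth step \eqn{0.5\,(1 + \tanh(k x))} used to blend the branches of the
#' perfusion ODE into an infinitely differentiable surrogate. Monotonically
#' increasing; 0 as \eqn{x \to -\infty}, 1 as \eqn{x \to +\infty}, exactly
#' 0.5 at x = 0.
#'
#' @param x Offset in seconds (vectorised).
#' @param steepness Transition steepness k in 1/seconds, > 0.
#' @return Blend factors in (0, 1).
#' @export
smooth_switch <- function(x, steepness) {
  if (!is.numeric(steepness) || length(steepness) != 1L ||
      !is.finite(steepness) || steepness <= 0) {
    rlang::abort("`steepness` must be a single positive number.")
  }
  0.5 * (1 + tanh(steepness * x))
}

#' Smooth surrogate of the three-branch perfusion ODE
#'
#' Replaces the discontinuous branch switches of [ode_rhs()] with
#' tanh blends so that gradient-based training behaves well:
#' \deqn{f_k(t) = g_1 (1-g_2)\,f_{during}(t) + g_2\,f_{after}(t)}
#' with \eqn{g_1 = \sigma_k(t - AT)}, \eqn{g_2 = \sigma_k(t - AT - \tau)} and
#' \eqn{\sigma_k} the [smooth_switch()]. The before-arrival branch is
#' identically zero and needs no term. As `steepness` grows the surrogate
#' converges to [ode_rhs()] away from the branch boundaries.
#'
#' @inheritParams pwi_signal
#' @param steepness Blend steepness in 1/seconds; default 50 (transition width
#'   about 40 ms, sharp relative to the 300 ms sampling interval).
#' @return dS/dt values, same length as `t`.
#' @export
smoothed_ode_rhs <- function(t, params, steepness = 50) {
  smoothed_ode_terms(t, params, steepness)$f
}

# Value and analytic parameter-gradients of the smoothed RHS, shared by the
# training code. Returns f plus df/dCBF, df/dAT, df/dT1b (vectors over t).
smoothed_ode_terms <- function(t, params, steepness = 50) {
  params <- as_perfusion_params(params)
  check_times(t)
  k <- steepness
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    rlang::abort("`steepness` must be a single positive number.")
  }
  cbf <- params$cbf; at <- params$at; t1b <- params$t1b; tau <- params$tau
  decay <- exp(-t / t1b)
  f_dur <- cbf * decay * (1 - (t - at) / t1b)
  f_aft <- -cbf * decay * tau / t1b
  th1 <- tanh(k * (t - at)); th2 <- tanh(k * (t - at - tau))
  g1 <- 0.5 * (1 + th1); g2 <- 0.5 * (1 + th2)
  g1p <- 0.5 * k * (1 - th1^2)  # d g1 / d t = - d g1 / d AT
  g2p <- 0.5 * k * (1 - th2^2)
  f <- g1 * (1 - g2) * f_dur + g2 * f_aft

  d_dur_cbf <- f_dur / cbf
  d_aft_cbf <- f_aft / cbf
  d_dur_at <- cbf * decay / t1b
  d_dur_t1b <- cbf * decay * ((t / t1b^2) * (1 - (t - at) / t1b) +
                                (t - at) / t1b^2)
  d_aft_t1b <- -cbf * tau * decay * (t - t1b) / t1b^3

  d_cbf <- g1 * (1 - g2) * d_dur_cbf + g2 * d_aft_cbf
  d_at <- -g1p * (1 - g2) * f_dur + g1 * g2p * f_dur - g2p * f_aft +
    g1 * (1 - g2) * d_dur_at
  d_t1b <- g1 * (1 - g2) * d_dur_t1b + g2 * d_aft_t1b

  list(f = f, d_cbf = d_cbf, d_at = d_at, d_t1b = d_t1b)
}
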