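#' Network architecture specification
#'
#' The baseline PINN body: a fully connected network with hyperbolic-tangent
#' activations, two hidden layers of 32 units each, one input unit (time) and
#' one output unit (the PWI signal estimate).
#'
#' @param n_hidden_layers Number of hidden layers; this implementation
#'   supports exactly 2 (the baseline architecture).
#' @param units_per_layer Units per hidden layer (default 32).
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_hidden_layers = 2L, units_per_layer = 32L) {
  if (n_hidden_layers != 2L) {
    rlang::abort("Only the two-hidden-layer baseline architecture is supported.")
  }
  if (units_per_layer < 1L) rlang::abort("`units_per_layer` must be >= 1.")
  structure(list(n_hidden_layers = 2L,
                 units_per_layer = as.integer(units_per_layer),
                 activation = "tanh"),
            class = "network_spec")
}

#' Count of trainable network weights
#' @param spec A [network_spec()].
#' @return Integer number of weights and biases.
#' @export
network_n_params <- function(spec = network_spec()) {
  u <- spec$units_per_layer
  (1L * u + u) + (u * u + u) + (u * 1L + 1L)
}

#' Initialise network weights
#'
#' Glorot-uniform initialisation, reproducible under `seed`. The returned
#' object holds the raw weight tensors consumed by the compiled training core
#' and by [pinn_forward()].
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A `pinn_network`: list with `w1`, `b1` (first layer), `W2`, `b2`,
#'   `w3`, `b3`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  u <- spec$units_per_layer
  rng <- local_rng(seed)
  rng({
    lim1 <- sqrt(6 / (1 + u))
    lim2 <- sqrt(6 / (u + u))
    lim3 <- sqrt(6 / (u + 1))
    structure(
      list(w1 = stats::runif(u, -lim1, lim1),
           b1 = rep(0, u),
           W2 = matrix(stats::runif(u * u, -lim2, lim2), u, u),
           b2 = rep(0, u),
           w3 = stats::runif(u, -lim3, lim3),
           b3 = 0,
           spec = spec),
      class = "pinn_network")
  })
}

#' Hard initial-condition output transform
#'
#' Multiplies the raw network output by \eqn{\tanh(t/t_c)} so that
#' \eqn{\hat S(0) = 0} holds identically, for any network weights, rather
#' than being encouraged by a penalty.
#'
#' @param raw_output Raw network output at times `t`.
#' @param t Times in seconds.
#' @param t_c Time constant of the transform, seconds.
#' @return Constrained signal estimates \eqn{\hat S(t)}.
#' @export
hard_ic_transform <- function(raw_output, t, t_c) {
  tanh(t / t_c) * raw_output
}

# Raw network forward pass and (optionally) input derivative, R reference
# implementation matching the compiled path.
network_raw <- function(net, t, t_max) {
  # compiled-path tensors come back as u x 1 matrices; flatten the vectors
  net <- list(w1 = as.numeric(net$w1), b1 = as.numeric(net$b1),
              W2 = as.matrix(net$W2), b2 = as.numeric(net$b2),
              w3 = as.numeric(net$w3), b3 = as.numeric(net$b3))
  x <- t / t_max
  z1 <- outer(net$w1, x) + net$b1
  h1 <- tanh(z1)
  z2 <- net$W2 %*% h1 + net$b2
  h2 <- tanh(z2)
  n_out <- drop(crossprod(net$w3, h2)) + net$b3
  h1x <- (1 - h1^2) * net$w1
  h2x <- (1 - h2^2) * (net$W2 %*% h1x)
  nx <- drop(crossprod(net$w3, h2x)) / t_max
  list(value = n_out, deriv = nx)
}

#' Evaluate a fitted PINN's signal estimate
#'
#' Applies the network forward pass, the hard initial condition, and the
#' signal rescaling of a trained model.
#'
#' @param model A list with `net`, `t_max`, `t_c`, `s_scale` (as stored in a
#'   `pinn_fit`/`supinn_fit`), or a `pinn_network` (then `t_max`, `t_c`,
#'   `s_scale` must be given).
#' @param t Times in seconds.
#' @param t_max,t_c,s_scale Normalisation constants (only when `model` is a
#'   bare network).
#' @return A tibble with columns `time`, `value`, `deriv`.
#' @export
pinn_forward <- function(model, t, t_max = NULL, t_c = NULL, s_scale = NULL) {
  if (inherits(model, "pinn_network")) {
    model <- list(net = model, t_max = t_max, t_c = t_c,
                  s_scale = s_scale %||% 1)
  }
  raw <- network_raw(model$net, t, model$t_max)
  a <- tanh(t / model$t_c)
  adot <- (1 - a^2) / model$t_c
  tibble::tibble(
    time = t,
    value = model$s_scale * a * raw$value,
    deriv = model$s_scale * (adot * raw$value + a * raw$deriv))
}

#' ODE-residual (physics) loss
#'
#' Mean squared residual of the smoothed perfusion ODE at the collocation
#' points: \eqn{\frac{1}{N_O}\sum_i (d\hat S/dt(t_i) - f(t_i))^2}.
#'
#' @param predict Either a fitted model (as in [pinn_forward()]) or a
#'   function `t -> list(value, deriv)` supplying the signal estimate and its
#'   time derivative (e.g. an analytical solution, for verification).
#' @param params A [perfusion_params()].
#' @param colloc Collocation times, non-empty.
#' @param steepness Blend steepness of [smoothed_ode_rhs()].
#' @return Non-negative scalar loss.
#' @export
ode_loss <- function(predict, params, colloc, steepness = 50) {
  if (length(colloc) == 0L) rlang::abort("`colloc` must be non-empty.")
  pred <- if (is.function(predict)) predict(colloc) else
    pinn_forward(predict, colloc)
  f <- smoothed_ode_rhs(colloc, params, steepness)
  mean((pred$deriv - f)^2)
}

#' Data-misfit loss
#'
#' Weighted mean squared error between the signal estimate and the measured
#' series: \eqn{\frac{1}{N_D}\sum_i w(t_i)(\hat S(t_i) - S(t_i))^2}.
#'
#' @inheritParams ode_loss
#' @param data Data frame with `time`, `value` and optional `weight`
#'   (all-1 default, as in the baseline PINN).
#' @return Non-negative scalar loss.
#' @export
data_loss <- function(predict, data) {
  data <- check_series(data)
  pred <- if (is.function(predict)) predict(data$time) else
    pinn_forward(predict, data$time)
  mean(data$weight * (pred$value - data$value)^2)
}

#' Three-tier training schedule
#'
#' Tier 1 trains the network weights only, with the kinetic parameters frozen
#' (forward alignment); tiers 2 and 3 train network and parameters jointly,
#' tier 3 at a reduced learning rate (fine-tuning).
#'
#' @param iters Integer vector of three per-tier iteration counts.
#' @param lr Numeric vector of three per-tier Adam learning rates.
#' @param log_every Record the loss decomposition every this many iterations.
#' @return A `pinn_schedule` object.
#' @export
pinn_schedule <- function(iters = c(5000L, 20000L, 5000L),
                          lr = c(1e-3, 1e-3, 1e-4),
                          log_every = 100L) {
  if (length(iters) != 3L || any(iters < 0)) {
    rlang::abort("`iters` must be three non-negative integer counts.")
  }
  if (length(lr) != 3L || any(lr <= 0)) {
    rlang::abort("`lr` must be three positive learning rates.")
  }
  structure(list(iters = as.integer(iters), lr = as.numeric(lr),
                 log_every = as.integer(log_every)),
            class = "pinn_schedule")
}

#' Loss configuration for PINN training
#'
#' @param gamma Data-loss coefficient. The default 1 weights the physics and
#'   data terms equally: with times in seconds and signals normalised to unit
#'   maximum both terms are O(1), and equal weighting recovers noiseless
#'   parameters to under 1\% while retaining the physics term's noise
#'   regularisation (see the methods vignette for the calibration; the
#'   appropriate value is tied to the time/signal unit conventions).
#' @param n_collocation Number of equally spaced ODE collocation points over
#'   \[0, t_max\]; the data times are always appended.
#' @param steepness Blend steepness of the smoothed ODE, 1/seconds.
#' @return A `loss_spec` object.
#' @export
loss_spec <- function(gamma = 1, n_collocation = 100L, steepness = 50) {
  if (gamma <= 0) rlang::abort("`gamma` must be positive.")
  if (n_collocation < 1L) rlang::abort("`n_collocation` must be >= 1.")
  structure(list(gamma = gamma, n_collocation = as.integer(n_collocation),
                 steepness = steepness),
            class = "loss_spec")
}

pinn_setup <- function(data, loss) {
  t_max <- max(data$time)
  colloc <- sort(unique(c(seq(0, t_max, length.out = loss$n_collocation),
                          data$time)))
  s_scale <- max(abs(data$value), 1e-6)
  list(t_max = t_max, t_c = 0.1 * t_max, s_scale = s_scale, colloc = colloc)
}

#' Fit the baseline physics-informed neural network to one voxel
#'
#' Trains a [network_spec()] network under the combined loss
#' \eqn{L = L_{ODE} + \gamma L_{data}} with the hard initial condition and
#' the three-tier schedule. In `"inverse"` mode CBF, AT and T1b are trainable
#' from tier 2 onwards (initialised at the bound midpoints and projected onto
#' the bounds after each update); in `"forward"` mode `init_params` are held
#' fixed throughout and only the signal is learned.
#'
#' @param data Data frame with columns `time`, `value`, optional `weight`.
#' @param mode `"inverse"` (estimate parameters) or `"forward"` (solve the
#'   ODE at fixed parameters).
#' @param init_params Optional [perfusion_params()] starting values; required
#'   in forward mode.
#' @param schedule A [pinn_schedule()].
#' @param loss A [loss_spec()].
#' @param bounds Box constraints for cbf, at, t1b (as in [lsf_config()]).
#' @param network A [network_spec()].
#' @param seed Integer seed for weight initialisation.
#' @param reference_cbf Optional reference CBF; when given, the returned
#'   convergence flag additionally applies the order-of-magnitude criterion
#'   of [assess_convergence()].
#' @param tau Bolus duration in seconds.
#' @return A `pinn_fit`/`asl_fit` object: `params`, `converged`,
#'   `loss_history` tibble (`iteration`, `loss`, `loss_ode`, `loss_data`,
#'   `cbf`, `at`, `t1b`), `predicted` dense-grid tibble, and the trained
#'   `model` (network plus normalisation constants).
#' @examples
#' \donttest{
#' p <- perfusion_params(0.4, 0.5, 1.8)
#' d <- simulate_voxel(p, seq(0.3, 3.6, by = 0.3))
#' fit <- fit_pinn(d, schedule = pinn_schedule(c(500, 2000, 500)))
#' glance(fit)
#' }
#' @export
fit_pinn <- function(data, mode = c("inverse", "forward"), init_params = NULL,
                     schedule = pinn_schedule(), loss = loss_spec(),
                     bounds = lsf_config()$bounds, network = network_spec(),
                     seed = 1L, reference_cbf = NULL, tau = 0.9) {
  mode <- match.arg(mode)
  data <- check_series(data)
  if (mode == "forward" && is.null(init_params)) {
    rlang::abort("Forward mode requires `init_params`.")
  }
  setup <- pinn_setup(data, loss)
  init <- if (is.null(init_params)) {
    list(cbf = mean(bounds$cbf), at = mean(bounds$at), t1b = mean(bounds$t1b))
  } else {
    p <- as_perfusion_params(init_params)
    list(cbf = p$cbf, at = p$at, t1b = p$t1b)
  }
  net <- build_network(network, seed)

  res <- supinn_train_cpp(
    branches = list(list(net = unclass(net)[c("w1", "b1", "W2", "b2", "w3", "b3")],
                         times = data$time, values = data$value,
                         weights = data$weight)),
    colloc = setup$colloc, tau = tau, steepness = loss$steepness,
    gamma = loss$gamma, t_max = setup$t_max, t_c = setup$t_c,
    s_scale = setup$s_scale, cbf0 = init$cbf, at0 = init$at,
    t1b0 = init$t1b,
    lower = c(bounds$cbf[1], bounds$at[1], bounds$t1b[1]),
    upper = c(bounds$cbf[2], bounds$at[2], bounds$t1b[2]),
    tier_iters = schedule$iters, tier_lr = schedule$lr,
    train_params = (mode == "inverse"), log_every = schedule$log_every)

  finalize_pinn_fit(res, data, setup, mode, init, seed, reference_cbf,
                    method = "pinn", branch = 1L, tau = tau)
}

finalize_pinn_fit <- function(res, data, setup, mode, init, seed,
                              reference_cbf, method, branch, tau = 0.9) {
  est <- list(cbf = res$cbf[branch], at = res$at[branch], t1b = res$t1b,
              tau = tau)
  if (mode == "forward") est <- list(cbf = init$cbf, at = init$at,
                                     t1b = init$t1b, tau = tau)
  model <- list(net = res$nets[[branch]], t_max = setup$t_max,
                t_c = setup$t_c, s_scale = setup$s_scale)
  dense_t <- seq(0, setup$t_max, length.out = 200)
  predicted <- pinn_forward(model, dense_t)[, c("time", "value")]
  hist <- res$history
  colnames(hist) <- c("iteration", "loss", "loss_ode", "loss_data",
                      "cbf", "at", "t1b")
  converged <- !res$diverged && all(is.finite(unlist(est[c("cbf", "at", "t1b")])))
  if (!is.null(reference_cbf) && converged) {
    converged <- assess_convergence(est$cbf, reference_cbf)
  }
  new_fit_result(
    est, converged = converged, method = method, objective = res$loss,
    data = data, loss_history = tibble::as_tibble(as.data.frame(hist)),
    predicted = predicted,
    extra = list(model = model, mode = mode, seed = seed,
                 loss_ode = res$loss_ode, loss_data = res$loss_data,
                 iterations = res$iterations))
}
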