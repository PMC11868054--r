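test_that("the baseline network has the documented architecture", {
  spec <- network_spec()
  expect_identical(spec$n_hidden_layers, 2L)
  expect_identical(spec$units_per_layer, 32L)
  expect_identical(spec$activation, "tanh")
  # dense-layer count: (1*32+32) + (32*32+32) + (32*1+1)
  expect_identical(network_n_params(spec), 1153L)
  net <- build_network(spec, seed = 1)
  actual <- length(net$w1) + length(net$b1) + length(net$W2) +
    length(net$b2) + length(net$w3) + length(net$b3)
  expect_identical(actual, 1153L)
  expect_error(network_spec(n_hidden_layers = 3))
})

test_that("weight initialisation is reproducible under a seed", {
  probe <- seq(0, 3.6, length.out = 25)
  f1 <- pinn_forward(build_network(seed = 5), probe, t_max = 3.6, t_c = 0.36)
  f2 <- pinn_forward(build_network(seed = 5), probe, t_max = 3.6, t_c = 0.36)
  f3 <- pinn_forward(build_network(seed = 6), probe, t_max = 3.6, t_c = 0.36)
  expect_identical(f1$value, f2$value)
  expect_true(any(f1$value != f3$value))
})

test_that("the hard initial condition holds by construction", {
  expect_identical(hard_ic_transform(123.4, 0, t_c = 0.36), 0)
  net <- build_network(seed = 3)
  t_c <- 0.36
  f <- pinn_forward(net, c(0, 50), t_max = 3.6, t_c = t_c)
  expect_identical(f$value[1], 0)
  # far beyond t_c the transform saturates to the raw output
  raw <- supinnr:::network_raw(net, 50, 3.6)
  expect_equal(f$value[2], raw$value, tolerance = 1e-6)
  # the slope at zero is raw(0) / t_c
  raw0 <- supinnr:::network_raw(net, 0, 3.6)$value
  fdiff <- (pinn_forward(net, 1e-7, t_max = 3.6, t_c = t_c)$value) / 1e-7
  expect_equal(fdiff, raw0 / t_c, tolerance = 1e-4)
  expect_equal(f$deriv[1], raw0 / t_c, tolerance = 1e-10)
})

test_that("data loss reproduces hand-computed values and scales with w", {
  obs <- tibble::tibble(time = c(0.3, 0.6, 0.9), value = c(0.5, 0.6, 0.7),
                        weight = c(1, 0.5, 0.1))
  predict_fixed <- function(t) list(value = c(0.6, 0.8, 1.0), deriv = 0 * t)
  expect_equal(data_loss(predict_fixed, obs),
               (1 * 0.01 + 0.5 * 0.04 + 0.1 * 0.09) / 3)
  expect_identical(
    data_loss(function(t) list(value = obs$value, deriv = 0), obs), 0)
  flat <- obs
  flat$weight <- 1
  half <- obs
  half$weight <- 0.5  # halving unit weights stays within [0.1, 1]
  expect_equal(data_loss(predict_fixed, half),
               data_loss(predict_fixed, flat) / 2)
})

test_that("the ODE loss vanishes on the analytical solution", {
  p <- perfusion_params(0.4, 0.5, 1.8)
  analytic <- function(t) list(value = pwi_signal(t, p),
                               deriv = ode_rhs(t, p))
  colloc <- seq(0, 3.6, by = 0.05)
  colloc <- colloc[abs(colloc - p$at) > 0.06 &
                     abs(colloc - (p$at + p$tau)) > 0.06]
  expect_lt(ode_loss(analytic, p, colloc, steepness = 1000), 1e-8)
  expect_gte(ode_loss(analytic, p, colloc, steepness = 10), 0)
  # perturbing CBF changes the loss exactly as a direct recomputation says
  p2 <- perfusion_params(0.8, 0.5, 1.8)
  direct <- mean((ode_rhs(colloc, p) -
                    smoothed_ode_rhs(colloc, p2, 1000))^2)
  expect_equal(ode_loss(analytic, p2, colloc, steepness = 1000), direct)
  expect_error(ode_loss(analytic, p, numeric(0)), "colloc")
})

test_that("compiled and interpreted loss paths agree", {
  p <- perfusion_params(0.45, 0.55, 2.0)
  d <- make_series(p, noise_sd = 0.05, seed = 2)
  net <- build_network(seed = 9)
  colloc <- sort(unique(c(seq(0, 3.6, length.out = 40), d$time)))
  model <- list(net = net, t_max = 3.6, t_c = 0.36, s_scale = 1)
  cpp <- supinnr:::pinn_loss_grad_cpp(
    net_as_plain_list(net), d$time, d$value, d$weight, colloc,
    cbf = p$cbf, at = p$at, t1b = p$t1b, tau = p$tau, steepness = 50,
    gamma = 1, t_max = 3.6, t_c = 0.36, s_scale = 1)
  expect_equal(cpp$loss_ode, ode_loss(model, p, colloc), tolerance = 1e-12)
  expect_equal(cpp$loss_data, data_loss(model, d), tolerance = 1e-12)
})

test_that("analytic training gradients match finite differences", {
  p <- perfusion_params(0.6, 0.4, 2.0)
  d <- make_series(p, noise_sd = 0.05, seed = 3)
  net <- net_as_plain_list(build_network(seed = 7))
  colloc <- sort(unique(c(seq(0, 3.6, length.out = 30), d$time)))
  args <- list(net, d$time, d$value, d$weight, colloc, 0.6, 0.4, 2.0, 0.9,
               50, 0.005, 3.6, 0.36, 0.3)
  ref <- do.call(supinnr:::pinn_loss_grad_cpp, args)
  loss_at <- function(a) do.call(supinnr:::pinn_loss_grad_cpp, a)$loss
  h <- 1e-6
  set.seed(1)
  for (field in c("w1", "b1", "W2", "b2", "w3", "b3")) {
    idx <- sample(length(net[[field]]), min(5, length(net[[field]])))
    for (k in idx) {
      a1 <- args; a1[[1]][[field]][k] <- a1[[1]][[field]][k] + h
      a2 <- args; a2[[1]][[field]][k] <- a2[[1]][[field]][k] - h
      fd <- (loss_at(a1) - loss_at(a2)) / (2 * h)
      expect_equal(as.numeric(ref$grad_net[[field]])[k], fd,
                   tolerance = 1e-4)
    }
  }
  for (slot in 6:8) {  # cbf, at, t1b
    a1 <- args; a1[[slot]] <- args[[slot]] + h
    a2 <- args; a2[[slot]] <- args[[slot]] - h
    fd <- (loss_at(a1) - loss_at(a2)) / (2 * h)
    ana <- switch(slot - 5, ref$grad_cbf, ref$grad_at, ref$grad_t1b)
    expect_equal(ana, fd, tolerance = 1e-5)
  }
})

test_that("the logged loss decomposes exactly and tiers are isolated", {
  d <- make_series(noise_sd = 0.02, seed = 4)
  sched <- pinn_schedule(c(100L, 100L, 100L), log_every = 10L)
  fit <- fit_pinn(d, schedule = sched, seed = 1)
  h <- fit$loss_history
  expect_true(all(abs(h$loss - (h$loss_ode + 1 * h$loss_data)) < 1e-10))
  # tier 1 trains network weights only: parameters bit-unchanged
  tier1 <- h[h$iteration <= 100, ]
  expect_identical(unique(tier1$cbf), tier1$cbf[1])
  expect_identical(unique(tier1$at), tier1$at[1])
  expect_identical(unique(tier1$t1b), tier1$t1b[1])
  # and they start at the bound midpoints
  expect_equal(tier1$cbf[1], mean(c(1e-3, 2)))
})

test_that("training is deterministic under a fixed seed", {
  d <- make_series(noise_sd = 0.05, seed = 8)
  f1 <- fit_pinn(d, schedule = smoke_schedule(), seed = 3)
  f2 <- fit_pinn(d, schedule = smoke_schedule(), seed = 3)
  f3 <- fit_pinn(d, schedule = smoke_schedule(), seed = 4)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
  expect_false(identical(f1$params, f3$params))
  # the hard IC survives training
  expect_identical(pinn_forward(f1$model, 0)$value, 0)
})

test_that("forward mode holds parameters fixed and fits the signal", {
  p <- perfusion_params(0.4, 0.5, 1.8)
  d <- make_series(p)
  fit <- fit_pinn(d, mode = "forward", init_params = p,
                  schedule = pinn_schedule(c(1000L, 2000L, 1000L)), seed = 2)
  expect_identical(fit$params$cbf, 0.4)
  truth <- pwi_signal(fit$predicted$time, p)
  expect_lt(signal_mse(fit$predicted$value, truth), 1e-3)
  expect_error(fit_pinn(d, mode = "forward"), "init_params")
})

test_that("inverse mode recovers noiseless parameters", {
  p <- perfusion_params(0.35, 0.45, 1.8)
  d <- make_series(p)
  fit <- fit_pinn(d, schedule = reduced_schedule(), seed = 2,
                  reference_cbf = p$cbf)
  expect_true(fit$converged)
  expect_lt(abs(relative_error(fit$params$cbf, p$cbf)), 15)
  expect_lt(abs(relative_error(fit$params$at, p$at)), 15)
})
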