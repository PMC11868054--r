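test_that("pwi_signal evaluates all three branches correctly", {
  p <- ref_params()  # cbf 1, at 0.6, t1b 1.6, tau 0.9
  expect_identical(pwi_signal(0.2, p), 0)          # before arrival
  expect_identical(pwi_signal(0.6, p), 0)          # continuous at t = AT
  expect_equal(pwi_signal(1.0, p), 1.0 * 0.4 * exp(-1.0 / 1.6))
  expect_equal(pwi_signal(2.0, p), 1.0 * 0.9 * exp(-2.0 / 1.6))
})

test_that("pwi_signal is vectorised and agrees with scalar calls", {
  p <- perfusion_params(0.37, 0.42, 2.1)
  ts <- seq(0, 3.6, by = 0.17)
  vec <- pwi_signal(ts, p)
  expect_equal(vec, vapply(ts, pwi_signal, numeric(1), params = p))
})

test_that("parameter and argument validation raises errors", {
  expect_error(perfusion_params(-1, 0.5, 1.8), "cbf")
  expect_error(perfusion_params(1, -0.1, 1.8), "at")
  expect_error(perfusion_params(1, 0.5, 0), "t1b")
  expect_error(perfusion_params(1, 0.5, 1.8, tau = -1), "tau")
  expect_error(pwi_signal(NaN, ref_params()))
  expect_error(pwi_signal(-0.1, ref_params()))
  expect_error(smooth_switch(1, steepness = 0), "steepness")
  expect_error(smoothed_ode_rhs(1, ref_params(), steepness = -5), "steepness")
})

test_that("pwi_signal is continuous at both branch boundaries", {
  for (p in list(ref_params(), perfusion_params(0.3, 0.35, 2.2))) {
    eps <- 1e-10
    for (tb in c(p$at, p$at + p$tau)) {
      left <- pwi_signal(max(tb - eps, 0), p)
      right <- pwi_signal(tb + eps, p)
      expect_lt(abs(left - right), 1e-9)
    }
  }
})

test_that("signal has a single maximum in (AT, AT+tau] then decays", {
  p <- perfusion_params(0.5, 0.4, 1.7)
  ts <- seq(0, 3.6, by = 0.001)
  s <- pwi_signal(ts, p)
  t_peak <- ts[which.max(s)]
  expect_gt(t_peak, p$at)
  expect_lte(t_peak, p$at + p$tau + 1e-9)
  post <- s[ts >= p$at + p$tau]
  expect_true(all(diff(post) < 0))
})

test_that("ode_rhs matches a finite difference of the signal", {
  p <- ref_params()
  expect_identical(ode_rhs(0.2, p), 0)
  for (t0 in c(1.0, 2.0)) {
    fd <- fd_central(function(t) pwi_signal(t, p), t0)
    expect_lt(abs(ode_rhs(t0, p) - fd), 1e-6)
  }
  expect_lt(ode_rhs(2.0, p), 0)  # post-bolus decay is strictly negative

  # property: 200 random draws away from the breakpoints
  set.seed(42)
  for (k in 1:200) {
    p <- perfusion_params(runif(1, 0.1, 1), runif(1, 0.1, 0.8),
                          runif(1, 1, 3))
    repeat {
      t0 <- runif(1, 0.02, 3.6)
      if (min(abs(t0 - c(p$at, p$at + p$tau))) > 1e-3) break
    }
    fd <- fd_central(function(t) pwi_signal(t, p), t0)
    expect_lt(abs(ode_rhs(t0, p) - fd), 1e-5)
  }
})

test_that("smooth_switch is a symmetric saturating step", {
  expect_identical(smooth_switch(0, 7), 0.5)
  expect_equal(smooth_switch(10, 100), 1, tolerance = 1e-15)
  xs <- seq(-2, 2, by = 0.1)
  expect_equal(smooth_switch(-xs, 3) + smooth_switch(xs, 3),
               rep(1, length(xs)))
  expect_true(all(diff(smooth_switch(xs, 5)) > 0))
})

test_that("smoothed ODE agrees with the branch ODE away from breakpoints", {
  p <- ref_params()
  t_mid <- p$at + p$tau / 2
  expect_lt(abs(smoothed_ode_rhs(t_mid, p, steepness = 1000) -
                  ode_rhs(t_mid, p)), 1e-6)
  # switch value one half at its centre: only the during-branch term remains
  f_dur <- p$cbf * exp(-p$at / p$t1b)  # (1 - 0/t1b) = 1 at t = AT
  expect_equal(smoothed_ode_rhs(p$at, p, steepness = 1e4), 0.5 * f_dur,
               tolerance = 1e-6)
})

test_that("smoothing gap shrinks monotonically with steepness", {
  p <- ref_params()
  ts <- seq(0, 3.6, by = 0.002)
  keep <- abs(ts - p$at) > 0.05 & abs(ts - (p$at + p$tau)) > 0.05
  gaps <- vapply(c(10, 100, 1000), function(k) {
    max(abs(smoothed_ode_rhs(ts[keep], p, k) - ode_rhs(ts[keep], p)))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("analytic parameter gradients of the smoothed RHS are exact", {
  p <- perfusion_params(0.45, 0.52, 1.9)
  ts <- c(0.3, 0.7, 1.1, 2.5)
  terms <- supinnr:::smoothed_ode_terms(ts, p, steepness = 50)
  for (field in c("cbf", "at", "t1b")) {
    fd <- fd_central(function(v) {
      q <- p; q[[field]] <- v
      smoothed_ode_rhs(ts, q, steepness = 50)
    }, p[[field]])
    expect_equal(terms[[paste0("d_", field)]], fd, tolerance = 1e-6)
  }
})
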