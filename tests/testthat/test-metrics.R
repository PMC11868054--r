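test_that("relative error is the signed percentage deviation", {
  expect_identical(relative_error(1, 1), 0)
  expect_identical(relative_error(2, 1), 100)
  expect_equal(relative_error(0.997, 1), -0.3)
  expect_equal(relative_error(c(1.1, 0.9), c(1, 1)), c(10, -10))
  expect_warning(out <- relative_error(c(1, 2), c(1, 0)), "zero")
  expect_identical(out[2], NA_real_)
})

test_that("convergence is an order-of-magnitude criterion on CBF", {
  expect_true(assess_convergence(1, 1))
  expect_false(assess_convergence(10.01, 1))
  expect_true(assess_convergence(0.11, 1))
  expect_true(assess_convergence(10, 1))   # exactly one order of magnitude
  expect_true(assess_convergence(0.1, 1))
  expect_false(assess_convergence(0.099, 1))
  expect_false(assess_convergence(NaN, 1))
  expect_false(assess_convergence(Inf, 1))
  expect_error(assess_convergence(1, 0), "reference_cbf")
})

test_that("convergence rate is |total - failed| / total x 100", {
  expect_identical(convergence_rate(rep(TRUE, 4)), 100)
  expect_identical(convergence_rate(c(TRUE, TRUE, TRUE, FALSE)), 75)
  expect_identical(convergence_rate(rep(FALSE, 10)), 0)
  expect_error(convergence_rate(logical(0)), "non-empty")
})

test_that("Laplacian variance annihilates constant and affine maps", {
  expect_identical(laplacian_variance(matrix(3.7, 5, 5)), 0)
  ramp <- outer(1:6, 1:5, function(i, j) 2 * i - 3 * j + 1)
  expect_identical(laplacian_variance(ramp), 0)
})

test_that("Laplacian variance matches a brute-force stencil evaluation", {
  # centre spike on 3x3: one interior voxel, Laplacian -4, variance 0
  spike <- matrix(0, 3, 3); spike[2, 2] <- 1
  expect_identical(laplacian_variance(spike), 0)

  set.seed(9)
  m <- matrix(stats::rnorm(42), 6, 7)
  roi <- matrix(stats::runif(42) > 0.2, 6, 7)
  brute <- c()
  for (i in 2:5) {
    for (j in 2:6) {
      if (roi[i, j] && roi[i - 1, j] && roi[i + 1, j] &&
          roi[i, j - 1] && roi[i, j + 1]) {
        brute <- c(brute, m[i - 1, j] + m[i + 1, j] + m[i, j - 1] +
                     m[i, j + 1] - 4 * m[i, j])
      }
    }
  }
  expect_equal(laplacian_variance(m, roi),
               mean((brute - mean(brute))^2), tolerance = 1e-12)
  expect_error(laplacian_variance(m, roi = matrix(FALSE, 6, 7)))
  expect_error(laplacian_variance(matrix(1, 2, 2)), "small")
})

test_that("signal MSE is the mean squared difference", {
  expect_identical(signal_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(signal_mse(c(0.1, -0.1), c(0, 0)), 0.01)
  expect_equal(signal_mse(c(1, 2, 4), c(0.5, 2.5, 3)),
               (0.25 + 0.25 + 1) / 3)
  expect_error(signal_mse(1:3, 1:4), "equal length")
})

test_that("evaluation reports aggregate the per-voxel table exactly", {
  g <- generate_grid(sim_config(seed = 6))
  roi_idx <- which(g$roi, arr.ind = TRUE)
  set.seed(3)
  fits <- tibble::tibble(
    row = roi_idx[, 1], col = roi_idx[, 2],
    cbf = g$truth$cbf_map[roi_idx] * exp(stats::rnorm(nrow(roi_idx), 0, 0.1)),
    at = g$truth$at_map[roi_idx] * exp(stats::rnorm(nrow(roi_idx), 0, 0.1)),
    t1b = 1.8, converged = TRUE,
    mse = stats::runif(nrow(roi_idx), 0, 0.01))
  fits$converged[1:3] <- FALSE
  ev <- evaluate_fits(fits, g)
  vox <- tidy(ev)
  s <- glance(ev)
  keep <- vox$converged
  expect_equal(s$re_cbf_mean, mean(vox$re_cbf[keep]), tolerance = 1e-12)
  expect_equal(s$re_cbf_sd, stats::sd(vox$re_cbf[keep]), tolerance = 1e-12)
  expect_equal(s$re_at_mean_abs, mean(abs(vox$re_at[keep])), tolerance = 1e-12)
  expect_equal(s$mse_mean, mean(vox$mse[keep]), tolerance = 1e-12)
  expect_equal(s$convergence_rate, convergence_rate(vox$converged))
  # a perfect prediction scores zero error and the truth map's smoothness
  perfect <- fits
  perfect$cbf <- g$truth$cbf_map[roi_idx]
  perfect$at <- g$truth$at_map[roi_idx]
  perfect$converged <- TRUE
  ev0 <- evaluate_fits(perfect, g)
  expect_equal(glance(ev0)$re_cbf_mean, 0)
  expect_equal(glance(ev0)$lapvar_cbf,
               laplacian_variance(g$truth$cbf_map * ifelse(g$roi, 1, NA),
                                  g$roi))
})
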