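test_that("spatial weights reproduce the hand-computed neighbourhood example", {
  # centre voxel of a 3x3 grid: neighbours at t1 take {0,0,0,0,1,1,1,1},
  # at t2 all 0.5 -> population sd 0.5 and 0 -> weights 0.1 and 1
  vals <- array(0, dim = c(3, 3, 2))
  neigh <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1),
                 c(3, 2), c(3, 3))
  vals[cbind(neigh[, 1], neigh[, 2], 1)] <- c(0, 0, 0, 0, 1, 1, 1, 1)
  vals[cbind(neigh[, 1], neigh[, 2], 2)] <- 0.5
  g <- manual_grid(vals)
  w <- spatial_weights(g)
  expect_equal(w$sigma[2, 2, ], c(0.5, 0))
  expect_equal(w$weight[2, 2, ], c(0.1, 1))
})

test_that("uniform neighbourhood uncertainty maps to weight one", {
  vals <- array(rep(c(0.2, 0.4, 0.1), each = 9), dim = c(3, 3, 3))
  w <- spatial_weights(manual_grid(vals))
  expect_true(all(w$weight[2, 2, ] == 1))
})

test_that("weights stay within [0.1, 1] on generated grids", {
  g <- generate_grid(sim_config(noise_sd = 0.2, seed = 5))
  w <- spatial_weights(g)
  inroi <- w$weight[rep(g$roi, length(g$times))]
  expect_true(all(inroi >= 0.1 & inroi <= 1))
  expect_true(all(is.na(w$weight[rep(!g$roi, length(g$times))])))
  # within each voxel the extremes are attained
  i <- which(g$roi, arr.ind = TRUE)[1, ]
  expect_equal(min(w$weight[i[1], i[2], ]), 0.1)
  expect_equal(max(w$weight[i[1], i[2], ]), 1)
  # monotone: larger sigma never gets a larger weight
  ord <- order(w$sigma[i[1], i[2], ])
  expect_true(all(diff(w$weight[i[1], i[2], ][ord]) <= 1e-12))
})

test_that("a voxel with no in-ROI neighbours falls back to weight one", {
  vals <- array(stats::rnorm(3 * 5 * 2), dim = c(3, 5, 2))
  roi <- matrix(FALSE, 3, 5)
  roi[1, 1] <- TRUE
  roi[3, 5] <- TRUE  # two isolated ROI voxels
  expect_warning(w <- spatial_weights(manual_grid(vals, roi = roi)),
                 "no in-ROI neighbour")
  expect_true(all(w$weight[1, 1, ] == 1))
})

test_that("companion voxels are drawn uniformly from the ROI", {
  g <- generate_grid(sim_config(shape = c(7, 7), roi_margin = 2L, seed = 3))
  expect_identical(sum(g$roi), 9L)  # 3x3 interior... enlarge below
  g <- generate_grid(sim_config(shape = c(12, 12), roi_margin = 1L, seed = 3))
  roi_idx <- which(g$roi, arr.ind = TRUE)
  target <- unname(c(roi_idx[1, 1], roi_idx[1, 2]))

  one <- select_branch_voxels(g, target, n_branches = 1L, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$row, one$col), target)

  s1 <- select_branch_voxels(g, target, seed = 42)
  s2 <- select_branch_voxels(g, target, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(g$roi[cbind(s1$row, s1$col)]))
  expect_identical(anyDuplicated(s1[, c("row", "col")]), 0L)
})

test_that("selection frequencies match the uniform law on a 10-voxel ROI", {
  vals <- array(stats::rnorm(4 * 5 * 2), dim = c(4, 5, 2))
  roi <- matrix(FALSE, 4, 5)
  roi[cbind(rep(1:2, 5), rep(1:5, each = 2))] <- TRUE  # 10 ROI voxels
  g <- manual_grid(vals, roi = roi)
  target <- c(1, 1)
  counts <- integer(20)
  for (k in 1:1000) {
    s <- select_branch_voxels(g, target, n_branches = 3L, seed = k)
    picked <- (s$col[-1] - 1) * 4 + s$row[-1]
    counts[picked] <- counts[picked] + 1L
  }
  eligible <- which(roi & !(row(roi) == 1 & col(roi) == 1))
  freq <- counts[eligible] / 1000
  expect_true(all(abs(freq - 2 / 9) <= 0.05))
  expect_error(select_branch_voxels(g, c(3, 1)), "in-ROI")
  tiny_roi <- matrix(FALSE, 4, 5); tiny_roi[1, 1:2] <- TRUE
  expect_error(select_branch_voxels(manual_grid(vals, roi = tiny_roi),
                                    c(1, 1), n_branches = 3L), "smaller")
})

test_that("identical-branch fits agree across branches and recover truth", {
  # a constant-parameter noiseless grid: every branch sees the same curve
  p <- perfusion_params(0.4, 0.5, 1.8)
  vals <- array(rep(pwi_signal(default_times(), p), each = 25),
                dim = c(5, 5, 12))
  g <- manual_grid(vals, times = default_times())
  fit <- fit_supinn(g, target = c(3, 3), schedule = reduced_schedule(),
                    seed = 1)
  expect_lt(abs(relative_error(fit$params$cbf, p$cbf)), 5)
  expect_lt(abs(relative_error(fit$params$at, p$at)), 5)
  # branch-local CBF/AT agree since the data are identical
  expect_lt(diff(range(fit$branches$cbf)) / mean(fit$branches$cbf), 0.02)
  # the shared T1b is a single trainable: bit-identical across branches
  expect_identical(length(unique(fit$branches$t1b)), 1L)
  expect_identical(fit$branches$t1b[1], fit$params$t1b)
})

test_that("SUPINN's error spread grows more slowly with noise than LSF's", {
  sd_re <- function(ns) {
    grid <- generate_grid(sim_config(noise_sd = ns, seed = 7))
    roi <- which(grid$roi, arr.ind = TRUE)
    set.seed(2)
    pick <- roi[sample(nrow(roi), 6), ]
    tc <- grid$truth$cbf_map[pick]
    lsf <- fit_grid(grid, "lsf", voxels = pick,
                    config = lsf_config(fit_t1b = TRUE), seed = 1)
    sup <- fit_grid(grid, "supinn", voxels = pick,
                    schedule = reduced_schedule(), seed = 1)
    c(lsf = stats::sd(relative_error(lsf$cbf, tc)),
      sup = stats::sd(relative_error(sup$cbf, tc)))
  }
  lo <- sd_re(0.1)
  hi <- sd_re(0.5)
  expect_lt(hi[["sup"]] - lo[["sup"]], hi[["lsf"]] - lo[["lsf"]])
})

test_that("SUPINN maps are spatially smoother than voxel-wise PINN maps", {
  block <- as.matrix(expand.grid(row = 5:8, col = 5:8))
  for (seed in c(11, 21, 31)) {
    grid <- generate_grid(sim_config(noise_sd = 0.1, seed = seed))
    pin <- fit_grid(grid, "pinn", voxels = block,
                    schedule = reduced_schedule(), seed = 1)
    sup <- fit_grid(grid, "supinn", voxels = block,
                    schedule = reduced_schedule(), seed = 1)
    roi <- matrix(FALSE, 12, 12); roi[block] <- TRUE
    lap <- function(f) {
      m <- matrix(NA_real_, 12, 12); m[block] <- f$cbf
      laplacian_variance(m, roi)
    }
    expect_lte(lap(sup), lap(pin))
  }
})
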