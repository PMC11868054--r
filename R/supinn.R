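#' Spatial-uncertainty data weights
#'
#' For every in-ROI voxel and time point, computes the neighbourhood
#' variability of the PWI signal — the population standard deviation over the
#' up-to-8 in-plane immediate neighbours that lie inside the ROI — and turns
#' it into a data-confidence weight. Within each voxel the weights are
#' affinely rescaled across time so the highest-uncertainty time point gets
#' weight 0.1 and the lowest gets 1:
#' \deqn{w(t) = 1 - 0.9\,\frac{\sigma(t)-\sigma_{min}}{\sigma_{max}-\sigma_{min}}.}
#' Voxels whose neighbourhood uncertainties are all equal (including all
#' zero) get weight 1 everywhere; a voxel with no in-ROI neighbour gets
#' weight 1 everywhere with a warning. The standard-deviation divisor is the
#' actual in-ROI neighbour count, so ROI-edge voxels are not biased by the
#' nominal neighbourhood size.
#'
#' @param grid A `voxel_grid`.
#' @return A list of class `uncertainty_weights` with arrays `sigma` and
#'   `weight` (rows x cols x time; `NA` outside the ROI).
#' @export
spatial_weights <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (sum(grid$roi) < 1L) rlang::abort("ROI is empty.")
  nr <- grid$shape[1]; nc <- grid$shape[2]; nt <- length(grid$times)
  sigma <- array(NA_real_, dim = c(nr, nc, nt))
  weight <- array(NA_real_, dim = c(nr, nc, nt))
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  orphan <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!grid$roi[i, j]) next
      rr <- i + offsets$dr
      cc <- j + offsets$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      inroi <- grid$roi[cbind(rr, cc)]
      rr <- rr[inroi]; cc <- cc[inroi]
      if (length(rr) == 0L) {
        orphan <- orphan + 1L
        weight[i, j, ] <- 1
        sigma[i, j, ] <- 0
        next
      }
      neigh <- matrix(grid$values[cbind(rep(rr, nt), rep(cc, nt),
                                        rep(seq_len(nt), each = length(rr)))],
                      nrow = length(rr))
      mu <- colMeans(neigh)
      s <- sqrt(colMeans(sweep(neigh, 2, mu)^2))
      sigma[i, j, ] <- s
      rng <- max(s) - min(s)
      weight[i, j, ] <- if (rng < .Machine$double.eps) {
        rep(1, nt)
      } else {
        # clamp: 1 - 0.9 is not exactly 0.1 in floating point
        pmin(pmax(1 - 0.9 * (s - min(s)) / rng, 0.1), 1)
      }
    }
  }
  if (orphan > 0L) {
    rlang::warn(sprintf(
      "spatial_weights: %d ROI voxel(s) had no in-ROI neighbour; weights set to 1.",
      orphan))
  }
  structure(list(sigma = sigma, weight = weight), class = "uncertainty_weights")
}

#' Randomly select companion voxels for a multi-branch fit
#'
#' The target voxel occupies the first branch; the remaining branches are
#' filled with distinct voxels drawn uniformly at random from the whole ROI
#' (excluding the target), reproducibly under `seed`.
#'
#' @param grid A `voxel_grid`.
#' @param target Length-2 integer vector (row, col) inside the ROI.
#' @param n_branches Total number of branches (target included); default 3.
#' @param seed Integer seed.
#' @return A tibble with columns `branch`, `row`, `col`; row 1 is the target.
#' @export
select_branch_voxels <- function(grid, target, n_branches = 3L, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  target <- as.integer(target)
  if (length(target) != 2L || !grid$roi[target[1], target[2]]) {
    rlang::abort("`target` must be an in-ROI (row, col) pair.")
  }
  roi_idx <- which(grid$roi, arr.ind = TRUE)
  if (nrow(roi_idx) < n_branches) {
    rlang::abort("ROI smaller than the number of branches.")
  }
  is_target <- roi_idx[, 1] == target[1] & roi_idx[, 2] == target[2]
  pool <- roi_idx[!is_target, , drop = FALSE]
  picks <- if (n_branches > 1L) {
    rng <- local_rng(seed)
    rng(sample.int(nrow(pool), n_branches - 1L))
  } else {
    integer(0)
  }
  tibble::tibble(
    branch = seq_len(n_branches),
    row = c(target[1], pool[picks, 1]),
    col = c(target[2], pool[picks, 2]))
}

#' Fit SUPINN: a multi-branch spatially uncertainty-weighted PINN
#'
#' Builds one network branch per selected voxel (the target plus randomly
#' chosen companions), each with its own trainable CBF and AT, while a single
#' T1b trainable is shared by all branches — pooling information across
#' voxels for the global parameter. Each branch's data loss is weighted by
#' the voxel's spatial-uncertainty weights ([spatial_weights()]), and the
#' total loss is the sum over branches of \eqn{L_{ODE} + \gamma L_{data}},
#' trained under the three-tier schedule.
#'
#' @param grid A `voxel_grid`.
#' @param target Length-2 (row, col) of the voxel of interest.
#' @param n_branches Number of branches (default 3: target + 2 companions, an
#'   empirically good balance of accuracy and cost).
#' @param weights Optional precomputed [spatial_weights()]; computed from the
#'   grid when omitted.
#' @inheritParams fit_pinn
#' @param selection_seed Seed for the companion-voxel draw; defaults to
#'   `seed`.
#' @return A `supinn_fit`/`asl_fit`: target-voxel `params` (with the shared
#'   `t1b`), `branches` tibble (per-branch voxel and estimates), `converged`,
#'   `loss_history`, `predicted`, and the target branch `model`.
#' @export
fit_supinn <- function(grid, target, n_branches = 3L, weights = NULL,
                       schedule = pinn_schedule(), loss = loss_spec(),
                       bounds = lsf_config()$bounds, network = network_spec(),
                       seed = 1L, selection_seed = NULL,
                       reference_cbf = NULL, tau = 0.9) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(weights)) weights <- spatial_weights(grid)
  selection <- select_branch_voxels(grid, target, n_branches,
                                    seed = selection_seed %||% seed)
  series <- lapply(seq_len(n_branches), function(b) {
    grid_series(grid, selection$row[b], selection$col[b],
                weights = weights$weight[selection$row[b], selection$col[b], ])
  })
  setup <- pinn_setup_multi(series, loss)
  init <- list(cbf = mean(bounds$cbf), at = mean(bounds$at),
               t1b = mean(bounds$t1b))
  branches <- lapply(seq_len(n_branches), function(b) {
    net <- build_network(network, seed = voxel_subseed(seed, b))
    list(net = unclass(net)[c("w1", "b1", "W2", "b2", "w3", "b3")],
         times = series[[b]]$time, values = series[[b]]$value,
         weights = series[[b]]$weight)
  })

  res <- supinn_train_cpp(
    branches = branches, colloc = setup$colloc, tau = tau,
    steepness = loss$steepness, gamma = loss$gamma, t_max = setup$t_max,
    t_c = setup$t_c, s_scale = setup$s_scale,
    cbf0 = rep(init$cbf, n_branches), at0 = rep(init$at, n_branches),
    t1b0 = init$t1b,
    lower = c(bounds$cbf[1], bounds$at[1], bounds$t1b[1]),
    upper = c(bounds$cbf[2], bounds$at[2], bounds$t1b[2]),
    tier_iters = schedule$iters, tier_lr = schedule$lr,
    train_params = TRUE, log_every = schedule$log_every)

  fit <- finalize_pinn_fit(res, series[[1]], setup, mode = "inverse",
                           init = init, seed = seed,
                           reference_cbf = reference_cbf,
                           method = "supinn", branch = 1L, tau = tau)
  fit$branches <- dplyr::mutate(selection, cbf = res$cbf, at = res$at,
                                t1b = res$t1b)
  fit$selection <- selection
  fit
}

pinn_setup_multi <- function(series, loss) {
  t_max <- max(vapply(series, function(s) max(s$time), numeric(1)))
  colloc <- sort(unique(c(seq(0, t_max, length.out = loss$n_collocation),
                          unlist(lapply(series, function(s) s$time)))))
  s_scale <- max(vapply(series, function(s) max(abs(s$value)), numeric(1)),
                 1e-6)
  list(t_max = t_max, t_c = 0.1 * t_max, s_scale = s_scale, colloc = colloc)
}

#' Fit every ROI voxel of a grid with one method
#'
#' Convenience driver iterating a voxel-wise estimator over the ROI and
#' collecting the per-voxel estimates into a tidy table; the input to map
#' reconstruction and [evaluate_fits()].
#'
#' @param grid A `voxel_grid`.
#' @param method One of `"lsf"`, `"lsf_multi"`, `"pinn"`, `"supinn"`.
#' @param t1b Fixed T1b for the LSF methods (defaults to the grid truth when
#'   available).
#' @param config An [lsf_config()] for the LSF methods.
#' @param schedule,loss,bounds,network Passed to the PINN methods.
#' @param seed Base seed; per-voxel seeds are derived deterministically.
#' @param voxels Optional two-column matrix/data frame of (row, col) indices
#'   to fit; defaults to every ROI voxel.
#' @param use_reference Use the grid's true CBF map for the
#'   order-of-magnitude convergence flag (when truth is present).
#' @return A tibble with one row per voxel: `row`, `col`, `cbf`, `at`,
#'   `t1b`, `converged`, `objective`, `mse` (signal MSE of the fit's
#'   prediction against the voxel's observed series at the data times).
#' @export
fit_grid <- function(grid, method = c("lsf", "lsf_multi", "pinn", "supinn"),
                     t1b = NULL, config = lsf_config(),
                     schedule = pinn_schedule(), loss = loss_spec(),
                     bounds = lsf_config()$bounds, network = network_spec(),
                     seed = 1L, voxels = NULL, use_reference = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(voxels)) {
    voxels <- which(grid$roi, arr.ind = TRUE)
  } else {
    voxels <- as.matrix(voxels)
  }
  if (is.null(t1b) && !is.null(grid$truth)) t1b <- grid$truth$t1b
  weights <- if (method == "supinn") spatial_weights(grid) else NULL
  roi_idx <- which(grid$roi, arr.ind = TRUE)

  rows <- lapply(seq_len(nrow(voxels)), function(k) {
    i <- voxels[k, 1]; j <- voxels[k, 2]
    vseed <- voxel_subseed(seed, (j - 1L) * grid$shape[1] + i)
    ref <- if (use_reference && !is.null(grid$truth)) {
      grid$truth$cbf_map[i, j]
    } else NULL
    series <- grid_series(grid, i, j)
    fit <- switch(
      method,
      lsf = fit_lsf(series, config = config, t1b = t1b),
      lsf_multi = {
        sel <- select_branch_voxels(grid, c(i, j), 3L, seed = vseed)
        fit_lsf_multi(lapply(seq_len(3L), function(b) {
          grid_series(grid, sel$row[b], sel$col[b])
        }), config = config, t1b = t1b)
      },
      pinn = fit_pinn(series, schedule = schedule, loss = loss,
                      bounds = bounds, network = network, seed = vseed,
                      reference_cbf = ref),
      supinn = fit_supinn(grid, c(i, j), weights = weights,
                          schedule = schedule, loss = loss, bounds = bounds,
                          network = network, seed = vseed,
                          reference_cbf = ref))
    conv <- fit$converged
    if (!is.null(ref) && conv && is.finite(fit$params$cbf)) {
      conv <- assess_convergence(fit$params$cbf, ref)
    }
    pred <- if (is.finite(fit$params$cbf)) {
      pwi_signal(series$time, fit$params)
    } else rep(NA_real_, nrow(series))
    tibble::tibble(
      row = i, col = j, cbf = fit$params$cbf, at = fit$params$at,
      t1b = fit$params$t1b, converged = conv,
      objective = fit$objective %||% NA_real_,
      mse = signal_mse(pred, series$value))
  })
  dplyr::bind_rows(rows)
}
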