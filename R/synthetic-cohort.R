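#' Simulation configuration for a synthetic single-slice PWI dataset
#'
#' Describes one synthetic acquisition: grid geometry, the ranges and
#' smoothness of the spatial CBF and AT fields, the subject-level T1b, the
#' sampling grid, and the additive white-Gaussian-noise level.
#'
#' The defaults emulate a pulsed-labelling infant acquisition: 12 time points
#' every 300 ms on a single slice, CBF spanning the normalised range reported
#' across the youngest to oldest subjects (0.12 to 0.56), AT spanning 0.32 to
#' 0.49 s, and a physiologically motivated global T1b of 1.8 s.
#'
#' @param shape Integer vector (rows, cols); both >= 3 so the spatial
#'   neighbourhood weighting has interior voxels.
#' @param cbf_range,at_range Length-2 ascending ranges of the smooth fields.
#' @param t1b Global (subject-level) blood T1 in seconds.
#' @param noise_sd Standard deviation of the additive white Gaussian noise,
#'   expressed as a fraction of the grid's peak noiseless signal; >= 0. A
#'   noise sweep from 0.1 to 0.5 thus spans mild (10\% of peak) to severe
#'   (50\% of peak) corruption regardless of the normalised-CBF scale. (At
#'   the single-voxel level, [simulate_voxel()] takes an absolute standard
#'   deviation instead.)
#' @param n_timepoints Number of post-labelling samples, >= 2.
#' @param dt Sampling interval in seconds.
#' @param t0 First sample time in seconds.
#' @param smoothness Gaussian length-scale of the random fields, in voxels.
#' @param roi_margin Width of the excluded border; the ROI is the interior.
#' @param tau Bolus duration in seconds.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(shape = c(12L, 12L),
                       cbf_range = c(0.12, 0.56),
                       at_range = c(0.32, 0.49),
                       t1b = 1.8,
                       noise_sd = 0,
                       n_timepoints = 12L,
                       dt = 0.3,
                       t0 = 0.3,
                       smoothness = 2,
                       roi_margin = 1L,
                       tau = 0.9,
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 3L)) {
    rlang::abort("`shape` must be two integers, each >= 3.")
  }
  if (length(cbf_range) != 2L || any(cbf_range <= 0) || diff(cbf_range) < 0) {
    rlang::abort("`cbf_range` must be positive and ascending.")
  }
  if (length(at_range) != 2L || any(at_range < 0) || diff(at_range) < 0) {
    rlang::abort("`at_range` must be non-negative and ascending.")
  }
  if (t1b <= 0) rlang::abort("`t1b` must be positive.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  if (n_timepoints < 2L) rlang::abort("`n_timepoints` must be >= 2.")
  if (dt <= 0) rlang::abort("`dt` must be positive.")
  if (t0 < 0) rlang::abort("`t0` must be non-negative.")
  if (smoothness <= 0) rlang::abort("`smoothness` must be positive.")
  structure(
    list(shape = shape, cbf_range = cbf_range, at_range = at_range,
         t1b = t1b, noise_sd = noise_sd,
         n_timepoints = as.integer(n_timepoints), dt = dt, t0 = t0,
         smoothness = smoothness, roi_margin = as.integer(roi_margin),
         tau = tau, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %dx%d grid, %d time points (t0 = %.2g s, dt = %.2g s)\n",
           "  CBF in [%.3g, %.3g], AT in [%.3g, %.3g] s, T1b = %.3g s\n",
           "  noise sd = %.3g, seed = %d\n"),
    x$shape[1], x$shape[2], x$n_timepoints, x$t0, x$dt,
    x$cbf_range[1], x$cbf_range[2], x$at_range[1], x$at_range[2],
    x$t1b, x$noise_sd, x$seed))
  invisible(x)
}

sim_times <- function(config) {
  config$t0 + config$dt * (seq_len(config$n_timepoints) - 1L)
}

#' Simulate one voxel's noisy PWI time series
#'
#' Evaluates the analytical signal [pwi_signal()] at the acquisition times and
#' adds i.i.d. Gaussian noise of standard deviation `noise_sd`, matching the
#' stationary-noise assumption (motion artefacts are presumed excluded
#' upstream).
#'
#' @param params A [perfusion_params()] object.
#' @param times Acquisition times in seconds, strictly increasing.
#' @param noise_sd Noise standard deviation, >= 0.
#' @param seed Integer seed; the draw is reproducible under a fixed seed.
#' @return A tibble with columns `time`, `value`, `weight` (all weights 1).
#' @export
simulate_voxel <- function(params, times, noise_sd = 0, seed = 1L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    rlang::abort("`noise_sd` must be a single non-negative number.")
  }
  if (any(diff(times) <= 0)) rlang::abort("`times` must be strictly increasing.")
  clean <- pwi_signal(times, params)
  eps <- if (noise_sd > 0) {
    rng <- local_rng(seed)
    rng(stats::rnorm(length(times), sd = noise_sd))
  } else {
    numeric(length(times))
  }
  tibble::tibble(time = times, value = clean + eps, weight = 1)
}

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards. Returned closure evaluates its argument lazily.
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
    expr
  }
}

# Deterministic per-voxel sub-seed below 2^31, spread by a large prime.
voxel_subseed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483629)
}

# Separable Gaussian blur with reflective padding; sigma in voxels.
gaussian_smooth <- function(mat, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  smooth_1d <- function(v) {
    n <- length(v)
    left <- pmin(pmax(seq(half + 1L, 2L), 1L), n)
    right <- pmin(pmax(seq(n - 1L, n - half), 1L), n)
    padded <- c(v[left], v, v[right])
    as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
  }
  out <- apply(mat, 2L, smooth_1d)
  t(apply(out, 1L, smooth_1d))
}

smooth_field <- function(shape, range, sigma) {
  white <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  sm <- gaussian_smooth(white, sigma)
  lo <- min(sm); hi <- max(sm)
  if (hi - lo < .Machine$double.eps) {
    return(matrix(mean(range), shape[1], shape[2]))
  }
  range[1] + (sm - lo) / (hi - lo) * diff(range)
}

#' Generate a synthetic single-slice voxel grid
#'
#' Builds spatially smooth CBF and AT fields (Gaussian-filtered white noise,
#' affinely rescaled to the configured ranges — neighbouring voxels share
#' similar local parameters), a single global T1b, and per-voxel noisy PWI
#' series on a common time grid. Per-voxel noise uses voxel-distinct sub-seeds
#' derived deterministically from `config$seed`, so the whole grid is
#' bit-reproducible. The absolute noise standard deviation is
#' `config$noise_sd` times the grid's peak noiseless signal, so the nominal
#' noise level states the corruption relative to the signal scale.
#'
#' @param config A [sim_config()].
#' @return An object of class `voxel_grid`: a list with `shape`, `times`,
#'   `values` (rows x cols x time array), `roi` (logical matrix marking the
#'   interior region of interest), and `truth` (list with `cbf_map`, `at_map`
#'   matrices, scalar `t1b`, `tau`), plus the originating `config`.
#' @export
generate_grid <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be a sim_config object.")
  }
  shape <- config$shape
  times <- sim_times(config)
  rng <- local_rng(config$seed)
  fields <- rng({
    list(cbf = smooth_field(shape, config$cbf_range, config$smoothness),
         at = smooth_field(shape, config$at_range, config$smoothness))
  })
  roi <- matrix(FALSE, shape[1], shape[2])
  m <- config$roi_margin
  roi[(1 + m):(shape[1] - m), (1 + m):(shape[2] - m)] <- TRUE

  clean <- array(0, dim = c(shape[1], shape[2], length(times)))
  for (j in seq_len(shape[2])) {
    for (i in seq_len(shape[1])) {
      p <- perfusion_params(fields$cbf[i, j], fields$at[i, j],
                            config$t1b, config$tau)
      clean[i, j, ] <- pwi_signal(times, p)
    }
  }
  abs_sd <- config$noise_sd * max(abs(clean))
  values <- clean
  if (abs_sd > 0) {
    for (j in seq_len(shape[2])) {
      for (i in seq_len(shape[1])) {
        idx <- (j - 1L) * shape[1] + i
        p <- perfusion_params(fields$cbf[i, j], fields$at[i, j],
                              config$t1b, config$tau)
        values[i, j, ] <- simulate_voxel(
          p, times, abs_sd, seed = voxel_subseed(config$seed, idx))$value
      }
    }
  }
  structure(
    list(shape = shape, times = times, values = values, roi = roi,
         truth = list(cbf_map = fields$cbf, at_map = fields$at,
                      t1b = config$t1b, tau = config$tau),
         config = config),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %dx%d slice, %d time points, %d ROI voxels%s\n",
    x$shape[1], x$shape[2], length(x$times), sum(x$roi),
    if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Extract one voxel's time series from a grid
#'
#' @param grid A `voxel_grid`.
#' @param row,col 1-based voxel indices.
#' @param weights Optional per-time weights (e.g. a row of
#'   [spatial_weights()]); defaults to 1.
#' @return A tibble with columns `time`, `value`, `weight`.
#' @export
grid_series <- function(grid, row, col, weights = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (row < 1 || row > grid$shape[1] || col < 1 || col > grid$shape[2]) {
    rlang::abort("Voxel index out of range.")
  }
  w <- if (is.null(weights)) rep(1, length(grid$times)) else weights
  tibble::tibble(time = grid$times, value = grid$values[row, col, ],
                 weight = w)
}

#' Long-format view of a voxel grid
#'
#' @param x A `voxel_grid`.
#' @param ... Unused.
#' @return A tibble with one row per voxel and time point: `row`, `col`,
#'   `roi`, `time`, `value`, and (when ground truth is attached) `cbf`, `at`.
#' @export
as_tibble.voxel_grid <- function(x, ...) {
  grid_idx <- expand.grid(row = seq_len(x$shape[1]), col = seq_len(x$shape[2]))
  per_voxel <- tibble::tibble(
    row = grid_idx$row, col = grid_idx$col,
    roi = x$roi[cbind(grid_idx$row, grid_idx$col)])
  if (!is.null(x$truth)) {
    per_voxel$cbf <- x$truth$cbf_map[cbind(grid_idx$row, grid_idx$col)]
    per_voxel$at <- x$truth$at_map[cbind(grid_idx$row, grid_idx$col)]
  }
  n_t <- length(x$times)
  out <- per_voxel[rep(seq_len(nrow(per_voxel)), each = n_t), ]
  out$time <- rep(x$times, nrow(per_voxel))
  # aperm to (time, row, col) so vectorisation order matches the row-fastest
  # voxel layout above with time innermost
  out$value <- as.vector(aperm(x$values, c(3, 1, 2)))
  out
}

#' Noise-sweep configurations
#'
#' Returns the noise-robustness experiment design: copies of `base` with the
#' white-noise standard deviation stepped from 0 in increments of 0.1 up to a
#' maximum of 0.5 (six conditions including the noiseless baseline).
#'
#' @param base A [sim_config()].
#' @return A list of 6 `sim_config` objects.
#' @export
noise_sweep_configs <- function(base) {
  if (!inherits(base, "sim_config")) {
    rlang::abort("`base` must be a sim_config object.")
  }
  lapply(seq(0, 0.5, by = 0.1), function(sd) {
    out <- base
    out$noise_sd <- sd
    out
  })
}
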