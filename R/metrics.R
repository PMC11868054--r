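#' Signed relative error in percent
#'
#' \eqn{(predicted - target)/target \times 100}. Targets equal to zero are
#' undefined and return `NA` with a warning counting the exclusions.
#'
#' @param predicted,target Numeric vectors (recycled to common length).
#' @return Signed percentages.
#' @export
relative_error <- function(predicted, target) {
  out <- (predicted - target) / target * 100
  zero <- is.finite(predicted) & target == 0
  if (any(zero)) {
    rlang::warn(sprintf(
      "relative_error: %d target value(s) equal to zero excluded (NA).",
      sum(zero)))
    out[zero] <- NA_real_
  }
  out
}

#' Order-of-magnitude convergence check
#'
#' A fit is deemed not to have converged when its CBF estimate diverges from
#' the reference CBF by more than one order of magnitude (ratio above 10 or
#' below 0.1), or is non-finite.
#'
#' @param estimated_cbf Estimated CBF value(s).
#' @param reference_cbf Reference (ground-truth) CBF, > 0.
#' @return Logical: `TRUE` when converged.
#' @export
assess_convergence <- function(estimated_cbf, reference_cbf) {
  if (any(!is.finite(reference_cbf)) || any(reference_cbf <= 0)) {
    rlang::abort("`reference_cbf` must be finite and positive.")
  }
  ratio <- estimated_cbf / reference_cbf
  is.finite(ratio) & ratio <= 10 & ratio >= 0.1
}

#' Convergence rate in percent
#'
#' \eqn{|total - failed| / total \times 100} over a set of convergence flags.
#'
#' @param flags Logical vector, one per attempted fit; non-empty.
#' @return Percentage of converged fits in \[0, 100\].
#' @export
convergence_rate <- function(flags) {
  if (length(flags) == 0L) rlang::abort("`flags` must be non-empty.")
  total <- length(flags)
  failed <- sum(!flags)
  abs(total - failed) / total * 100
}

#' Variance of the discrete Laplacian of a parameter map
#'
#' Spatial-smoothness measure: the population variance, over interior in-ROI
#' voxels, of the 5-point Laplacian
#' \eqn{\nabla^2 m_{ij} = m_{i-1,j}+m_{i+1,j}+m_{i,j-1}+m_{i,j+1}-4m_{ij}}.
#' Lower values indicate spatially smoother maps. A voxel is interior when it
#' and its four neighbours lie inside the ROI (and the raster).
#'
#' @param param_map Numeric matrix.
#' @param roi Logical matrix of the same shape; defaults to everywhere TRUE.
#' @return A non-negative scalar.
#' @export
laplacian_variance <- function(param_map, roi = NULL) {
  if (!is.matrix(param_map)) rlang::abort("`param_map` must be a matrix.")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(param_map), ncol(param_map))
  if (!identical(dim(roi), dim(param_map))) {
    rlang::abort("`roi` must match the shape of `param_map`.")
  }
  nr <- nrow(param_map); nc <- ncol(param_map)
  if (nr < 3L || nc < 3L) rlang::abort("Map too small for interior Laplacian.")
  core <- 2:(nr - 1)
  corec <- 2:(nc - 1)
  lap <- param_map[core - 1, corec] + param_map[core + 1, corec] +
    param_map[core, corec - 1] + param_map[core, corec + 1] -
    4 * param_map[core, corec]
  ok <- roi[core, corec] & roi[core - 1, corec] & roi[core + 1, corec] &
    roi[core, corec - 1] & roi[core, corec + 1]
  vals <- lap[ok]
  if (length(vals) < 1L) rlang::abort("No interior in-ROI voxels.")
  if (any(!is.finite(vals))) rlang::abort("Map must be finite inside the ROI.")
  mean((vals - mean(vals))^2)
}

#' Mean squared error between predicted and observed signals
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
signal_mse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    rlang::abort("`predicted` and `observed` must have equal length.")
  }
  mean((predicted - observed)^2)
}

#' Evaluate fitted parameter maps against ground truth
#'
#' Builds the per-voxel evaluation table and its summary: signed relative
#' errors for CBF, AT and (when estimated) T1b, convergence rate, Laplacian
#' variance of the fitted maps, and signal MSE when predictions are supplied.
#' Fits flagged as non-converged are excluded from the error aggregates but
#' counted in the convergence rate.
#'
#' @param fits A tibble as returned by [fit_grid()]: one row per voxel with
#'   columns `row`, `col`, `cbf`, `at`, `t1b`, `converged`, and optionally
#'   `mse`.
#' @param grid The `voxel_grid` whose `truth` the fits are compared against.
#' @return An object of class `asl_evaluation`: list with `voxels` (per-voxel
#'   tibble incl. relative errors), `summary` (one-row tibble of aggregates).
#' @export
evaluate_fits <- function(fits, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(grid$truth)) rlang::abort("`grid` carries no ground truth.")
  idx <- cbind(fits$row, fits$col)
  vox <- dplyr::mutate(
    tibble::as_tibble(fits),
    cbf_true = grid$truth$cbf_map[idx],
    at_true = grid$truth$at_map[idx],
    t1b_true = grid$truth$t1b,
    re_cbf = relative_error(.data$cbf, .data$cbf_true),
    re_at = relative_error(.data$at, .data$at_true),
    re_t1b = relative_error(.data$t1b, .data$t1b_true))
  conv <- vox$converged
  ok <- conv & is.finite(vox$re_cbf)
  maps <- fit_maps(fits, grid$shape)
  summary <- tibble::tibble(
    n_voxels = nrow(vox),
    convergence_rate = convergence_rate(conv),
    re_cbf_mean = mean(vox$re_cbf[ok]),
    re_cbf_sd = stats::sd(vox$re_cbf[ok]),
    re_cbf_mean_abs = mean(abs(vox$re_cbf[ok])),
    re_at_mean = mean(vox$re_at[ok]),
    re_at_sd = stats::sd(vox$re_at[ok]),
    re_at_mean_abs = mean(abs(vox$re_at[ok])),
    re_t1b_mean = mean(vox$re_t1b[ok]),
    re_t1b_sd = stats::sd(vox$re_t1b[ok]),
    lapvar_cbf = laplacian_variance(maps$cbf, maps$mask),
    lapvar_at = laplacian_variance(maps$at, maps$mask),
    mse_mean = if ("mse" %in% names(vox)) mean(vox$mse[ok]) else NA_real_,
    mse_sd = if ("mse" %in% names(vox)) stats::sd(vox$mse[ok]) else NA_real_)
  structure(list(voxels = vox, summary = summary), class = "asl_evaluation")
}

# Rasterise a per-voxel fit table back onto the grid.
fit_maps <- function(fits, shape) {
  cbf <- matrix(NA_real_, shape[1], shape[2])
  at <- matrix(NA_real_, shape[1], shape[2])
  mask <- matrix(FALSE, shape[1], shape[2])
  idx <- cbind(fits$row, fits$col)
  cbf[idx] <- fits$cbf
  at[idx] <- fits$at
  mask[idx] <- TRUE
  list(cbf = cbf, at = at, mask = mask)
}

#' @export
print.asl_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<asl_evaluation> %d voxels, convergence %.1f%%\n",
           "  RE CBF %.1f +/- %.1f %%   RE AT %.1f +/- %.1f %%\n",
           "  Laplacian variance: CBF %.3g, AT %.3g\n"),
    s$n_voxels, s$convergence_rate, s$re_cbf_mean, s$re_cbf_sd,
    s$re_at_mean, s$re_at_sd, s$lapvar_cbf, s$lapvar_at))
  invisible(x)
}

#' @rdname evaluate_fits
#' @param x An `asl_evaluation`.
#' @param ... Unused.
#' @export
tidy.asl_evaluation <- function(x, ...) x$voxels

#' @rdname evaluate_fits
#' @export
glance.asl_evaluation <- function(x, ...) x$summary
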