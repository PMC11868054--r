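#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.asl_fit <- function(x, ...) {
  cat(sprintf("<%s fit> %s\n", x$method,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  CBF = %.4g, AT = %.4g s, T1b = %.4g s\n",
              x$params$cbf, x$params$at, x$params$t1b))
  if (!is.null(x$objective) && is.finite(x$objective)) {
    cat(sprintf("  final objective = %.4g\n", x$objective))
  }
  invisible(x)
}

#' Tidy a voxel fit
#'
#' @param x An `asl_fit` (from [fit_lsf()], [fit_pinn()], [fit_supinn()], ...).
#' @param ... Unused.
#' @return One row per estimated parameter: `term`, `estimate`.
#' @export
tidy.asl_fit <- function(x, ...) {
  tibble::tibble(term = c("cbf", "at", "t1b"),
                 estimate = c(x$params$cbf, x$params$at, x$params$t1b))
}

#' One-row fit summary
#'
#' @inheritParams tidy.asl_fit
#' @return Tibble with `method`, `converged`, `objective`, parameter
#'   estimates and (for PINN-family fits) the final loss decomposition.
#' @export
glance.asl_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, converged = x$converged,
    objective = x$objective %||% NA_real_,
    cbf = x$params$cbf, at = x$params$at, t1b = x$params$t1b,
    loss_ode = x$loss_ode %||% NA_real_,
    loss_data = x$loss_data %||% NA_real_,
    n_obs = nrow(x$data))
}

#' Observed series with fitted values attached
#'
#' @inheritParams tidy.asl_fit
#' @return The fit's data with a `.fitted` column (model prediction at the
#'   acquisition times) and `.resid`.
#' @export
augment.asl_fit <- function(x, ...) {
  fitted_vals <- if (!is.null(x$model)) {
    pinn_forward(x$model, x$data$time)$value
  } else if (is.finite(x$params$cbf)) {
    pwi_signal(x$data$time, x$params)
  } else {
    rep(NA_real_, nrow(x$data))
  }
  dplyr::mutate(tibble::as_tibble(x$data), .fitted = fitted_vals,
                .resid = .data$value - .fitted)
}

#' Plot a voxel fit
#'
#' Observed PWI samples (point size mapped to the data-confidence weight)
#' with the fitted signal curve overlaid.
#'
#' @param object An `asl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asl_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, size = .data$weight),
                        alpha = 0.8, show.legend = any(object$data$weight < 1)) +
    ggplot2::scale_size_continuous(range = c(1, 2.5), limits = c(0.1, 1)) +
    ggplot2::labs(x = "time after labelling (s)", y = "PWI signal",
                  title = sprintf("%s fit: CBF = %.3g, AT = %.3g s, T1b = %.3g s",
                                  object$method, object$params$cbf,
                                  object$params$at, object$params$t1b),
                  size = "weight") +
    ggplot2::theme_minimal()
  if (!is.null(object$predicted)) {
    p <- p + ggplot2::geom_line(data = object$predicted,
                                ggplot2::aes(y = .data$value),
                                colour = "#2166ac")
  }
  p
}

#' Plot a parameter map from per-voxel fits
#'
#' @param fits A tibble from [fit_grid()].
#' @param parameter Which map to draw: `"cbf"`, `"at"` or `"t1b"`.
#' @return A ggplot raster of the fitted parameter over the slice.
#' @export
plot_parameter_map <- function(fits, parameter = c("cbf", "at", "t1b")) {
  parameter <- match.arg(parameter)
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = toupper(parameter)) +
    ggplot2::theme_minimal()
}

#' Plot the training loss decomposition of a PINN-family fit
#'
#' @param fit A `pinn_fit` or `supinn_fit`.
#' @return A ggplot of total, ODE and data loss against iteration (log10 y).
#' @export
plot_loss_history <- function(fit) {
  if (is.null(fit$loss_history)) rlang::abort("Fit carries no loss history.")
  long <- tidyr::pivot_longer(fit$loss_history,
                              c("loss", "loss_ode", "loss_data"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss") +
    ggplot2::theme_minimal()
}
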