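# Shared fixtures: everything is generated in code at test time.

default_times <- function() seq(0.3, 3.6, by = 0.3)

ref_params <- function() perfusion_params(cbf = 1, at = 0.6, t1b = 1.6)

make_series <- function(params = perfusion_params(0.4, 0.5, 1.8),
                        noise_sd = 0, seed = 1L) {
  simulate_voxel(params, default_times(), noise_sd = noise_sd, seed = seed)
}

# Fast schedule for smoke tests where accuracy is not under test.
smoke_schedule <- function() pinn_schedule(c(200L, 400L, 200L), log_every = 50L)

# Reduced schedule that still trains meaningfully (used for comparative
# properties where only orderings are asserted).
reduced_schedule <- function() pinn_schedule(c(2000L, 8000L, 2000L))

# Full default schedule (accuracy-bearing fits).
full_schedule <- function() pinn_schedule()

# Build a voxel_grid directly from a value array (bypassing the simulator),
# for hand-constructed neighbourhood examples.
manual_grid <- function(values, roi = NULL, times = NULL, truth = NULL) {
  stopifnot(length(dim(values)) == 3L)
  shape <- dim(values)[1:2]
  if (is.null(times)) times <- seq(0.3, by = 0.3, length.out = dim(values)[3])
  if (is.null(roi)) roi <- matrix(TRUE, shape[1], shape[2])
  structure(
    list(shape = shape, times = times, values = values, roi = roi,
         truth = truth, config = NULL),
    class = "voxel_grid")
}

# Central finite difference of a scalar-argument function.
fd_central <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

net_as_plain_list <- function(net) {
  unclass(net)[c("w1", "b1", "W2", "b2", "w3", "b3")]
}
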