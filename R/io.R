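#' Write a voxel grid as NIfTI files with a JSON sidecar
#'
#' Writes the 4D PWI series (`pwi.nii.gz`, x-y-z-t with a singleton slice
#' dimension), the ROI mask (`mask.nii.gz`, uint8 with 1 = ROI), optional
#' ground-truth maps (`cbf.nii.gz`, `at.nii.gz`) and a JSON sidecar
#' (`pwi.json`) holding the acquisition time grid, the global T1b, tau, the
#' seed and the originating configuration — a provenance record sufficient to
#' reproduce the simulation bit-exactly.
#'
#' @param grid A `voxel_grid`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pwi = file.path(dir, "pwi.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             sidecar = file.path(dir, "pwi.json"))
  pwi <- array(grid$values,
               dim = c(grid$shape[1], grid$shape[2], 1L, length(grid$times)))
  RNifti::writeNifti(RNifti::asNifti(pwi, datatype = "double"), paths[["pwi"]])
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(grid$roi),
                          dim = c(grid$shape, 1L)), datatype = "uint8"),
    paths[["mask"]])
  sidecar <- list(times = grid$times, tau = grid$truth$tau %||% 0.9,
                  shape = grid$shape)
  if (!is.null(grid$truth)) {
    paths <- c(paths, cbf = file.path(dir, "cbf.nii.gz"),
               at = file.path(dir, "at.nii.gz"))
    RNifti::writeNifti(
      RNifti::asNifti(array(grid$truth$cbf_map, dim = c(grid$shape, 1L)),
                      datatype = "double"), paths[["cbf"]])
    RNifti::writeNifti(
      RNifti::asNifti(array(grid$truth$at_map, dim = c(grid$shape, 1L)),
                      datatype = "double"), paths[["at"]])
    sidecar$t1b <- grid$truth$t1b
  }
  if (!is.null(grid$config)) {
    sidecar$seed <- grid$config$seed
    sidecar$config <- unclass(grid$config)
  }
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a PWI dataset into a voxel grid
#'
#' Accepts the layout written by [write_grid()]: a 4D NIfTI with a singleton
#' slice dimension, a mask, and a JSON sidecar carrying the time grid (or an
#' explicit `times` argument).
#'
#' @param pwi Path to the 4D PWI NIfTI, or a directory containing
#'   `pwi.nii.gz`, `mask.nii.gz`, `pwi.json`.
#' @param mask Path to the ROI mask NIfTI (ignored when `pwi` is a
#'   directory).
#' @param times Acquisition times in seconds; read from the sidecar when
#'   omitted.
#' @param cbf,at Optional paths to ground-truth maps.
#' @param t1b Optional ground-truth global T1b.
#' @return A `voxel_grid`.
#' @export
read_pwi <- function(pwi, mask = NULL, times = NULL, cbf = NULL, at = NULL,
                     t1b = NULL) {
  sidecar <- NULL
  if (dir.exists(pwi)) {
    dir <- pwi
    pwi <- file.path(dir, "pwi.nii.gz")
    mask <- mask %||% file.path(dir, "mask.nii.gz")
    side_path <- file.path(dir, "pwi.json")
    if (file.exists(side_path)) sidecar <- jsonlite::read_json(side_path)
    cbf_path <- file.path(dir, "cbf.nii.gz")
    at_path <- file.path(dir, "at.nii.gz")
    if (is.null(cbf) && file.exists(cbf_path)) cbf <- cbf_path
    if (is.null(at) && file.exists(at_path)) at <- at_path
  }
  if (!file.exists(pwi)) rlang::abort(sprintf("PWI file not found: %s", pwi))
  if (is.null(mask) || !file.exists(mask)) {
    rlang::abort("ROI mask file is required and was not found.")
  }
  img <- RNifti::readNifti(pwi)
  d <- dim(img)
  if (length(d) != 4L) {
    rlang::abort(sprintf("Expected a 4D PWI image (x, y, z, t); got %dD.",
                         length(d)))
  }
  if (d[3] != 1L) rlang::abort("Only single-slice (z-extent 1) PWI is supported.")
  if (is.null(times) && !is.null(sidecar)) {
    times <- as.numeric(unlist(sidecar$times))
  }
  if (is.null(times)) {
    rlang::abort("Acquisition `times` not given and no JSON sidecar found.")
  }
  if (length(times) != d[4]) {
    rlang::abort("Length of `times` does not match the image's time extent.")
  }
  read_slice <- function(path) {
    # NIfTI readers may drop the singleton slice dimension
    matrix(as.vector(as.array(RNifti::readNifti(path)))[seq_len(d[1] * d[2])],
           d[1], d[2])
  }
  roi <- read_slice(mask) != 0
  truth <- NULL
  t1b <- t1b %||% sidecar$t1b
  if (!is.null(cbf) && !is.null(at)) {
    truth <- list(cbf_map = read_slice(cbf),
                  at_map = read_slice(at),
                  t1b = t1b %||% NA_real_,
                  tau = sidecar$tau %||% 0.9)
  }
  config <- NULL
  if (!is.null(sidecar$config)) {
    fields <- lapply(sidecar$config, function(x) unlist(x, use.names = FALSE))
    config <- tryCatch(do.call(sim_config, fields[
      c("shape", "cbf_range", "at_range", "t1b", "noise_sd", "n_timepoints",
        "dt", "t0", "smoothness", "roi_margin", "tau", "seed")]),
      error = function(e) NULL)
  }
  structure(
    list(shape = c(d[1], d[2]), times = times,
         values = array(as.array(img)[, , 1, ], dim = c(d[1], d[2], d[4])),
         roi = roi, truth = truth, config = config),
    class = "voxel_grid")
}

#' Write per-voxel fits and parameter maps
#'
#' Writes the tidy per-voxel table (`fits.csv`), CBF/AT maps and convergence
#' mask as NIfTI, and the subject-level T1b with provenance (seed, method) as
#' JSON.
#'
#' @param fits Tibble from [fit_grid()].
#' @param grid The fitted `voxel_grid` (for the raster shape).
#' @param dir Output directory.
#' @param method Method label recorded in the provenance JSON.
#' @param seed Seed recorded in the provenance JSON.
#' @return Invisibly, the named vector of paths written.
#' @export
write_fits <- function(fits, grid, dir, method = "unknown", seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maps <- fit_maps(fits, grid$shape)
  conv <- matrix(0L, grid$shape[1], grid$shape[2])
  conv[cbind(fits$row, fits$col)] <- as.integer(fits$converged)
  paths <- c(csv = file.path(dir, "fits.csv"),
             cbf = file.path(dir, "cbf.nii.gz"),
             at = file.path(dir, "at.nii.gz"),
             converged = file.path(dir, "converged.nii.gz"),
             t1b = file.path(dir, "t1b.json"))
  utils::write.csv(fits, paths[["csv"]], row.names = FALSE)
  RNifti::writeNifti(RNifti::asNifti(array(maps$cbf, dim = c(grid$shape, 1L)),
                                     datatype = "double"), paths[["cbf"]])
  RNifti::writeNifti(RNifti::asNifti(array(maps$at, dim = c(grid$shape, 1L)),
                                     datatype = "double"), paths[["at"]])
  RNifti::writeNifti(RNifti::asNifti(array(conv, dim = c(grid$shape, 1L)),
                                     datatype = "uint8"), paths[["converged"]])
  t1b_vals <- fits$t1b[is.finite(fits$t1b)]
  jsonlite::write_json(
    list(t1b = if (method == "supinn") stats::median(t1b_vals) else
      mean(t1b_vals), method = method, seed = seed),
    paths[["t1b"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run a simulation from a configuration
#'
#' @param config A [sim_config()], or a path to a YAML file whose fields
#'   match its arguments.
#' @param out Output directory.
#' @return The generated `voxel_grid`, invisibly; files per [write_grid()].
#' @export
run_simulate <- function(config, out) {
  config <- load_sim_config(config)
  grid <- generate_grid(config)
  write_grid(grid, out)
  invisible(grid)
}

load_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    fields <- yaml::read_yaml(config)
    known <- names(formals(sim_config))
    return(do.call(sim_config, fields[intersect(names(fields), known)]))
  }
  if (is.list(config)) {
    known <- names(formals(sim_config))
    return(do.call(sim_config, config[intersect(names(config), known)]))
  }
  rlang::abort("`config` must be a sim_config, a list, or a YAML path.")
}

#' Fit a whole dataset from files
#'
#' Reads a PWI dataset, fits every ROI voxel with the requested method, and
#' writes maps, the per-voxel table and the subject T1b.
#'
#' @param method One of `"lsf"`, `"lsf_multi"`, `"pinn"`, `"supinn"`.
#' @param pwi,mask Paths as in [read_pwi()] (`pwi` may be a directory).
#' @param out Output directory.
#' @param seed Global seed.
#' @param t1b Fixed T1b for the LSF methods (sidecar value used when absent).
#' @param schedule,loss Passed to the PINN-family methods.
#' @param ... Further arguments to [fit_grid()].
#' @return The per-voxel fits tibble, invisibly.
#' @export
run_fit <- function(method, pwi, mask = NULL, out, seed = 1L, t1b = NULL,
                    schedule = pinn_schedule(), loss = loss_spec(), ...) {
  grid <- read_pwi(pwi, mask)
  fits <- fit_grid(grid, method = method, t1b = t1b, schedule = schedule,
                   loss = loss, seed = seed, ...)
  write_fits(fits, grid, out, method = method, seed = seed)
  invisible(fits)
}

#' Evaluate fitted maps against ground truth, from files
#'
#' @param pred Directory written by [run_fit()].
#' @param truth Directory written by [run_simulate()] (must carry truth
#'   maps).
#' @param report Path of the JSON report to write; a CSV with the per-voxel
#'   table is written next to it.
#' @return The `asl_evaluation`, invisibly.
#' @export
run_evaluate <- function(pred, truth, report) {
  grid <- read_pwi(truth)
  if (is.null(grid$truth)) rlang::abort("`truth` directory has no truth maps.")
  fits <- tibble::as_tibble(utils::read.csv(file.path(pred, "fits.csv")))
  ev <- evaluate_fits(fits, grid)
  dir.create(dirname(report), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(ev$summary), report, auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(ev$voxels, sub("\\.json$", ".csv", report),
                   row.names = FALSE)
  invisible(ev)
}
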