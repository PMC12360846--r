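# Gaussian point-spread simulation of a density map from an atomic model:
# rho(x) = sum_i theta * Z_i * exp(-k |x - r_i|^2), summed over heavy atoms,
# with k = 1 / (2 sigma^2) and sigma = resolution * sigma_factor.

#' Simulation parameters
#'
#' @param resolution nominal map resolution in Angstrom (> 0); sets the
#'   Gaussian width via `sigma = resolution * sigma_factor`.
#' @param theta global amplitude scaling factor (> 0). Normalization removes
#'   the overall scale downstream, so the default 1 is only a convention.
#' @param sigma_factor converts resolution to the Gaussian sigma. The
#'   default `1 / (pi * sqrt(2))` is the ChimeraX molmap convention; other
#'   packages use other conventions, hence the knob.
#' @param cutoff_sigmas truncate each atom's contribution beyond this many
#'   sigmas (>= 3 for the documented accuracy bound); `Inf` disables the
#'   cutoff (exact evaluation, used by oracle tests).
#' @return an object of class `sim_params` with the derived decay constant
#'   `k = 1 / (2 sigma^2)` in 1/Angstrom^2.
#' @export
sim_params <- function(resolution = 2, theta = 1,
                       sigma_factor = 1 / (pi * sqrt(2)),
                       cutoff_sigmas = 5) {
  if (!is.finite(resolution) || resolution <= 0) stop("`resolution` must be > 0")
  if (!is.finite(theta) || theta <= 0) stop("`theta` must be > 0")
  if (!is.finite(sigma_factor) || sigma_factor <= 0)
    stop("`sigma_factor` must be > 0")
  if (is.finite(cutoff_sigmas) && cutoff_sigmas < 3)
    stop("`cutoff_sigmas` must be >= 3 (or Inf for exact evaluation)")
  sigma <- resolution * sigma_factor
  structure(list(resolution = resolution, theta = theta,
                 sigma_factor = sigma_factor, cutoff_sigmas = cutoff_sigmas,
                 sigma = sigma, k = resolution_to_k(resolution, sigma_factor)),
            class = "sim_params")
}

#' Convert resolution to the Gaussian decay constant k
#'
#' `k = 1 / (2 (resolution * sigma_factor)^2)` in 1/Angstrom^2. k falls as
#' 1/resolution^2, so lower-resolution maps get broader kernels.
#'
#' @param resolution resolution in Angstrom (> 0).
#' @param sigma_factor resolution-to-sigma conversion factor (> 0).
#' @return the decay constant k.
#' @export
resolution_to_k <- function(resolution, sigma_factor = 1 / (pi * sqrt(2))) {
  if (any(!is.finite(resolution)) || any(resolution <= 0))
    stop("`resolution` must be > 0")
  if (any(!is.finite(sigma_factor)) || any(sigma_factor <= 0))
    stop("`sigma_factor` must be > 0")
  1 / (2 * (resolution * sigma_factor)^2)
}

#' Build a zero-filled grid covering a model
#'
#' Axis-aligned grid covering the model's bounding box expanded by `margin`
#' on every side, sampled at `voxel` Angstrom.
#'
#' @param model an [atomic_model].
#' @param voxel voxel edge length in Angstrom (> 0), scalar or length 3.
#' @param margin padding in Angstrom added on every side (>= 0).
#' @return a zero-filled [density_map].
#' @export
grid_from_model <- function(model, voxel = 1, margin = 5) {
  if (!is_atomic_model(model)) stop("expected an `atomic_model`")
  if (any(voxel <= 0)) stop("`voxel` must be > 0")
  if (margin < 0) stop("`margin` must be >= 0")
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  xyz <- coords_matrix(model)
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  n <- pmax(1L, as.integer(floor((hi - lo) / voxel + 1e-9)) + 1L)
  density_map(array(0, dim = n), voxel_size = voxel, origin = lo)
}

#' Simulate a density map from an atomic model
#'
#' Evaluates the Gaussian point-spread sum over heavy atoms on the grid of
#' `grid` (its data values are ignored). Each atom's contribution is
#' truncated beyond `cutoff_sigmas * sigma`; the truncated tail is bounded
#' by `theta * Z * exp(-cutoff_sigmas^2 / 2)` per atom and voxel. The
#' squared-exponential factorizes over axes, so each atom costs three 1D
#' Gaussian vectors plus an outer product over its local box.
#'
#' @param model an [atomic_model].
#' @param grid a [density_map] defining shape, voxel size and origin.
#' @param params a [sim_params].
#' @param use_occupancy multiply each atom's weight by its occupancy
#'   (default `FALSE`: the plain Z-weighted sum).
#' @return a [density_map] on the same grid with the simulated density.
#' @export
simulate_map <- function(model, grid, params = sim_params(),
                         use_occupancy = FALSE) {
  if (!is_atomic_model(model)) stop("expected an `atomic_model`")
  stopifnot_map(grid)
  if (!inherits(params, "sim_params")) stop("expected `sim_params`")
  d <- dim(grid$data)
  acc <- array(0, dim = d)
  k <- params$k
  radius <- if (is.finite(params$cutoff_sigmas))
    params$cutoff_sigmas * params$sigma else Inf
  cx <- axis_coords(grid, 1L)
  cy <- axis_coords(grid, 2L)
  cz <- axis_coords(grid, 3L)
  w <- params$theta * model$atoms$number
  if (use_occupancy) w <- w * model$atoms$occupancy
  xyz <- coords_matrix(model)
  for (i in seq_len(nrow(xyz))) {
    if (is.finite(radius)) {
      ix <- which(abs(cx - xyz[i, 1]) <= radius)
      iy <- which(abs(cy - xyz[i, 2]) <= radius)
      iz <- which(abs(cz - xyz[i, 3]) <= radius)
      if (!length(ix) || !length(iy) || !length(iz)) next
    } else {
      ix <- seq_along(cx); iy <- seq_along(cy); iz <- seq_along(cz)
    }
    gx <- exp(-k * (cx[ix] - xyz[i, 1])^2)
    gy <- exp(-k * (cy[iy] - xyz[i, 2])^2)
    gz <- exp(-k * (cz[iz] - xyz[i, 3])^2)
    acc[ix, iy, iz] <- acc[ix, iy, iz] +
      w[i] * (gx %o% gy %o% gz)
  }
  density_map(acc, voxel_size = grid$voxel_size, origin = grid$origin,
              label = grid$label)
}

#' Simulate a normalized map on the grid of a reference map
#'
#' Runs [simulate_map] on the reference's exact grid (shape, voxel size,
#' origin) and min-max normalizes the result — the procedure that produces
#' a training input map matched voxel-for-voxel to an experimental target.
#'
#' @param model an [atomic_model].
#' @param reference a [density_map] whose grid is copied.
#' @param params a [sim_params] (default: 2 Angstrom resolution).
#' @return a normalized [density_map] on the reference grid.
#' @export
simulate_on_reference <- function(model, reference, params = sim_params()) {
  stopifnot_map(reference)
  out <- simulate_map(model, reference, params)
  if (max(out$data) == 0) {
    warning("model lies entirely outside the reference grid; returning zeros")
    return(out)
  }
  minmax_normalize(out)
}
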