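# Curation of raw experimental maps into training targets, and stochastic
# augmentation of simulated input maps.
#
# A raw deposited map carries solvent, lipid and nanodisc background that
# spoils the voxelwise pairing with a clean simulated map. Curation boxes
# the region around the (aligned) atomic model, resamples to a 1 A grid and
# min-max normalizes, producing the "ExpMap" training target.

#' Rectangular world-space box
#'
#' @param lower,upper length-3 world coordinates in Angstrom with
#'   `upper > lower` componentwise.
#' @return an object of class `box_spec`.
#' @export
box_spec <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L ||
      any(!is.finite(c(lower, upper))))
    stop("`lower` and `upper` must be finite length-3 vectors")
  # equality is allowed so that a margin-0 box around a single atom (or a
  # planar set) stays representable; such a box selects one voxel layer
  if (any(upper < lower)) stop("`upper` must not be below `lower`")
  structure(list(lower = lower, upper = upper), class = "box_spec")
}

#' Bounding box of a model, expanded by a margin
#'
#' @param model an [atomic_model].
#' @param margin Angstrom added on every side (>= 0). The default 5 A keeps
#'   the box "slightly larger" than the structure so boundary density is
#'   retained.
#' @return a [box_spec].
#' @export
compute_bounding_box <- function(model, margin = 5) {
  if (!is_atomic_model(model)) stop("expected an `atomic_model`")
  if (margin < 0) stop("`margin` must be >= 0")
  xyz <- coords_matrix(model)
  box_spec(apply(xyz, 2L, min) - margin, apply(xyz, 2L, max) + margin)
}

#' Extract a world-space box from a map
#'
#' Keeps the voxels whose centres lie inside the box; parts of the box
#' outside the map are zero-filled, and the origin is updated so world
#' coordinates are preserved.
#'
#' @param map a [density_map].
#' @param box a [box_spec] overlapping the map's world extent.
#' @return a [density_map] covering the box.
#' @export
extract_box <- function(map, box) {
  stopifnot_map(map)
  if (!inherits(box, "box_spec")) stop("expected a `box_spec`")
  d <- dim(map$data)
  # voxel index range (1-based) whose centres fall inside [lower, upper]
  first <- ceiling((box$lower - map$origin) / map$voxel_size - 1e-9) + 1
  last <- floor((box$upper - map$origin) / map$voxel_size + 1e-9) + 1
  if (any(last < 1) || any(first > d))
    stop("box does not overlap the map extent")
  first_cl <- pmax(first, 1); last_cl <- pmin(last, d)
  if (any(last_cl < first_cl)) stop("box does not overlap the map extent")
  nd <- as.integer(last - first + 1)
  out <- array(0, dim = nd)
  # placement of the clipped region inside the output canvas
  off <- as.integer(first_cl - first)
  sz <- as.integer(last_cl - first_cl + 1)
  out[off[1] + seq_len(sz[1]), off[2] + seq_len(sz[2]), off[3] + seq_len(sz[3])] <-
    map$data[first_cl[1]:last_cl[1], first_cl[2]:last_cl[2],
             first_cl[3]:last_cl[3]]
  density_map(out, voxel_size = map$voxel_size,
              origin = map$origin + (first - 1) * map$voxel_size,
              label = map$label)
}

#' Curate a raw experimental map into a training target
#'
#' Boxes the raw map around the aligned model (bounding box + margin),
#' resamples the boxed map to a 1 A cubic grid and min-max normalizes to
#' `[0, 1]`.
#'
#' @param raw a [density_map], aligned in world space with `model`.
#' @param model the [atomic_model] fitted to the map.
#' @param margin box margin in Angstrom (default 5).
#' @param target_voxel output voxel size (default 1 A cubic).
#' @return a normalized [density_map] at `target_voxel`.
#' @export
curate_expmap <- function(raw, model, margin = 5, target_voxel = 1) {
  boxed <- extract_box(raw, compute_bounding_box(model, margin))
  minmax_normalize(resample_map(boxed, target_voxel))
}

#' Separable Gaussian blur of a 3D array (sigma in voxels, zero padding)
#' @noRd
gaussian_blur3 <- function(data, sigma) {
  if (sigma <= 0) return(data)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(data)
  conv_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    for (t in -r:r) {
      w <- kern[t + r + 1L]
      src <- seq_len(n) + t
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      dst <- which(ok)
      idx_dst <- switch(axis, list(dst, TRUE, TRUE), list(TRUE, dst, TRUE),
                        list(TRUE, TRUE, dst))
      idx_src <- switch(axis, list(src[ok], TRUE, TRUE),
                        list(TRUE, src[ok], TRUE), list(TRUE, TRUE, src[ok]))
      out <- do.call(`[<-`, c(list(out), idx_dst, list(
        do.call(`[`, c(list(out), idx_dst, list(drop = FALSE))) +
          w * do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
    }
    out
  }
  for (axis in 1:3) data <- conv_axis(data, axis)
  data
}

#' Augmentation configuration
#'
#' Three independent stochastic perturbations of a normalized simulated
#' map: additive Gaussian noise, Gaussian blur, and anisotropy (downsample
#' one random axis, then trilinear-upsample back). Each is applied with
#' `per_transform_probability`; all draws come from a generator seeded with
#' `seed`, so a given config is fully deterministic.
#'
#' @param noise_std_range `[lo, hi]` noise standard deviation in normalized
#'   density units.
#' @param blur_sigma_range `[lo, hi]` blur sigma in voxels.
#' @param anisotropy_factor_range `[lo, hi]` downsampling factor (>= 1).
#' @param per_transform_probability probability each transform fires.
#' @param seed integer RNG seed.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(noise_std_range = c(0, 0.05),
                           blur_sigma_range = c(0, 1.0),
                           anisotropy_factor_range = c(1.5, 2.0),
                           per_transform_probability = 0.5,
                           seed = 1L) {
  chk <- function(r, nm, lo_min = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo_min)
      stop("`", nm, "` must be [lo, hi] with ", lo_min, " <= lo <= hi")
  }
  chk(noise_std_range, "noise_std_range")
  chk(blur_sigma_range, "blur_sigma_range")
  chk(anisotropy_factor_range, "anisotropy_factor_range", lo_min = 1)
  p <- per_transform_probability
  if (!is.finite(p) || p < 0 || p > 1)
    stop("`per_transform_probability` must be in [0, 1]")
  structure(list(noise_std_range = as.numeric(noise_std_range),
                 blur_sigma_range = as.numeric(blur_sigma_range),
                 anisotropy_factor_range = as.numeric(anisotropy_factor_range),
                 per_transform_probability = p, seed = as.integer(seed)),
            class = "augment_config")
}

#' Downsample one axis by `factor` then trilinear-upsample back
#' @noRd
apply_anisotropy <- function(data, axis, factor) {
  d <- dim(data)
  n <- d[axis]
  m <- max(2L, as.integer(round(n / factor)))
  if (m >= n) return(data)
  small <- d; small[axis] <- m
  down <- resize_trilinear(data, small)
  resize_trilinear(down, d)
}

#' Apply seeded stochastic augmentation to a normalized map
#'
#' @param map a [density_map] with values in `[0, 1]`.
#' @param config an [augment_config].
#' @return a [density_map], same grid, values clipped back to `[0, 1]`.
#' @export
augment <- function(map, config = augment_config()) {
  stopifnot_map(map)
  if (!inherits(config, "augment_config")) stop("expected `augment_config`")
  rng <- range(map$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("`augment` expects a map normalized to [0, 1]; got range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))

  data <- map$data
  p <- config$per_transform_probability
  # fixed draw order keeps outputs reproducible across option values
  fire <- stats::runif(3L) < p
  noise_sd <- stats::runif(1L, config$noise_std_range[1], config$noise_std_range[2])
  blur_sd <- stats::runif(1L, config$blur_sigma_range[1], config$blur_sigma_range[2])
  aniso_f <- stats::runif(1L, config$anisotropy_factor_range[1],
                          config$anisotropy_factor_range[2])
  aniso_axis <- sample.int(3L, 1L)
  if (fire[1] && noise_sd > 0)
    data <- data + array(stats::rnorm(length(data), sd = noise_sd), dim(data))
  if (fire[2] && blur_sd > 0)
    data <- gaussian_blur3(data, blur_sd)
  if (fire[3] && aniso_f > 1)
    data <- apply_anisotropy(data, aniso_axis, aniso_f)
  map$data <- pmin(pmax(data, 0), 1)
  map
}

# -- seeded local RNG scope (save/restore the global .Random.seed) ----------
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
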