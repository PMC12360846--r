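# Desk-scale synthetic fixtures: random atom clouds (with optional
# helix-like runs to mimic secondary-structure density) and paired
# (simulated, pseudo-experimental) volumes with a known ground-truth
# transform, so every pipeline stage — including GAN training — can be
# exercised offline.
#
# The pseudo-experimental target is blur + noise of the simulated map: a
# known, learnable, low-capacity transform that makes toy-GAN success or
# failure attributable. It does not claim to emulate real cryo-EM noise
# physics.

#' Fixture specification
#'
#' @param n_atoms number of heavy atoms (>= 1).
#' @param extent cubic world extent in Angstrom; coordinates lie in
#'   `[0, extent]^3`.
#' @param element_mix named weights over elements C, N, O, S (normalized to
#'   sum to 1); the default approximates protein composition.
#' @param helix_fraction fraction of atoms laid along helical curves with
#'   ~1.5 Angstrom rise per turn step and 2.3 Angstrom inter-atom spacing,
#'   mimicking SSE-like density runs.
#' @param blur_sigma ground-truth target blur in voxels.
#' @param noise_std ground-truth additive Gaussian noise sd (normalized
#'   density units).
#' @param seed integer seed fixing the whole fixture.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_atoms = 60, extent = 26,
                         element_mix = c(C = 0.62, N = 0.17, O = 0.20, S = 0.01),
                         helix_fraction = 0.5, blur_sigma = 1.0,
                         noise_std = 0.03, seed = 1L) {
  if (n_atoms < 1) stop("`n_atoms` must be >= 1")
  if (extent <= 0) stop("`extent` must be > 0")
  if (is.null(names(element_mix)) ||
      !all(toupper(names(element_mix)) %in% names(periodic_table)))
    stop("`element_mix` must be a named weight vector over known elements")
  if (any(element_mix < 0) || sum(element_mix) <= 0)
    stop("`element_mix` weights must be non-negative and not all zero")
  if (helix_fraction < 0 || helix_fraction > 1)
    stop("`helix_fraction` must be in [0, 1]")
  if (blur_sigma < 0 || noise_std < 0)
    stop("`blur_sigma` and `noise_std` must be >= 0")
  structure(list(n_atoms = as.integer(n_atoms), extent = extent,
                 element_mix = element_mix / sum(element_mix),
                 helix_fraction = helix_fraction,
                 blur_sigma = blur_sigma, noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Draw a random atom cloud
#'
#' `helix_fraction` of the atoms are placed along random helical paths
#' (radius 2.3 Angstrom, 1.5 Angstrom rise, 2.3 Angstrom arc spacing,
#' random axis orientation); the rest are uniform in the extent. All
#' coordinates are clamped into `[0, extent]^3`. Deterministic per seed.
#'
#' @param spec a [fixture_spec].
#' @return an [atomic_model].
#' @export
random_atom_cloud <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop("expected a `fixture_spec`")
  old <- local_rng(spec$seed)
  on.exit(restore_rng(old))
  n <- spec$n_atoms
  n_helix <- round(spec$helix_fraction * n)
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n_helix) {
    run <- min(sample(6:12, 1L), n_helix - nrow(pts))
    centre <- stats::runif(3L, 0.25, 0.75) * spec$extent
    # random orthonormal frame for the helix axis
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    radius <- 2.3; rise <- 1.5
    dphi <- 2.3 / sqrt(radius^2 + (rise / (2 * pi))^2)  # ~2.3 A arc steps
    t <- seq_len(run) * dphi
    local <- cbind(radius * cos(t), radius * sin(t), rise * t / (2 * pi))
    pts <- rbind(pts, sweep(local %*% t(q), 2L, centre, `+`))
  }
  n_unif <- n - n_helix
  if (n_unif > 0)
    pts <- rbind(pts, matrix(stats::runif(3 * n_unif, 0, spec$extent),
                             n_unif, 3))
  pts <- pmin(pmax(pts, 0), spec$extent)
  elems <- sample(names(spec$element_mix), n, replace = TRUE,
                  prob = spec$element_mix)
  atomic_model(data.frame(
    element = elems, number = element_to_z(elems),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    occupancy = 1, chain = "A", resid = as.character(seq_len(n)),
    stringsAsFactors = FALSE))
}

#' Build a paired (simulated, pseudo-experimental) map
#'
#' `sim` is the normalized 2 Angstrom simulation of `model` on a 1 Angstrom
#' grid; `pseudo_exp` is `minmax_normalize(blur(sim, blur_sigma) +
#' noise(noise_std))` on the same grid, so the generator's learnable target
#' transform is known exactly.
#'
#' @param model an [atomic_model] (defaults to `random_atom_cloud(spec)`).
#' @param spec a [fixture_spec] supplying the ground-truth transform + seed.
#' @param params a [sim_params].
#' @param voxel,margin grid spec for [grid_from_model].
#' @return list with [density_map]s `sim` and `pseudo_exp`.
#' @export
make_training_pair <- function(model = NULL, spec = fixture_spec(),
                               params = sim_params(), voxel = 1, margin = 3) {
  if (is.null(model)) model <- random_atom_cloud(spec)
  grid <- grid_from_model(model, voxel = voxel, margin = margin)
  sim <- simulate_on_reference(model, grid, params)
  old <- local_rng(spec$seed + 1000L)
  on.exit(restore_rng(old))
  data <- sim$data
  if (spec$blur_sigma > 0) data <- gaussian_blur3(data, spec$blur_sigma)
  if (spec$noise_std > 0)
    data <- data + array(stats::rnorm(length(data), sd = spec$noise_std),
                         dim(data))
  pseudo <- minmax_normalize(density_map(data, sim$voxel_size, sim$origin,
                                         label = "pseudo_exp"))
  list(sim = sim, pseudo_exp = pseudo)
}

#' Build a paired tile dataset from synthetic fixtures
#'
#' Generates `n_pairs` fixtures (seeds `spec$seed + i`), forms each
#' (sim, pseudo_exp) pair, tiles both maps with identical geometry and
#' returns the aligned tile pairs.
#'
#' @param n_pairs number of fixture map pairs (>= 1).
#' @param spec base [fixture_spec]; pair i uses seed `spec$seed + i`.
#' @param params a [sim_params].
#' @return list of `list(sim = 32^3 array, exp = 32^3 array, start =
#'   tile offset, map = fixture index)` entries.
#' @export
build_toy_dataset <- function(n_pairs = 8, spec = fixture_spec(),
                              params = sim_params()) {
  if (n_pairs < 1) stop("`n_pairs` must be >= 1")
  out <- list()
  for (i in seq_len(n_pairs)) {
    sp <- spec
    sp$seed <- spec$seed + i
    pair <- make_training_pair(spec = sp, params = params)
    ps <- pad_and_tile(pair$sim)
    pe <- pad_and_tile(pair$pseudo_exp)
    stopifnot(identical(ps$starts, pe$starts))
    for (t in seq_along(ps$tiles))
      out[[length(out) + 1L]] <- list(sim = ps$tiles[[t]],
                                      exp = pe$tiles[[t]],
                                      start = ps$starts[t, ], map = i)
  }
  out
}
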