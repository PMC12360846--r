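# Map-pair similarity metrics: SSIM over sliding local windows, plain
# cross-correlation, mean-centred cross-correlation, and the Pearson
# correlation coefficient. The two mean-centred forms are algebraically
# identical over the same voxel support; both are provided because the
# field's tools report them separately (their defaults can differ in which
# voxels they include, emulated here with an optional threshold mask).

#' Put two maps on a common grid
#'
#' Resamples `b` onto `a`'s grid by trilinear interpolation in world
#' coordinates (points outside `b` read as 0) and returns the two same-shape
#' arrays. Maps already on identical grids are returned unchanged.
#'
#' @param a,b [density_map]s with overlapping world extents.
#' @return list with arrays `x` (from `a`) and `y` (from `b`).
#' @export
align_grids <- function(a, b) {
  stopifnot_map(a); stopifnot_map(b)
  same <- identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size - b$voxel_size)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
  if (same) return(list(x = a$data, y = b$data))
  lo_a <- a$origin; hi_a <- a$origin + (dim(a$data) - 1) * a$voxel_size
  lo_b <- b$origin; hi_b <- b$origin + (dim(b$data) - 1) * b$voxel_size
  if (any(hi_b < lo_a) || any(lo_b > hi_a))
    stop("maps have disjoint world extents")
  rb <- sample_on_grid(b, dims = dim(a$data), voxel_size = a$voxel_size,
                       origin = a$origin)
  list(x = a$data, y = rb$data)
}

#' Structural similarity index over a 3D volume
#'
#' Local means, variances and covariance are computed in sliding cubic
#' windows (uniform weights, unbiased variance) over every fully interior
#' window position, the SSIM formula is evaluated per window and averaged.
#' `c1 = (0.01 data_range)^2`, `c2 = (0.03 data_range)^2`.
#'
#' @param x,y numeric 3D arrays of identical shape.
#' @param window odd window edge length (default 7), at most the smallest
#'   volume dimension.
#' @param data_range value range of the data (1 for normalized maps).
#' @return mean SSIM score in `[-1, 1]`.
#' @export
ssim_volume <- function(x, y, window = 7L, data_range = 1) {
  if (!identical(dim(x), dim(y))) stop("`x` and `y` must have identical shape")
  d <- dim(x)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (any(d < window)) stop("window (", window, ") exceeds a volume dimension")
  n <- window^3
  box <- function(a) box_sum3(a, window)
  sx <- box(x); sy <- box(y)
  sxx <- box(x * x); syy <- box(y * y); sxy <- box(x * y)
  mx <- sx / n; my <- sy / n
  # unbiased variances/covariance, as in the standard image-library default
  vx <- (sxx - n * mx^2) / (n - 1)
  vy <- (syy - n * my^2) / (n - 1)
  cxy <- (sxy - n * mx * my) / (n - 1)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# sliding-window box sums over all fully interior positions (valid mode)
box_sum3 <- function(a, w) {
  for (axis in 1:3) {
    d <- dim(a)
    n <- d[axis]
    cs <- apply(a, setdiff(1:3, axis), function(v) {
      c0 <- cumsum(v)
      c0[w:n] - c(0, c0)[seq_len(n - w + 1L)]
    })
    # apply returns the reduced axis first; rotate it back into place
    a <- aperm(array(cs, dim = c(n - w + 1L, d[-axis])),
               order(c(axis, setdiff(1:3, axis))))
  }
  a
}

#' Plain cross-correlation of two volumes
#'
#' `dot(x, y) / (||x|| ||y||)` — not mean-centred, so adding a constant
#' changes the score.
#'
#' @param x,y numeric arrays of identical shape, each with at least one
#'   nonzero value.
#' @return correlation in `[-1, 1]`.
#' @export
map_correlation <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("`x` and `y` must have identical shape")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("correlation undefined: an input is all zero")
  sum(x * y) / (nx * ny)
}

#' Mean-centred cross-correlation
#'
#' `dot(x - mean(x), y - mean(y)) / (||x - mean(x)|| ||y - mean(y)||)`.
#' Algebraically identical to [map_pcc] over the same voxel set.
#'
#' @inheritParams map_correlation
#' @return correlation in `[-1, 1]`.
#' @export
correlation_about_mean <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("`x` and `y` must have identical shape")
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0)
    stop("correlation about mean undefined: an input is constant")
  sum(xc * yc) / (nx * ny)
}

#' Pearson correlation coefficient by the explicit summation form
#'
#' `sum((x_i - xbar)(y_i - ybar)) / sqrt(sum((x_i - xbar)^2)) /
#' sqrt(sum((y_i - ybar)^2))` over all voxels.
#'
#' @inheritParams map_correlation
#' @return PCC in `[-1, 1]`.
#' @export
map_pcc <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("`x` and `y` must have identical shape")
  xbar <- mean(x); ybar <- mean(y)
  num <- sum((x - xbar) * (y - ybar))
  den <- sqrt(sum((x - xbar)^2)) * sqrt(sum((y - ybar)^2))
  if (den == 0) stop("PCC undefined: an input is constant")
  num / den
}

#' Score a generated map against an experimental map
#'
#' Aligns the grids (the second map is resampled onto the first's grid),
#' then computes SSIM and the three correlation scores. An optional
#' `threshold` restricts the correlation family to voxels where either map
#' exceeds the level, emulating tools that mask low-density solvent before
#' correlating; SSIM is always computed on the full common grid.
#'
#' @param generated,experimental [density_map]s with overlapping extents.
#' @param window,data_range passed to [ssim_volume].
#' @param threshold optional density level for the correlation mask.
#' @return a `metrics_report` list: `ssim`, `correlation`,
#'   `correlation_about_mean`, `pcc`, `n_voxels`.
#' @export
evaluate_pair <- function(generated, experimental, window = 7L,
                          data_range = NULL, threshold = NULL) {
  al <- align_grids(generated, experimental)
  x <- al$x; y <- al$y
  if (is.null(data_range)) {
    data_range <- max(max(x) - min(x), max(y) - min(y))
    if (data_range == 0) data_range <- 1
  }
  s <- ssim_volume(x, y, window = window, data_range = data_range)
  xm <- x; ym <- y
  n_vox <- length(x)
  if (!is.null(threshold)) {
    keep <- x > threshold | y > threshold
    if (!any(keep)) stop("threshold mask removes every voxel")
    xm <- x[keep]; ym <- y[keep]
    n_vox <- sum(keep)
  }
  structure(list(ssim = s,
                 correlation = map_correlation(xm, ym),
                 correlation_about_mean = correlation_about_mean(xm, ym),
                 pcc = map_pcc(xm, ym),
                 n_voxels = n_vox),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("map similarity over %d voxels:\n  SSIM %.4f",
                     "  correlation %.4f  correlation-about-mean %.4f  PCC %.4f\n"),
              x$n_voxels, x$ssim, x$correlation, x$correlation_about_mean,
              x$pcc))
  invisible(x)
}
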