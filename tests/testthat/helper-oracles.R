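# Shared builders and independent brute-force oracles. The oracles are
# deliberately naive (triple loops, two-pass sums) and share no code with
# the package implementations they check.

toy_model <- function(coords, elements = rep("C", nrow(coords)),
                      occupancy = 1) {
  coords <- matrix(coords, ncol = 3)
  atomic_model(data.frame(
    element = elements,
    number = unname(c(H = 1, C = 6, N = 7, O = 8, S = 16)[elements]),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = occupancy, chain = "A",
    resid = as.character(seq_len(nrow(coords))),
    stringsAsFactors = FALSE))
}

random_map <- function(dims, voxel = 1, origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  density_map(array(runif(prod(dims)), dims), voxel_size = voxel,
              origin = origin)
}

# Eq.-style Gaussian sum: loop over every voxel and every atom, no cutoff
oracle_simulate <- function(model, grid, theta, k) {
  d <- dim(grid$data)
  out <- array(0, d)
  at <- model$atoms
  for (kk in seq_len(d[3])) for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
    p <- grid$origin + (c(ii, jj, kk) - 1) * grid$voxel_size
    s <- 0
    for (a in seq_len(nrow(at))) {
      r2 <- (p[1] - at$x[a])^2 + (p[2] - at$y[a])^2 + (p[3] - at$z[a])^2
      s <- s + theta * at$number[a] * exp(-k * r2)
    }
    out[ii, jj, kk] <- s
  }
  out
}

# naive trilinear resampling at world coordinates, outside -> 0
oracle_resample <- function(map, target_voxel, dims) {
  out <- array(0, dims)
  d <- dim(map$data)
  for (kk in seq_len(dims[3])) for (jj in seq_len(dims[2]))
    for (ii in seq_len(dims[1])) {
      w <- map$origin + (c(ii, jj, kk) - 1) * target_voxel
      g <- (w - map$origin) / map$voxel_size  # 0-based fractional index
      lo <- floor(g); f <- g - lo
      v <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        idx <- lo + c(dx, dy, dz) + 1
        if (all(idx >= 1) && all(idx <= d)) {
          wt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
          v <- v + wt * map$data[idx[1], idx[2], idx[3]]
        }
      }
      out[ii, jj, kk] <- v
    }
  out
}

# windowed SSIM: explicit loop over every fully-interior window
oracle_ssim <- function(x, y, window = 7, data_range = 1) {
  d <- dim(x)
  r <- window %/% 2
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  vals <- c()
  for (kk in (1 + r):(d[3] - r)) for (jj in (1 + r):(d[2] - r))
    for (ii in (1 + r):(d[1] - r)) {
      wx <- x[(ii - r):(ii + r), (jj - r):(jj + r), (kk - r):(kk + r)]
      wy <- y[(ii - r):(ii + r), (jj - r):(jj + r), (kk - r):(kk + r)]
      mx <- mean(wx); my <- mean(wy)
      vx <- sum((wx - mx)^2) / (length(wx) - 1)
      vy <- sum((wy - my)^2) / (length(wy) - 1)
      cxy <- sum((wx - mx) * (wy - my)) / (length(wx) - 1)
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  mean(vals)
}

# two-pass mean/covariance Pearson correlation
oracle_pcc <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2) / sqrt(dy2)
}

# a 32^3 tile-pair dataset small enough for fast training tests
tiny_tile_dataset <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sim <- array(runif(32^3), c(32, 32, 32))
    list(sim = sim, exp = pmin(sim * 0.8 + 0.1, 1))
  })
}
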