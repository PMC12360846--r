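# Deterministic decomposition of a map into 32^3 tiles and center-crop
# reassembly.
#
# The map is centrally placed in a zero canvas that exceeds it by 2 x 32
# voxels per axis (offset 32). Tiles of 32^3 are laid out so that their
# central 20^3 "core" blocks exactly partition the region holding the
# original data: tile starts along an axis are 26 + 20 j (0-based into the
# padded canvas), giving cores at [32 + 20 j, 52 + 20 j). Only the cores are
# used when reassembling processed tiles, so the 6-voxel rim of every tile
# is pure context and boundary effects of a tile-wise operator never reach
# the output.

TILE_SIZE <- 32L
CORE_SIZE <- 20L
CORE_LO <- 6L   # core occupies [start + 6, start + 26) within a tile
PAD_OFF <- 32L  # original data offset within the padded canvas

#' Split a map into 32^3 tiles with zero padding
#'
#' @param map a [density_map] (every axis >= 1 voxel).
#' @return an object of class `tile_pack`: `tiles` (list of 32^3 arrays in
#'   lexicographic z,y,x order), `starts` (n x 3 matrix of 0-based voxel
#'   offsets of each tile into the padded canvas, columns x,y,z),
#'   `original_shape`, `voxel_size`, `origin`, `label`.
#' @export
pad_and_tile <- function(map) {
  stopifnot_map(map)
  d <- dim(map$data)
  if (any(d < 1L)) stop("map has an empty axis")
  padded <- array(0, dim = d + 2L * PAD_OFF)
  padded[PAD_OFF + seq_len(d[1]), PAD_OFF + seq_len(d[2]),
         PAD_OFF + seq_len(d[3])] <- map$data
  ntile <- as.integer(ceiling(d / CORE_SIZE))
  starts_axis <- lapply(1:3, function(a)
    (PAD_OFF - CORE_LO) + CORE_SIZE * (seq_len(ntile[a]) - 1L))
  n <- prod(ntile)
  tiles <- vector("list", n)
  starts <- matrix(0L, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  i <- 0L
  for (sz in starts_axis[[3]]) for (sy in starts_axis[[2]])
    for (sx in starts_axis[[1]]) {
      i <- i + 1L
      tiles[[i]] <- padded[sx + seq_len(TILE_SIZE), sy + seq_len(TILE_SIZE),
                           sz + seq_len(TILE_SIZE)]
      starts[i, ] <- c(sx, sy, sz)
    }
  structure(list(tiles = tiles, starts = starts, original_shape = d,
                 voxel_size = map$voxel_size, origin = map$origin,
                 label = map$label, tile_size = TILE_SIZE,
                 core_size = CORE_SIZE),
            class = "tile_pack")
}

#' @export
print.tile_pack <- function(x, ...) {
  cat(sprintf("tile_pack: %d tiles of %d^3 (core %d^3) from a %s map\n",
              length(x$tiles), x$tile_size, x$core_size,
              paste(x$original_shape, collapse = "x")))
  invisible(x)
}

#' Reassemble processed tiles into a map
#'
#' Pastes each tile's central 20^3 core at its recorded position and crops
#' the padded canvas back to the original shape. With `processed_tiles =
#' pack$tiles` this is a bit-exact identity.
#'
#' @param pack a `tile_pack` from [pad_and_tile].
#' @param processed_tiles list of 32^3 arrays, same length/order as
#'   `pack$tiles` (defaults to the stored tiles).
#' @return a [density_map] with the grid of the source map.
#' @export
reassemble <- function(pack, processed_tiles = pack$tiles) {
  if (!inherits(pack, "tile_pack")) stop("expected a `tile_pack`")
  if (length(processed_tiles) != length(pack$tiles))
    stop("processed_tiles count (", length(processed_tiles),
         ") does not match the pack (", length(pack$tiles), ")")
  ts <- pack$tile_size
  ok_shape <- vapply(processed_tiles, function(t)
    is.numeric(t) && identical(dim(t), c(ts, ts, ts)), logical(1))
  if (!all(ok_shape))
    stop("every processed tile must be a numeric ", ts, "^3 array")
  d <- pack$original_shape
  canvas <- array(0, dim = d + 2L * PAD_OFF)
  core_idx <- CORE_LO + seq_len(pack$core_size)
  for (i in seq_along(processed_tiles)) {
    s <- pack$starts[i, ]
    canvas[s[1] + core_idx, s[2] + core_idx, s[3] + core_idx] <-
      processed_tiles[[i]][core_idx, core_idx, core_idx]
  }
  density_map(canvas[PAD_OFF + seq_len(d[1]), PAD_OFF + seq_len(d[2]),
                     PAD_OFF + seq_len(d[3]), drop = FALSE],
              voxel_size = pack$voxel_size, origin = pack$origin,
              label = pack$label)
}
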