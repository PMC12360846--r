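# Density-map and atomic-model containers plus MRC2014 / PDB / mmCIF I/O.
#
# Grid convention used throughout the package:
#   * `data` is a numeric 3D array with dim = c(nx, ny, nz); the FIRST array
#     index runs along world x (fastest-varying on disk), the third along z.
#   * the world coordinate of the centre of voxel [i, j, k] (1-based) is
#       origin + (i - 1, j - 1, k - 1) * voxel_size.
#   * MRC files with permuted axis order (mapc/mapr/maps) are reordered to
#     this canonical layout on read, so world-space densities never depend
#     on how a file was stored.

#' Construct a density map
#'
#' A density map is a 3D scalar volume on a regular grid with a physical
#' voxel size and a world-space origin (the coordinate of the centre of the
#' first voxel, in Angstrom).
#'
#' @param data numeric 3D array, dim `c(nx, ny, nz)`; index 1 runs along x.
#' @param voxel_size numeric length-3 (or scalar) voxel edge lengths in
#'   Angstrom, all > 0.
#' @param origin numeric length-3 world coordinate (Angstrom) of the centre
#'   of voxel `[1, 1, 1]`.
#' @param label free-text label stored in the MRC header on write.
#' @return an object of class `density_map`.
#' @export
density_map <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 label = as.character(label)[1]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density_map %d x %d x %d, voxel (%g, %g, %g) A, origin (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%g, %g]%s\n", min(x$data), max(x$data),
              if (nzchar(x$label)) paste0("  label: ", x$label) else ""))
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

stopifnot_map <- function(map) {
  if (!is_density_map(map)) stop("expected a `density_map` object")
  invisible(map)
}

#' World coordinates of all voxel centres along one axis
#' @noRd
axis_coords <- function(map, axis) {
  n <- dim(map$data)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$voxel_size[axis]
}

# ---------------------------------------------------------------------------
# MRC2014 reader / writer
# ---------------------------------------------------------------------------

mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC2014 density map
#'
#' Reads modes 0, 1, 2 and 6. The stored axis order (`mapc`, `mapr`,
#' `maps`) is undone so the returned array is always indexed x-fastest; the
#' origin is taken from the `ORIGIN` header record, falling back to
#' `nstart * voxel_size` when that record is all zero.
#'
#' @param path path to an `.mrc` / `.map` file.
#' @return a [density_map].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fsize <- file.info(path)$size
  if (fsize < 1024) stop("malformed MRC header: file shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 1024L)
  rd_int <- function(word, n = 1L) # word: 1-based 4-byte word index
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word + n - 1L) * 4L)],
            "integer", n = n, size = 4L, endian = "little")
  rd_flt <- function(word, n = 1L)
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word + n - 1L) * 4L)],
            "double", n = n, size = 4L, endian = "little")

  nxyz <- rd_int(1L, 3L)          # columns, rows, sections
  mode <- rd_int(4L)
  nstart <- rd_int(5L, 3L)
  mxyz <- rd_int(8L, 3L)
  cella <- rd_flt(11L, 3L)
  mapcrs <- rd_int(17L, 3L)
  orig <- rd_flt(50L, 3L)
  magic <- rawToChar(hdr_raw[(52L * 4L + 1L):(52L * 4L + 3L)])
  nsymbt <- rd_int(24L)
  nlabl <- rd_int(56L)
  label <- ""
  if (is.finite(nlabl) && nlabl >= 1L && nlabl <= 10L) {
    lab <- hdr_raw[1025L - 800L + seq_len(80L)]
    label <- trimws(rawToChar(lab[lab != as.raw(0)]))
  }

  if (any(nxyz <= 0L) || any(is.na(nxyz)))
    stop("malformed MRC header: non-positive nx/ny/nz (", paste(nxyz, collapse = ","), ")")
  if (!identical(magic, "MAP"))
    stop("malformed MRC header: missing 'MAP ' magic word")
  if (!as.character(mode) %in% names(mrc_modes))
    stop("unsupported MRC mode ", mode, " (only volume modes 0/1/2/6 are read)")
  if (!setequal(mapcrs, 1:3))
    stop("malformed MRC header: mapc/mapr/maps must be a permutation of 1,2,3, got (",
         paste(mapcrs, collapse = ","), ")")
  if (any(mxyz <= 0L))
    stop("malformed MRC header: non-positive mx/my/mz")

  nvox <- prod(as.double(nxyz))
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[[as.character(mode)]]
  if (fsize < 1024 + nsymbt + nvox * bytes_per)
    stop("malformed MRC file: truncated data block (field nx*ny*nz implies ",
         nvox * bytes_per, " data bytes)")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))

  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = TRUE)),
    `1` = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "double", n = nvox, size = 4L, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = FALSE, endian = "little")))
  stored <- array(vals, dim = nxyz)  # dims follow (mapc, mapr, maps) axes

  # canonical dim a (world axis a) <- stored dim holding that axis
  perm <- match(1:3, mapcrs)
  data <- aperm(stored, perm)

  voxel <- cella / mxyz              # along world x, y, z
  if (any(!is.finite(voxel)) || any(voxel <= 0)) voxel <- c(1, 1, 1)

  if (all(orig == 0)) {
    nstart_world <- nstart[perm]     # starts follow stored axis order
    orig <- nstart_world * voxel
  }
  density_map(data, voxel_size = voxel, origin = orig, label = label)
}

#' Write a density map as MRC2014 (mode 2, axis order x,y,z)
#'
#' Values are stored as 32-bit floats; doubles that are not exactly
#' representable in float32 round to the nearest float32 on disk.
#'
#' @param map a [density_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot_map(map)
  d <- dim(map$data)
  con <- tryCatch(file(path, "wb"), condition = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nstart
  wi(d)                                   # mx my mz
  wf(d * map$voxel_size)                  # cella
  wf(c(90, 90, 90))                       # cellb
  wi(1:3)                                 # mapc mapr maps
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(0L)                                  # ispg
  wi(0L)                                  # nsymbt
  writeBin(raw(100L), con)                # extra words 26-49 (exttyp/nversion 0)
  wf(map$origin)                          # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(map$data)))      # rms
  wi(1L)                                  # nlabl
  lab <- charToRaw(substr(map$label, 1L, 80L))
  writeBin(c(lab, raw(800L - length(lab))), con)
  writeBin(as.numeric(map$data), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atomic models: PDB and mmCIF
# ---------------------------------------------------------------------------

# Atomic numbers for element symbols (IUPAC 1..92 covers all deposition needs)
periodic_table <- local({
  syms <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
            "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V",
            "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se",
            "Br", "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh",
            "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba",
            "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
            "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt",
            "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac",
            "Th", "Pa", "U")
  stats::setNames(seq_along(syms), toupper(syms))
})

#' Construct an atomic model
#'
#' Holds the heavy atoms that source the Gaussian point-spread simulation:
#' element symbol, atomic number Z, position (Angstrom) and occupancy.
#' Hydrogens are excluded by the readers, so `n_atoms` counts heavy atoms.
#'
#' @param atoms data.frame with columns `element`, `number`, `x`, `y`, `z`,
#'   `occupancy` and optionally `chain`, `resid`.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  req <- c("element", "number", "x", "y", "z", "occupancy")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop("`atoms` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: zero heavy atoms")
  if (any(atoms$number < 1) || any(!is.finite(atoms$number)))
    stop("atomic numbers must be >= 1")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancies must lie in [0, 1]")
  structure(list(atoms = atoms, n_atoms = nrow(atoms)), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d heavy atoms, elements {%s}\n", x$n_atoms,
              paste(sort(unique(x$atoms$element)), collapse = ", ")))
  invisible(x)
}

is_atomic_model <- function(x) inherits(x, "atomic_model")

coords_matrix <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

element_to_z <- function(symbols) {
  z <- periodic_table[toupper(trimws(symbols))]
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}

resolve_altloc <- function(df) {
  # keep the highest-occupancy alternate location; ties -> first in file order
  key <- paste(df$chain, df$resid, df$atom_name, sep = "\r")
  has_alt <- df$altloc != "" & df$altloc != " " & df$altloc != "."
  if (!any(has_alt) || !anyDuplicated(key)) return(df)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(df$occupancy[idx])]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

finalize_model <- function(df, drop_hydrogens = TRUE) {
  df$number <- element_to_z(df$element)
  df <- resolve_altloc(df)
  if (drop_hydrogens) df <- df[df$number > 1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty model: zero heavy atoms after hydrogen exclusion")
  rownames(df) <- NULL
  atomic_model(df[, c("element", "number", "x", "y", "z", "occupancy",
                      "chain", "resid")])
}

read_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(sel) == 0L) stop("no ATOM/HETATM records found")
  ln <- lines[sel]
  elem <- trimws(substr(ln, 77L, 78L))
  # element column may be absent in minimal files; fall back to atom name
  noelem <- !nzchar(elem)
  if (any(noelem)) {
    nm <- trimws(substr(ln[noelem], 13L, 16L))
    elem[noelem] <- sub("^([A-Za-z]{1,2}).*$", "\\1", nm)
    two <- toupper(elem[noelem]) %in% names(periodic_table) &
      nchar(elem[noelem]) == 2L
    elem[noelem][!two] <- substr(elem[noelem][!two], 1L, 1L)
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[is.na(occ)] <- 1
  data.frame(
    element = elem,
    x = as.numeric(substr(ln, 31L, 38L)),
    y = as.numeric(substr(ln, 39L, 46L)),
    z = as.numeric(substr(ln, 47L, 54L)),
    occupancy = pmin(pmax(occ, 0), 1),
    chain = substr(ln, 22L, 22L),
    resid = trimws(substr(ln, 23L, 26L)),
    atom_name = trimws(substr(ln, 13L, 16L)),
    altloc = substr(ln, 17L, 17L),
    stringsAsFactors = FALSE)
}

# minimal mmCIF _atom_site loop parser (whitespace-delimited, quote-aware)
read_cif_atoms <- function(lines) {
  loop_at <- which(trimws(lines) == "loop_")
  for (la in loop_at) {
    i <- la + 1L
    fields <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1L
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    rows <- list()
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (!nzchar(tl) || startsWith(tl, "_") || startsWith(tl, "loop_") ||
          startsWith(tl, "#") || startsWith(tl, "data_")) break
      rows[[length(rows) + 1L]] <- scan(text = tl, what = character(),
                                        quiet = TRUE)
      i <- i + 1L
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab) || ncol(tab) != length(fields))
      stop("malformed mmCIF _atom_site loop: token/field count mismatch")
    colnames(tab) <- sub("^_atom_site\\.", "", fields)
    need <- c("type_symbol", "Cartn_x", "Cartn_y", "Cartn_z")
    if (!all(need %in% colnames(tab)))
      stop("mmCIF _atom_site loop lacks required fields: ",
           paste(setdiff(need, colnames(tab)), collapse = ", "))
    grab <- function(col, default) {
      if (col %in% colnames(tab)) tab[, col] else rep(default, nrow(tab))
    }
    occ <- suppressWarnings(as.numeric(grab("occupancy", "1")))
    occ[is.na(occ)] <- 1
    alt <- grab("label_alt_id", ".")
    return(data.frame(
      element = tab[, "type_symbol"],
      x = as.numeric(tab[, "Cartn_x"]),
      y = as.numeric(tab[, "Cartn_y"]),
      z = as.numeric(tab[, "Cartn_z"]),
      occupancy = pmin(pmax(occ, 0), 1),
      chain = grab("auth_asym_id", grab("label_asym_id", "A")),
      resid = grab("auth_seq_id", grab("label_seq_id", "1")),
      atom_name = grab("label_atom_id", ""),
      altloc = ifelse(alt %in% c(".", "?"), "", alt),
      stringsAsFactors = FALSE))
  }
  stop("no _atom_site loop found in mmCIF file")
}

#' Read an atomic model from PDB or mmCIF
#'
#' Hydrogens are excluded (the Gaussian simulation formula sums over heavy
#' atoms only); element symbols are mapped to atomic numbers through a
#' built-in periodic table; for alternate locations only the
#' highest-occupancy conformer is kept (ties break to file order).
#'
#' @param path a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param format `"auto"` (by extension, then content), `"pdb"` or `"cif"`.
#' @return an [atomic_model].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("^_atom_site\\.", lines))) "cif" else "pdb"
  }
  df <- if (format == "pdb") read_pdb_atoms(lines) else read_cif_atoms(lines)
  finalize_model(df)
}

# ---------------------------------------------------------------------------
# Resampling and normalization
# ---------------------------------------------------------------------------

#' Trilinear gather at fractional voxel indices (0-based), outside -> 0
#' @param data 3D array; xi, yi, zi equal-length numeric vectors of 0-based
#'   fractional indices into `data`.
#' @noRd
trilinear_gather <- function(data, xi, yi, zi) {
  d <- dim(data)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  acc <- numeric(length(xi))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] &
      w > 0
    if (any(ok)) {
      lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
      acc[ok] <- acc[ok] + w[ok] * data[lin]
    }
  }
  acc
}

#' Resample a map onto a new voxel size
#'
#' Trilinear interpolation on the world-coordinate grid. The output keeps
#' the input origin; each axis gets `floor(extent / target) + 1` samples
#' where `extent = (n - 1) * voxel` is the span between first and last voxel
#' centres, so the output grid covers the input extent. Samples falling
#' outside the input grid read as 0.
#'
#' @param map a [density_map].
#' @param target_voxel scalar or length-3 target voxel size in Angstrom.
#' @return a [density_map] with `voxel_size = target_voxel`.
#' @export
resample_map <- function(map, target_voxel) {
  stopifnot_map(map)
  if (length(target_voxel) == 1L) target_voxel <- rep(target_voxel, 3L)
  target_voxel <- as.numeric(target_voxel)
  if (length(target_voxel) != 3L || any(!is.finite(target_voxel)) ||
      any(target_voxel <= 0))
    stop("`target_voxel` must be 3 positive numbers")
  d <- dim(map$data)
  extent <- (d - 1) * map$voxel_size
  # +1e-9 guards floor() against extent/target like 18/1 = 17.999999...
  nd <- pmax(1L, as.integer(floor(extent / target_voxel + 1e-9)) + 1L)
  out <- sample_on_grid(map, dims = nd, voxel_size = target_voxel,
                        origin = map$origin)
  out$label <- map$label
  out
}

#' Sample a map on an arbitrary regular grid (trilinear, outside -> 0)
#' @noRd
sample_on_grid <- function(map, dims, voxel_size, origin) {
  d <- dim(map$data)
  # world coords of target voxel centres -> fractional source indices
  gx <- (origin[1] + (seq_len(dims[1]) - 1) * voxel_size[1] - map$origin[1]) /
    map$voxel_size[1]
  gy <- (origin[2] + (seq_len(dims[2]) - 1) * voxel_size[2] - map$origin[2]) /
    map$voxel_size[2]
  gz <- (origin[3] + (seq_len(dims[3]) - 1) * voxel_size[3] - map$origin[3]) /
    map$voxel_size[3]
  xi <- rep(gx, times = dims[2] * dims[3])
  yi <- rep(rep(gy, each = dims[1]), times = dims[3])
  zi <- rep(gz, each = dims[1] * dims[2])
  vals <- trilinear_gather(map$data, xi, yi, zi)
  density_map(array(vals, dim = dims), voxel_size = voxel_size, origin = origin)
}

#' Min-max normalize a map to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant map maps to all zeros.
#'
#' @param map a [density_map].
#' @return a [density_map] with values in `[0, 1]`.
#' @export
minmax_normalize <- function(map) {
  stopifnot_map(map)
  lo <- min(map$data); hi <- max(map$data)
  map$data <- if (hi > lo) (map$data - lo) / (hi - lo)
    else array(0, dim = dim(map$data))
  map
}
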