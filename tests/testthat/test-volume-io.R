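test_that("MRC write/read round trip preserves data, voxel size and origin", {
  m <- random_map(c(9, 7, 5), voxel = c(1, 1, 2), origin = c(-3, 2.5, 7),
                  seed = 4)
  # use float32-representable values so the round trip is bit-exact
  m$data <- array(round(m$data * 1024) / 1024, dim(m$data))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  m2 <- read_mrc(f)
  expect_identical(dim(m2$data), dim(m$data))
  expect_identical(m2$data, m$data)
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-6)

  const <- density_map(array(0.5, c(8, 8, 8)))
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(const, f2)
  expect_equal(mean(read_mrc(f2)$data), 0.5)

  aniso <- random_map(c(4, 4, 4), voxel = c(1, 1, 2), seed = 9)
  f3 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(aniso, f3)
  expect_equal(read_mrc(f3)$voxel_size, c(1, 1, 2), tolerance = 1e-6)
})

# hand-build an MRC file with arbitrary axis order so the reader's
# reordering is checked against an independently permuted array
write_mrc_permuted <- function(map, path, mapcrs) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  d <- dim(map$data)
  stored <- aperm(map$data, mapcrs)      # stored dim s holds world axis mapcrs[s]
  wi(dim(stored)); wi(2L); wi(c(0L, 0L, 0L)); wi(d)
  wf(d * map$voxel_size); wf(c(90, 90, 90)); wi(mapcrs)
  wf(c(min(stored), max(stored), mean(stored))); wi(0L); wi(0L)
  writeBin(raw(100L), con)
  wf(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0L); writeBin(raw(800L), con)
  writeBin(as.numeric(stored), con, size = 4L, endian = "little")
}

test_that("permuted axis order yields identical world-space densities", {
  m <- random_map(c(6, 5, 4), origin = c(1, 2, 3), seed = 7)
  m$data <- array(round(m$data * 1024) / 1024, dim(m$data))
  perms <- list(c(1L, 2L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L), c(3L, 2L, 1L))
  for (p in perms) {
    f <- tempfile(fileext = ".mrc")
    write_mrc_permuted(m, f, p)
    got <- read_mrc(f)
    expect_identical(got$data, m$data)
    expect_equal(got$origin, m$origin, tolerance = 1e-6)
    unlink(f)
  }
})

test_that("origin falls back to nstart * voxel when the origin record is zero", {
  m <- random_map(c(4, 4, 4), seed = 2)
  f <- withr::local_tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(4L, 4L, 4L)); wi(2L); wi(c(2L, -1L, 3L)); wi(c(4L, 4L, 4L))
  wf(c(8, 8, 8)); wf(c(90, 90, 90)); wi(1:3)   # voxel = 2 A
  wf(c(0, 1, 0.5)); wi(0L); wi(0L); writeBin(raw(100L), con)
  wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0L); writeBin(raw(800L), con)
  writeBin(as.numeric(m$data), con, size = 4L, endian = "little")
  close(con)
  got <- read_mrc(f)
  expect_equal(got$origin, c(2, -1, 3) * 2, tolerance = 1e-6)
})

test_that("malformed MRC files are rejected with a named field", {
  m <- random_map(c(6, 6, 6), seed = 1)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  # truncate the data block
  raw_all <- readBin(f, "raw", file.info(f)$size)
  f_trunc <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw_all[1:(1024 + 100)], f_trunc)
  expect_error(read_mrc(f_trunc), "truncated")
  # corrupt the mode word (word 4) to a complex mode
  bad <- raw_all
  bad[13:16] <- writeBin(4L, raw(), size = 4L, endian = "little")
  f_mode <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bad, f_mode)
  expect_error(read_mrc(f_mode), "mode")
  # break the magic
  bad2 <- raw_all
  bad2[209:211] <- charToRaw("XXX")
  f_magic <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bad2, f_magic)
  expect_error(read_mrc(f_magic), "MAP")
})

test_that("PDB parsing excludes hydrogens and resolves atomic numbers", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  N   ALA A   1       2.000   3.000   4.000  1.00 10.00           N",
    "ATOM      3  H   ALA A   1       3.000   4.000   5.000  1.00 10.00           H"),
    f)
  mod <- read_model(f)
  expect_equal(mod$n_atoms, 2L)
  expect_setequal(mod$atoms$number, c(6L, 7L))
  expect_equal(mod$atoms$x, c(1, 2))
})

test_that("mmCIF and PDB encodings of the same model parse identically", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.500   2.250   3.125  1.00 10.00           C",
    "ATOM      2  O   ALA A   1      -2.000   0.500   4.750  0.80 10.00           O",
    "ATOM      3  SG  CYS A   2       0.000   1.000  -1.500  1.00 10.00           S"),
    pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "ATOM 1 C CA . 1.500 2.250 3.125 1.00 A 1",
    "ATOM 2 O O . -2.000 0.500 4.750 0.80 A 1",
    "ATOM 3 S SG . 0.000 1.000 -1.500 1.00 A 2"),
    cif)
  a <- read_model(pdb)
  b <- read_model(cif)
  expect_equal(a$atoms$number, b$atoms$number)
  expect_equal(a$atoms$x, b$atoms$x)
  expect_equal(a$atoms$y, b$atoms$y)
  expect_equal(a$atoms$z, b$atoms$z)
  expect_equal(a$atoms$occupancy, b$atoms$occupancy)
})

test_that("altloc keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60 10.00           C"),
    f)
  mod <- read_model(f)
  expect_equal(mod$n_atoms, 1L)
  expect_equal(mod$atoms$x, 9)
})

test_that("unknown elements and empty models raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "ATOM      1  XX  UNK A   1       0.000   0.000   0.000  1.00 10.00          Xx",
    f)
  expect_error(read_model(f), "Xx")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "ATOM      1  H   ALA A   1       0.000   0.000   0.000  1.00 10.00           H",
    f2)
  expect_error(read_model(f2), "zero heavy atoms")
})

test_that("resample preserves constants and linear ramps", {
  const <- density_map(array(2.5, c(6, 6, 6)), voxel_size = 2)
  r <- resample_map(const, 1)
  # interior voxels (the rim can see the implicit zero outside)
  expect_equal(max(abs(r$data[2:10, 2:10, 2:10] - 2.5)), 0, tolerance = 1e-9)

  ramp <- density_map(array(rep(seq(0, 10, length.out = 11), 11 * 11),
                            c(11, 11, 11)), voxel_size = 1)
  r2 <- resample_map(ramp, 0.5)
  want <- (seq_len(dim(r2$data)[1]) - 1) * 0.5
  expect_equal(r2$data[, 6, 6], want, tolerance = 1e-6)
})

test_that("resample matches the brute-force trilinear oracle", {
  m <- random_map(c(10, 10, 10), voxel = 2, origin = c(1, -2, 0.5), seed = 11)
  r <- resample_map(m, 1)
  expect_identical(dim(r$data), c(19L, 19L, 19L))  # floor(18/1)+1 rule
  want <- oracle_resample(m, c(1, 1, 1), dim(r$data))
  expect_equal(r$data, want, tolerance = 1e-6)
  # identity at own voxel size on an aligned grid
  same <- resample_map(m, 2)
  expect_equal(same$data, m$data, tolerance = 1e-9)
})

test_that("minmax_normalize maps to [0,1], handles constants, idempotent", {
  m <- density_map(array(c(2, 3, 4, 2, 3, 4, 2, 3), c(2, 2, 2)))
  n <- minmax_normalize(m)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.5, 1))
  expect_equal(range(n$data), c(0, 1))
  expect_identical(minmax_normalize(n)$data, n$data)
  const <- minmax_normalize(density_map(array(7, c(3, 3, 3))))
  expect_true(all(const$data == 0))
})

test_that("world coordinate round trip holds for anisotropic voxels", {
  m <- random_map(c(5, 6, 7), voxel = c(0.5, 1, 2), origin = c(-1, 4, 2),
                  seed = 3)
  idx <- c(3, 5, 2)
  world <- m$origin + (idx - 1) * m$voxel_size
  back <- (world - m$origin) / m$voxel_size + 1
  expect_equal(back, idx)
})
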