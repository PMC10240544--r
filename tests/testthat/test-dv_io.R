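random_dataset <- function(nT, nC, nZ, ny, nx, seed = 1) {
  set.seed(seed)
  data <- array(sample.int(65536L, nT * nC * nZ * ny * nx, replace = TRUE) - 1L,
                dim = c(nT, nC, nZ, ny, nx))
  np <- nT * nC * nZ
  dv_dataset(data, pixel_size_um = c(0.1, 0.1, 0.25),
             wavelengths_nm = seq(400, by = 50, length.out = nC),
             exposure_ms = rep(20, nC),
             stage_origin_um = macro_position(1, 2, 3),
             plane_metadata = data.frame(x_um = runif(np), y_um = runif(np),
                                         z_um = runif(np),
                                         timestamp_s = seq_len(np)))
}

# independent byte-level header parse (raw readBin, no package code)
raw_header <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  bytes <- readBin(con, "raw", n = 1024L)
  list(ints = readBin(bytes, "integer", n = 256L, size = 4L,
                      endian = "little"),
       map = rawToChar(bytes[209:212]),
       machst = bytes[213:216])
}

test_that("written headers parse correctly with an independent byte reader", {
  path <- withr::local_tempfile(fileext = ".dv")
  write_dv(random_dataset(1, 1, 1, 4, 4), path)
  h <- raw_header(path)
  expect_equal(h$ints[1:4], c(4L, 4L, 1L, 6L))   # nx, ny, nz, mode
  expect_equal(h$map, "MAP ")
  expect_equal(as.integer(h$machst[1]), 0x44L)
  write_dv(random_dataset(2, 3, 4, 8, 6), path)
  h <- raw_header(path)
  expect_equal(h$ints[1:3], c(6L, 8L, 24L))      # nz = Z*C*T = 24
  expect_equal(h$ints[24], 24L * 32L)            # extended header bytes
  expect_equal(h$ints[25:26], c(3L, 2L))         # nC, nT
  # 16-bit voxel payload independently decoded for one known plane
  con <- file(path, "rb"); on.exit(close(con), add = TRUE)
  invisible(readBin(con, "raw", n = 1024L + h$ints[24]))
  praw <- readBin(con, "raw", n = 2L * 48L)
  first_plane <- as.integer(praw[seq(1, 96, 2)]) +
    256L * as.integer(praw[seq(2, 96, 2)])
  ds <- random_dataset(2, 3, 4, 8, 6)
  expect_equal(first_plane, as.vector(t(ds$data[1, 1, 1, , ])))
})

test_that("write then read round-trips voxels and metadata for random shapes", {
  path <- withr::local_tempfile(fileext = ".dv")
  shapes <- list(c(1, 1, 1, 4, 4), c(1, 3, 8, 16, 12), c(2, 2, 3, 5, 7),
                 c(3, 1, 2, 9, 4))
  for (s in shapes) {
    ds <- random_dataset(s[1], s[2], s[3], s[4], s[5], seed = sum(s))
    write_dv(ds, path)
    back <- read_dv(path)
    expect_identical(back$data, ds$data)
    expect_equal(back$wavelengths_nm, ds$wavelengths_nm, tolerance = 1e-6)
    expect_equal(back$plane_metadata$x_um, ds$plane_metadata$x_um,
                 tolerance = 1e-6)
    expect_equal(back$plane_metadata$timestamp_s,
                 ds$plane_metadata$timestamp_s, tolerance = 1e-6)
    expect_equal(back$pixel_size_um, ds$pixel_size_um, tolerance = 1e-6)
  }
})

test_that("the writer is deterministic to the byte", {
  p1 <- withr::local_tempfile(fileext = ".dv")
  p2 <- withr::local_tempfile(fileext = ".dv")
  ds <- random_dataset(2, 2, 2, 6, 6)
  write_dv(ds, p1)
  write_dv(ds, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a plain mode-6 MRC2014 file with no extended header is readable", {
  # written here with raw writeBin only: an independent minimal writer
  path <- withr::local_tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  vox <- sample.int(65536L, 3 * 4 * 2, replace = TRUE) - 1L
  writeBin(as.integer(c(3, 4, 2, 6, 0, 0, 0, 3, 4, 2)), con, size = 4,
           endian = "little")
  writeBin(c(3, 4, 2, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(c(min(vox), max(vox), mean(vox)), con, size = 4, endian = "little")
  writeBin(rep(0L, 29), con, size = 4, endian = "little")  # w23-51 incl. nsymbt 0
  writeBin(0L, con, size = 4, endian = "little")           # w52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(c(0, 0), con, size = 4, endian = "little")      # rms, nlabl
  writeBin(raw(800), con)
  lo <- as.raw(vox %% 256L); hi <- as.raw(vox %/% 256L)
  writeBin(as.vector(rbind(lo, hi)), con)
  close(con)
  ds <- read_dv(path)
  expect_equal(dim(ds$data), c(1L, 1L, 2L, 4L, 3L))
  expect_equal(as.vector(t(ds$data[1, 1, 1, , ])), vox[1:12])
  expect_equal(ds$wavelengths_nm, 0)
  expect_true(validate_dv(path)$valid)
})

test_that("malformed files are rejected with precise messages", {
  path <- withr::local_tempfile(fileext = ".dv")
  ds <- random_dataset(2, 3, 2, 4, 4)
  write_dv(ds, path)
  bytes <- readBin(path, "raw", file.size(path))
  # truncation
  writeBin(bytes[1:1500], path)
  expect_error(read_dv(path), "truncated")
  # nz not divisible by C*T
  bad <- bytes
  bad[9:12] <- writeBin(11L, raw(), size = 4, endian = "little")
  writeBin(bad, path)
  expect_error(read_dv(path), "not divisible")
  # wrong mode
  bad <- bytes
  bad[13:16] <- writeBin(2L, raw(), size = 4, endian = "little")
  writeBin(bad, path)
  expect_error(read_dv(path), "mode")
  # unknown sequence code
  bad <- bytes
  bad[113:116] <- writeBin(7L, raw(), size = 4, endian = "little")
  writeBin(bad, path)
  expect_error(read_dv(path), "sequence code")
  writeBin(raw(100), path)
  expect_error(read_dv(path), "1024-byte header")
})

test_that("validate_dv reports violations without raising", {
  path <- withr::local_tempfile(fileext = ".dv")
  write_dv(random_dataset(1, 2, 3, 4, 4), path)
  expect_true(validate_dv(path)$valid)
  bytes <- readBin(path, "raw", file.size(path))
  bad <- bytes
  bad[13:16] <- writeBin(1L, raw(), size = 4, endian = "little")  # mode
  writeBin(bad, path)
  rep <- validate_dv(path)
  expect_false(rep$valid)
  expect_match(rep$violations, "mode", all = FALSE)
  # extended header length not a multiple of the record size
  bad <- bytes
  bad[93:96] <- writeBin(33L, raw(), size = 4, endian = "little")
  writeBin(bad, path)
  rep <- validate_dv(path)
  expect_match(rep$violations, "not a multiple", all = FALSE)
  # corrupted magic
  bad <- bytes
  bad[209] <- as.raw(0)
  writeBin(bad, path)
  expect_match(validate_dv(path)$violations, "MAP", all = FALSE)
})

test_that("zero-sized datasets are rejected at construction", {
  expect_error(dv_dataset(array(0L, dim = c(1, 1, 0, 4, 4))), "zero-sized")
})
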