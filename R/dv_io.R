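# '.dv' dialect of the MRC2014 volume format.
#
# File layout (little-endian on write; big-endian accepted on read via the
# machine stamp):
#   bytes 0-1023    main header, MRC2014 word layout:
#     words 1-3     nx, ny, nz          (nz = Z * C * T)
#     word  4       mode                (always 6: 16-bit unsigned)
#     words 5-7     nxstart/nystart/nzstart (0)
#     words 8-10    mx, my, mz
#     words 11-13   cella: nx*px_x, ny*px_y, nz*px_z  (micrometres)
#     words 14-16   cellb: 90, 90, 90
#     words 17-19   mapc, mapr, maps = 1, 2, 3
#     words 20-22   dmin, dmax, dmean
#     word  23      ispg (0: image stack)
#     word  24      nsymbt: extended header length in bytes
#     word  25      dialect: number of wavelengths (C)
#     word  26      dialect: number of timepoints (T)
#     word  27      exttyp, 4 chars: "SCPK"
#     word  28      nversion: 20140
#     word  29      dialect: image sequence code (0 = "ZWT": Z fastest,
#                   then wavelength/channel, then time)
#     words 30-34   dialect: wavelengths (nm) of up to 5 channels
#     words 35-39   dialect: exposure (ms) of up to 5 channels
#     words 50-52   origin x, y, z (stage origin, micrometres)
#     word  53      map magic "MAP "
#     word  54      machine stamp (0x44 0x44 0x00 0x00 little-endian)
#     word  55      rms
#     word  56      nlabl; then 10 x 80-char labels
#   then nsymbt bytes of extended header: one 32-byte record per plane, in
#   file plane order, of 8 float32: stage x, y, z (um), timestamp (s),
#   plane min, max, mean, reserved (0)
#   then plane data, 16-bit unsigned, x fastest within a plane.

DV_PLANE_RECORD_BYTES <- 32L
DV_MODE_UINT16 <- 6L

#' A 5D acquisition dataset
#'
#' @param data integer array of dim `(T, C, Z, Y, X)`, 16-bit unsigned
#'   intensities.
#' @param pixel_size_um `(x, y, z)` voxel spacing, micrometres.
#' @param wavelengths_nm numeric vector of length C.
#' @param exposure_ms numeric vector of length C.
#' @param stage_origin_um a [macro_position()].
#' @param plane_metadata data frame with one row per plane in file order (Z
#'   fastest, then channel, then time) and columns `x_um`, `y_um`, `z_um`,
#'   `timestamp_s`; defaults to zeros.
#' @param channel_names optional character vector of length C.
#' @return object of class `dv_dataset`.
#' @export
dv_dataset <- function(data, pixel_size_um = c(1, 1, 1),
                       wavelengths_nm = NULL, exposure_ms = NULL,
                       stage_origin_um = macro_position(),
                       plane_metadata = NULL, channel_names = NULL) {
  stopifnot(length(dim(data)) == 5L)
  d <- dim(data)
  if (any(d < 1L)) stop("validation error: zero-sized dataset")
  storage.mode(data) <- "integer"
  nC <- d[2]
  if (is.null(wavelengths_nm)) wavelengths_nm <- rep(0, nC)
  if (is.null(exposure_ms)) exposure_ms <- rep(0, nC)
  stopifnot(length(wavelengths_nm) == nC, length(exposure_ms) == nC)
  nplanes <- d[1] * d[2] * d[3]
  if (is.null(plane_metadata))
    plane_metadata <- data.frame(x_um = rep(0, nplanes), y_um = 0, z_um = 0,
                                 timestamp_s = 0)
  stopifnot(nrow(plane_metadata) == nplanes)
  structure(list(data = data, pixel_size_um = as.numeric(pixel_size_um),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 exposure_ms = as.numeric(exposure_ms),
                 stage_origin_um = stage_origin_um,
                 plane_metadata = plane_metadata,
                 channel_names = channel_names),
            class = "dv_dataset")
}

#' @export
print.dv_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dv dataset T=%d C=%d Z=%d %dx%d px, voxel %.3g x %.3g x %.3g um>\n",
              d[1], d[2], d[3], d[5], d[4],
              x$pixel_size_um[1], x$pixel_size_um[2], x$pixel_size_um[3]))
  invisible(x)
}

#' @export
dim.dv_dataset <- function(x) dim(x$data)

# ---- low-level binary helpers --------------------------------------------

write_u16 <- function(con, values) {
  v <- as.integer(values)
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  writeBin(as.vector(rbind(lo, hi)), con)
}

read_u16 <- function(raw) {
  n <- length(raw) %/% 2L
  as.integer(raw[seq(1L, 2L * n, 2L)]) + 256L * as.integer(raw[seq(2L, 2L * n, 2L)])
}

swap4 <- function(raw) {
  n <- length(raw) %/% 4L
  idx <- rep(seq(0L, 4L * (n - 1L), 4L), each = 4L) + c(4L, 3L, 2L, 1L)
  raw[idx]
}

# file plane index (1-based) for (t, c, z) all 1-based, order Z fastest
dv_plane_index <- function(t, c, z, nZ, nC) z + nZ * (c - 1L) + nZ * nC * (t - 1L)

#' Write a dataset as a '.dv' file
#'
#' The writer is deterministic: the same dataset yields a byte-identical
#' file. Planes are written Z-fastest, then channel, then time, as recorded
#' in the header's image-sequence field.
#'
#' @param dataset a [dv_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dv <- function(dataset, path) {
  stopifnot(inherits(dataset, "dv_dataset"))
  d <- dim(dataset$data)           # (T, C, Z, Y, X)
  nT <- d[1]; nC <- d[2]; nZ <- d[3]; ny <- d[4]; nx <- d[5]
  nz_file <- nT * nC * nZ
  con <- file(path, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok && file.exists(path)) unlink(path)
  })
  vals <- dataset$data
  dmin <- min(vals); dmax <- max(vals); dmean <- mean(vals)
  px <- dataset$pixel_size_um
  writeBin(as.integer(c(nx, ny, nz_file, DV_MODE_UINT16, 0L, 0L, 0L,
                        nx, ny, nz_file)), con, size = 4, endian = "little")
  writeBin(c(nx * px[1], ny * px[2], nz_file * px[3], 90, 90, 90), con,
           size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(c(dmin, dmax, dmean), con, size = 4, endian = "little")
  nsymbt <- nz_file * DV_PLANE_RECORD_BYTES
  writeBin(c(0L, nsymbt, nC, nT), con, size = 4, endian = "little")  # w23-26
  writeChar("SCPK", con, nchars = 4, eos = NULL)                     # w27
  writeBin(c(20140L, 0L), con, size = 4, endian = "little")          # w28-29
  wl <- ex <- rep(0, 5)
  wl[seq_len(min(nC, 5))] <- dataset$wavelengths_nm[seq_len(min(nC, 5))]
  ex[seq_len(min(nC, 5))] <- dataset$exposure_ms[seq_len(min(nC, 5))]
  writeBin(wl, con, size = 4, endian = "little")                     # w30-34
  writeBin(ex, con, size = 4, endian = "little")                     # w35-39
  writeBin(rep(0L, 10), con, size = 4, endian = "little")            # w40-49
  org <- dataset$stage_origin_um
  writeBin(c(org$x_um, org$y_um, org$z_um), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  rms <- sd(as.numeric(vals))
  if (!is.finite(rms)) rms <- 0
  writeBin(rms, con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")                     # nlabl
  label <- "scopekit dv writer"
  writeChar(formatC(label, width = 80, flag = "-"), con, nchars = 80, eos = NULL)
  writeBin(raw(9L * 80L), con)
  # extended header: per-plane records in file order
  pm <- dataset$plane_metadata
  for (p in seq_len(nz_file)) {
    t <- (p - 1L) %/% (nZ * nC) + 1L
    c <- ((p - 1L) %/% nZ) %% nC + 1L
    z <- (p - 1L) %% nZ + 1L
    plane <- dataset$data[t, c, z, , ]
    writeBin(c(pm$x_um[p], pm$y_um[p], pm$z_um[p], pm$timestamp_s[p],
               min(plane), max(plane), mean(plane), 0), con,
             size = 4, endian = "little")
  }
  for (p in seq_len(nz_file)) {
    t <- (p - 1L) %/% (nZ * nC) + 1L
    c <- ((p - 1L) %/% nZ) %% nC + 1L
    z <- (p - 1L) %% nZ + 1L
    plane <- dataset$data[t, c, z, , , drop = TRUE]
    if (is.null(dim(plane))) plane <- matrix(plane, nrow = ny, ncol = nx)
    write_u16(con, as.vector(t(plane)))  # x fastest
  }
  ok <- TRUE
  invisible(path)
}

# decode header bytes defensively: corrupt files may carry nul bytes
safe_ascii <- function(bytes)
  tryCatch(rawToChar(bytes), error = function(e) "")

parse_dv_header <- function(raw1024) {
  machst <- raw1024[213:216]
  big <- identical(as.integer(machst[1]), 0x11L)
  getal <- if (big) function(r) swap4(r) else identity
  ints <- function(i) readBin(getal(raw1024[(4 * (i[1] - 1) + 1):(4 * i[length(i)])]),
                              "integer", n = length(i), size = 4, endian = "little")
  flts <- function(i) readBin(getal(raw1024[(4 * (i[1] - 1) + 1):(4 * i[length(i)])]),
                              "double", n = length(i), size = 4, endian = "little")
  list(nx = ints(1), ny = ints(2), nz = ints(3), mode = ints(4),
       mx = ints(8), my = ints(9), mz = ints(10),
       cella = flts(11:13), dmin = flts(20), dmax = flts(21), dmean = flts(22),
       ispg = ints(23), nsymbt = ints(24),
       n_wavelengths = ints(25), n_timepoints = ints(26),
       exttyp = safe_ascii(raw1024[105:108]),
       nversion = ints(28), sequence_code = ints(29),
       wavelengths_nm = flts(30:34), exposure_ms = flts(35:39),
       origin = flts(50:52),
       map = safe_ascii(raw1024[209:212]), machst = machst, big_endian = big,
       rms = flts(55), nlabl = ints(56))
}

#' Read a '.dv' (or plain MRC2014 mode-6) file
#'
#' Reconstructs the 5D `(T, C, Z, Y, X)` array and metadata. A plain
#' MRC2014 file with a zero-length extended header is read as a
#' single-channel, single-timepoint stack with default (empty) optical
#' metadata.
#'
#' @param path file path.
#' @return a [dv_dataset()].
#' @export
read_dv <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 1024)
    stop(sprintf("parse error: file shorter than the 1024-byte header (%d bytes)",
                 if (is.na(info$size)) 0L else info$size))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_dv_header(readBin(con, "raw", n = 1024L))
  if (!identical(hdr$map, "MAP "))
    stop("parse error: missing 'MAP ' magic at byte 208")
  if (hdr$mode != DV_MODE_UINT16)
    stop(sprintf("unsupported mode %d: only mode 6 (16-bit unsigned) is supported",
                 hdr$mode))
  if (hdr$nx < 1 || hdr$ny < 1 || hdr$nz < 1)
    stop("parse error: non-positive image dimensions in header")
  nC <- max(hdr$n_wavelengths, 1L)
  nT <- max(hdr$n_timepoints, 1L)
  if (hdr$nz %% (nC * nT) != 0)
    stop(sprintf("parse error: nz = %d not divisible by channels x timepoints = %d",
                 hdr$nz, nC * nT))
  if (hdr$sequence_code != 0L)
    stop(sprintf("unsupported dialect: unknown image sequence code %d",
                 hdr$sequence_code))
  nZ <- hdr$nz %/% (nC * nT)
  nplanes <- hdr$nz
  have_ext <- hdr$nsymbt > 0L
  if (have_ext && hdr$nsymbt != nplanes * DV_PLANE_RECORD_BYTES)
    stop(sprintf("parse error: extended header length %d != %d planes x %d bytes",
                 hdr$nsymbt, nplanes, DV_PLANE_RECORD_BYTES))
  expected <- 1024 + hdr$nsymbt + 2 * as.numeric(hdr$nx) * hdr$ny * hdr$nz
  if (info$size < expected)
    stop(sprintf("parse error: file truncated at byte %d (expected %d bytes)",
                 info$size, expected))
  pm <- data.frame(x_um = rep(0, nplanes), y_um = 0, z_um = 0, timestamp_s = 0)
  if (have_ext) {
    ext <- readBin(con, "raw", n = hdr$nsymbt)
    if (hdr$big_endian) ext <- swap4(ext)
    recs <- matrix(readBin(ext, "double", n = nplanes * 8L, size = 4,
                           endian = "little"), ncol = 8L, byrow = TRUE)
    pm <- data.frame(x_um = recs[, 1], y_um = recs[, 2], z_um = recs[, 3],
                     timestamp_s = recs[, 4])
  }
  npix <- hdr$nx * hdr$ny
  data <- array(0L, dim = c(nT, nC, nZ, hdr$ny, hdr$nx))
  for (p in seq_len(nplanes)) {
    praw <- readBin(con, "raw", n = 2L * npix)
    if (length(praw) < 2L * npix)
      stop(sprintf("parse error: file truncated inside plane %d", p))
    if (hdr$big_endian) {
      idx <- rep(seq(0L, 2L * (npix - 1L), 2L), each = 2L) + c(2L, 1L)
      praw <- praw[idx]
    }
    v <- read_u16(praw)
    t <- (p - 1L) %/% (nZ * nC) + 1L
    c <- ((p - 1L) %/% nZ) %% nC + 1L
    z <- (p - 1L) %% nZ + 1L
    data[t, c, z, , ] <- matrix(v, nrow = hdr$ny, byrow = TRUE)
  }
  px <- c(hdr$cella[1] / hdr$nx, hdr$cella[2] / hdr$ny, hdr$cella[3] / hdr$nz)
  px[!is.finite(px) | px <= 0] <- 1
  wavelengths <- if (hdr$n_wavelengths >= 1)
    hdr$wavelengths_nm[seq_len(min(nC, 5))] else rep(0, nC)
  exposures <- if (hdr$n_wavelengths >= 1)
    hdr$exposure_ms[seq_len(min(nC, 5))] else rep(0, nC)
  if (length(wavelengths) < nC) wavelengths <- c(wavelengths, rep(0, nC - length(wavelengths)))
  if (length(exposures) < nC) exposures <- c(exposures, rep(0, nC - length(exposures)))
  dv_dataset(data, pixel_size_um = px, wavelengths_nm = wavelengths,
             exposure_ms = exposures,
             stage_origin_um = macro_position(hdr$origin[1], hdr$origin[2],
                                              hdr$origin[3]),
             plane_metadata = pm)
}

#' Validate a '.dv' file
#'
#' Report-based: never raises on a bad file. Checks the map magic and
#' machine stamp, mode, dimension consistency, extended-header length
#' arithmetic and total file size.
#'
#' @param path file path.
#' @return list with elements `valid` (logical) and `violations`
#'   (character vector, empty when clean).
#' @export
validate_dv <- function(path) {
  violations <- character(0)
  note <- function(msg) violations <<- c(violations, msg)
  info <- file.info(path)
  if (is.na(info$size)) {
    return(list(valid = FALSE, violations = "file does not exist"))
  }
  if (info$size < 1024) {
    return(list(valid = FALSE,
                violations = sprintf("file shorter than 1024-byte header (%d bytes)",
                                     info$size)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_dv_header(readBin(con, "raw", n = 1024L))
  if (!identical(hdr$map, "MAP ")) note("missing 'MAP ' magic at byte 208")
  ms <- as.integer(hdr$machst[1])
  if (!ms %in% c(0x44L, 0x11L)) note("unknown machine stamp")
  if (hdr$mode != DV_MODE_UINT16)
    note(sprintf("mode is %d, expected 6 (16-bit unsigned)", hdr$mode))
  if (hdr$nx < 1 || hdr$ny < 1 || hdr$nz < 1)
    note("non-positive dimensions nx/ny/nz")
  nC <- max(hdr$n_wavelengths, 1L); nT <- max(hdr$n_timepoints, 1L)
  if (hdr$nz >= 1 && hdr$nz %% (nC * nT) != 0)
    note(sprintf("nz = %d not divisible by channels x timepoints = %d",
                 hdr$nz, nC * nT))
  if (hdr$nsymbt < 0) note("negative extended header length")
  if (hdr$nsymbt %% DV_PLANE_RECORD_BYTES != 0)
    note(sprintf("extended header length %d not a multiple of the %d-byte plane record",
                 hdr$nsymbt, DV_PLANE_RECORD_BYTES))
  else if (hdr$nsymbt > 0 && hdr$nsymbt != hdr$nz * DV_PLANE_RECORD_BYTES)
    note(sprintf("extended header holds %d plane records but nz = %d",
                 hdr$nsymbt %/% DV_PLANE_RECORD_BYTES, hdr$nz))
  if (hdr$nx >= 1 && hdr$ny >= 1 && hdr$nz >= 1 && hdr$nsymbt >= 0) {
    expected <- 1024 + hdr$nsymbt + 2 * as.numeric(hdr$nx) * hdr$ny * hdr$nz
    if (info$size != expected)
      note(sprintf("file size %d != expected %d bytes", info$size, expected))
  }
  list(valid = length(violations) == 0L, violations = violations)
}
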