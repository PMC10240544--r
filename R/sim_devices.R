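#' A stored multi-channel source sample volume
#'
#' In simulation mode the "sample on the stage" is a large multi-channel
#' image; a simulated camera returns the stage-position-defined subregion of
#' the channel selected by the filter wheel, blurred according to defocus.
#'
#' @param data numeric/integer 3D array `(Y, X, channel)` of 16-bit
#'   intensities, or a matrix for a single channel.
#' @param pixel_size_um sample-plane pixel size, micrometres (> 0).
#' @param focus_z_um stage Z of best focus, micrometres.
#' @param origin_um `(x, y)` stage coordinate of pixel `(0, 0)` (top-left).
#' @param nuclei optional ground-truth data frame from
#'   [generate_synthetic_sample()].
#' @return object of class `source_sample`.
#' @export
source_sample <- function(data, pixel_size_um = 1, focus_z_um = 0,
                          origin_um = c(0, 0), nuclei = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, pixel_size_um > 0,
            length(origin_um) == 2L)
  storage.mode(data) <- "integer"
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 focus_z_um = focus_z_um, origin_um = as.numeric(origin_um),
                 nuclei = nuclei),
            class = "source_sample")
}

#' @export
print.source_sample <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<source sample %dx%d px, %d channel(s), %.3g um/px, focus z = %g um>\n",
              d[2], d[1], d[3], x$pixel_size_um, x$focus_z_um))
  invisible(x)
}

#' Simulated camera state
#' @param sensor_shape `(height, width)` in pixels.
#' @param pixel_size_um sample-plane scale of one sensor pixel (> 0).
#' @param enabled logical.
#' @return object of class `camera_state`.
#' @export
camera_state <- function(sensor_shape = c(512L, 512L), pixel_size_um = 1,
                         enabled = TRUE) {
  stopifnot(length(sensor_shape) == 2L, all(sensor_shape >= 1),
            pixel_size_um > 0)
  structure(list(sensor_shape = as.integer(sensor_shape),
                 pixel_size_um = pixel_size_um, enabled = isTRUE(enabled)),
            class = "camera_state")
}

#' Simulated filter wheel state
#' @param n_positions number of wheel positions.
#' @param channel_map integer vector of length `n_positions` mapping each
#'   wheel position to a 0-based source channel index.
#' @param position current position, 0-based.
#' @return object of class `filter_wheel_state`.
#' @export
filter_wheel_state <- function(n_positions = 3L, channel_map = NULL,
                               position = 0L) {
  n_positions <- as.integer(n_positions)
  stopifnot(n_positions >= 1L)
  if (is.null(channel_map)) channel_map <- seq_len(n_positions) - 1L
  stopifnot(length(channel_map) == n_positions)
  structure(list(position = as.integer(position) %% n_positions,
                 n_positions = n_positions,
                 channel_map = as.integer(channel_map)),
            class = "filter_wheel_state")
}

#' Set the filter wheel position
#'
#' Positions wrap modulo the number of wheel positions, matching a physical
#' wheel's continuous rotation.
#'
#' @param wheel a [filter_wheel_state()].
#' @param position requested position (any integer; taken modulo
#'   `n_positions`).
#' @return updated wheel state.
#' @export
set_filter <- function(wheel, position) {
  wheel$position <- as.integer(position) %% wheel$n_positions
  wheel
}

# Reference exposure giving unit intensity gain at full light power.
REFERENCE_EXPOSURE_MS <- 100

#' Acquire one simulated camera frame
#'
#' Cuts the sensor-shaped subregion of the selected source channel centred
#' at the stage `(x, y)` position, applies a defocus blur of sigma
#' `blur_coeff * |z - focus_z|` pixels (Gaussian; sigma 0 means no
#' convolution), and scales intensity linearly with exposure and light power
#' (unit gain at 100 ms and power 1), clipping at the 16-bit ceiling.
#' Regions outside the source sample are filled with background value 0.
#'
#' Coordinate convention (used package-wide): stage +x runs along image
#' columns, +y along rows; pixel `(0, 0)` is top-left; the stage position
#' addresses the centre pixel `(floor(h/2), floor(w/2))` of the sensor.
#'
#' @param sample a [source_sample()].
#' @param camera a [camera_state()]; must be enabled.
#' @param stage_xyz_um numeric `(x, y, z)` stage position in micrometres.
#' @param wheel a [filter_wheel_state()] selecting the channel.
#' @param exposure_ms exposure time, milliseconds (> 0).
#' @param light_power light power fraction in `[0, 1]`.
#' @param blur_coeff defocus blur coefficient, sigma pixels per micrometre
#'   of defocus (default 0.5).
#' @return integer matrix `(height, width)`, values in `[0, 65535]`.
#' @export
acquire <- function(sample, camera, stage_xyz_um, wheel,
                    exposure_ms = REFERENCE_EXPOSURE_MS, light_power = 1,
                    blur_coeff = 0.5) {
  if (!isTRUE(camera$enabled)) stop("acquisition error: camera is disabled")
  if (!is.numeric(exposure_ms) || exposure_ms <= 0)
    stop("validation error: exposure_ms must be positive")
  stopifnot(length(stage_xyz_um) == 3L)
  ch <- wheel$channel_map[wheel$position + 1L] + 1L
  nch <- dim(sample$data)[3]
  if (ch < 1L || ch > nch)
    stop(sprintf("filter position maps to channel %d but sample has %d channels",
                 ch - 1L, nch))
  h <- camera$sensor_shape[1]; w <- camera$sensor_shape[2]
  px <- camera$pixel_size_um
  # fractional pixel index of the stage position in the source image
  jc <- (stage_xyz_um[1] - sample$origin_um[1]) / sample$pixel_size_um
  ic <- (stage_xyz_um[2] - sample$origin_um[2]) / sample$pixel_size_um
  cols <- round(jc) - floor(w / 2) + seq_len(w) - 1  # 0-based source cols
  rows <- round(ic) - floor(h / 2) + seq_len(h) - 1
  ny <- dim(sample$data)[1]; nx <- dim(sample$data)[2]
  out <- matrix(0, nrow = h, ncol = w)
  rok <- which(rows >= 0 & rows < ny)
  cok <- which(cols >= 0 & cols < nx)
  if (length(rok) && length(cok))
    out[rok, cok] <- sample$data[rows[rok] + 1L, cols[cok] + 1L, ch]
  sigma <- blur_coeff * abs(stage_xyz_um[3] - sample$focus_z_um)
  if (sigma > 0)
    out <- EBImage::gblur(out, sigma = sigma, boundary = "replicate")
  scale <- light_power * exposure_ms / REFERENCE_EXPOSURE_MS
  out <- round(out * scale)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  storage.mode(out) <- "integer"
  out
}

#' Generate a synthetic multi-channel source sample
#'
#' Emulates the large packaged demonstration sample: channel 0 carries
#' anti-aliased filled disks ("nuclei") at known positions on a
#' low-intensity background with additive Gaussian noise; further channels
#' carry a smooth deterministic texture plus noise so that defocus effects
#' are observable on every channel. Ground-truth disk centres are attached
#' as the `nuclei` element of the returned sample.
#'
#' @param width,height sample size in pixels.
#' @param n_channels number of channels (>= 1).
#' @param nuclei data frame with columns `x_px`, `y_px` (0-based centre),
#'   `radius_px` (> 0) and `peak` (intensity above background); may have
#'   zero rows.
#' @param seed integer seed; the generator is deterministic for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @param background background intensity level.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param pixel_size_um,focus_z_um,origin_um passed to [source_sample()].
#' @return a [source_sample()] with ground truth in `$nuclei`.
#' @export
generate_synthetic_sample <- function(width, height, n_channels = 1L,
                                      nuclei = NULL, seed = 1L,
                                      background = 200, noise_sd = 50,
                                      pixel_size_um = 1, focus_z_um = 0,
                                      origin_um = c(0, 0)) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 1L, height >= 1L, n_channels >= 1L)
  if (is.null(nuclei))
    nuclei <- data.frame(x_px = numeric(0), y_px = numeric(0),
                         radius_px = numeric(0), peak = numeric(0))
  if (nrow(nuclei)) {
    if (any(nuclei$radius_px <= 0))
      stop("validation error: all disk radii must be positive")
    if (any(nuclei$x_px - nuclei$radius_px < 0 |
            nuclei$x_px + nuclei$radius_px > width - 1 |
            nuclei$y_px - nuclei$radius_px < 0 |
            nuclei$y_px + nuclei$radius_px > height - 1))
      stop("validation error: disk extends outside the sample bounds")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  data <- array(0L, dim = c(height, width, n_channels))
  for (c in seq_len(n_channels)) {
    plane <- background + matrix(rnorm(height * width, sd = noise_sd),
                                 height, width)
    if (c == 1L && nrow(nuclei)) {
      for (k in seq_len(nrow(nuclei))) {
        cx <- nuclei$x_px[k]; cy <- nuclei$y_px[k]
        r <- nuclei$radius_px[k]; peak <- nuclei$peak[k]
        j0 <- max(0, floor(cx - r - 1)); j1 <- min(width - 1, ceiling(cx + r + 1))
        i0 <- max(0, floor(cy - r - 1)); i1 <- min(height - 1, ceiling(cy + r + 1))
        jj <- j0:j1; ii <- i0:i1
        dist <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`))
        cover <- pmin(pmax(r + 0.5 - dist, 0), 1)  # anti-aliased edge
        plane[ii + 1L, jj + 1L] <- plane[ii + 1L, jj + 1L] + peak * cover
      }
    } else if (c > 1L) {
      # smooth deterministic texture so non-primary channels are non-constant
      xx <- matrix(seq_len(width), height, width, byrow = TRUE)
      yy <- matrix(seq_len(height), height, width)
      plane <- plane + 300 * (1 + sin(2 * pi * xx / (40 + 13 * c)) *
                                  cos(2 * pi * yy / (57 + 7 * c))) / 2
    }
    plane <- round(plane)
    plane[plane < 0] <- 0
    plane[plane > 65535] <- 65535
    data[, , c] <- as.integer(plane)
  }
  source_sample(data, pixel_size_um = pixel_size_um, focus_z_um = focus_z_um,
                origin_um = origin_um, nuclei = nuclei)
}

#' Load a source sample from a multi-page TIFF
#'
#' One TIFF page per channel; pages must share the same size. Intensities
#' are rescaled from the TIFF's [0, 1] convention to 16-bit.
#'
#' @param path TIFF path.
#' @inheritParams source_sample
#' @return a [source_sample()].
#' @export
load_source_sample <- function(path, pixel_size_um = 1, focus_z_um = 0,
                               origin_um = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse RGB to first plane
    round(p * 65535)
  })
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("all TIFF pages must share the same dimensions")
  data <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (c in seq_along(pages)) data[, , c] <- as.integer(pages[[c]])
  source_sample(data, pixel_size_um = pixel_size_um, focus_z_um = focus_z_um,
                origin_um = origin_um)
}
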