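# Built-in simulated device types. Each constructor returns the handlers
# the device exposes plus an environment holding its live state, so that
# execution can mutate device state in place while the depot object itself
# stays immutable.

sim_stage_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  axes <- list()
  handlers <- list()
  dims <- strsplit(as.character(setting(settings, "axes", default = "xyz")),
                   "")[[1]]
  if (!all(dims %in% c("x", "y", "z")))
    stop(sprintf("invalid axes setting '%s' for stage '%s'",
                 paste(dims, collapse = ""), name), call. = FALSE)
  for (d in dims) {
    lo <- num_setting(settings, paste0(d, "_min"),
                      default = if (d == "z") -100 else -25000)
    hi <- num_setting(settings, paste0(d, "_max"),
                      default = if (d == "z") 100 else 25000)
    h <- handler(sprintf("%s:%s", name, d), "stage_axis", name,
                 analogue_line = if (d == "z")
                   num_setting(settings, "z_analogue_line", default = 0) else NULL)
    handlers[[h$name]] <- h
    axes[[h$name]] <- axis_state(h, d, position_um = 0, limits_um = c(lo, hi),
                                 rank = 0L)
  }
  st$axes <- axes
  list(handlers = handlers, state = st)
}

sim_piezo_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  range_um <- num_setting(settings, "range_um", default = 100)
  h <- handler(sprintf("%s:z", name), "stage_axis", name,
               analogue_line = num_setting(settings, "analogue_line",
                                           default = 1))
  st$axes <- list(axis_state(h, "z", position_um = 0,
                             limits_um = c(-range_um / 2, range_um / 2),
                             rank = 1L))
  names(st$axes) <- h$name
  list(handlers = list(h), state = st)
}

sim_camera_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  w <- as.integer(num_setting(settings, "width", default = 512))
  h_px <- as.integer(num_setting(settings, "height", default = 512))
  px <- num_setting(settings, "pixel_size_um", default = 1)
  st$camera <- camera_state(c(h_px, w), pixel_size_um = px)
  src <- setting(settings, "source")
  if (!is.null(src)) {
    st$sample <- load_source_sample(src, pixel_size_um = px)
  } else {
    seed <- as.integer(num_setting(settings, "sample_seed", default = 42))
    sw <- as.integer(num_setting(settings, "sample_width", default = 1200))
    sh <- as.integer(num_setting(settings, "sample_height", default = 1200))
    nc <- as.integer(num_setting(settings, "sample_channels", default = 4))
    st$sample <- default_demo_sample(sw, sh, nc, seed = seed,
                                     pixel_size_um = px)
  }
  hd <- handler(sprintf("%s:sensor", name), "camera", name,
                digital_line = num_setting(settings, "digital_line",
                                           default = 2))
  list(handlers = list(hd), state = st)
}

sim_laser_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  st$wavelength_nm <- num_setting(settings, "wavelength_nm", default = 488)
  st$on <- FALSE
  st$power <- 1
  hs <- handler(sprintf("%s:source", name), "light_source", name,
                digital_line = num_setting(settings, "digital_line",
                                           default = 1))
  hp <- handler(sprintf("%s:power", name), "light_power", name,
                analogue_line = num_setting(settings, "power_analogue_line",
                                            default = 3))
  list(handlers = list(hs, hp), state = st)
}

sim_filterwheel_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  n <- as.integer(num_setting(settings, "n_positions", default = 4))
  map <- setting(settings, "channel_map")
  map <- if (is.null(map)) seq_len(n) - 1L
         else as.integer(strsplit(as.character(map), ",")[[1]])
  st$wheel <- filter_wheel_state(n, map)
  h <- handler(sprintf("%s:position", name), "filter_wheel", name,
               analogue_line = num_setting(settings, "analogue_line",
                                           default = 2))
  list(handlers = list(h), state = st)
}

sim_executor_ctor <- function(name, settings) {
  st <- new.env(parent = emptyenv())
  st$settle_us <- as.integer(num_setting(settings, "settle_us", default = 1000))
  st$readout_us <- as.integer(num_setting(settings, "readout_us",
                                          default = 10000))
  h <- handler(sprintf("%s:trigger", name), "executor", name)
  list(handlers = list(h), state = st)
}

register_builtin_devices <- function() {
  register_device_type("sim_stage", sim_stage_ctor)
  register_device_type("sim_piezo", sim_piezo_ctor)
  register_device_type("sim_camera", sim_camera_ctor)
  register_device_type("sim_laser", sim_laser_ctor)
  register_device_type("sim_filterwheel", sim_filterwheel_ctor)
  register_device_type("sim_executor", sim_executor_ctor)
}

# Demonstration sample used when no source image is configured: a field of
# disk-like "nuclei" in channel 0 plus textured secondary channels.
default_demo_sample <- function(width = 1200, height = 1200, n_channels = 4,
                                seed = 42, pixel_size_um = 1) {
  nuclei <- plant_nuclei(width, height, n = 15, radius_range = c(15, 25),
                         peak_range = c(2500, 3500), margin = 60,
                         seed = seed)
  generate_synthetic_sample(width, height, n_channels, nuclei, seed = seed,
                            background = 200, noise_sd = 50,
                            pixel_size_um = pixel_size_um)
}

#' Randomly place non-overlapping disks for a synthetic sample
#'
#' Rejection-samples disk centres so that disks keep `margin` pixels from
#' the image border and at least one diameter between centres.
#'
#' @param width,height sample size in pixels.
#' @param n number of disks.
#' @param radius_range `(min, max)` radius in pixels.
#' @param peak_range `(min, max)` peak intensity above background.
#' @param margin minimum distance from any border, pixels.
#' @param seed integer seed (caller RNG state is preserved).
#' @return data frame with columns `x_px`, `y_px`, `radius_px`, `peak`.
#' @export
plant_nuclei <- function(width, height, n, radius_range = c(15, 25),
                         peak_range = c(2500, 3500), margin = 60, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  xs <- ys <- rs <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < 20000L) {
    tries <- tries + 1L
    r <- runif(1, radius_range[1], radius_range[2])
    x <- runif(1, margin, width - 1 - margin)
    y <- runif(1, margin, height - 1 - margin)
    if (length(xs) == 0L ||
        all(sqrt((xs - x)^2 + (ys - y)^2) > 2 * (rs + r))) {
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }
  }
  if (length(xs) < n)
    stop(sprintf("could only place %d of %d disks", length(xs), n))
  data.frame(x_px = xs, y_px = ys, radius_px = rs,
             peak = runif(n, peak_range[1], peak_range[2]))
}

#' Default simulated depot configuration
#'
#' With no configuration to specific hardware the system starts in
#' simulation mode: an XYZ stage, a camera imaging a synthetic
#' multi-channel sample, one laser, a 4-position filter wheel, and a
#' software trigger executor. A nested fine Z stage can be added with the
#' `sim_piezo` device type.
#'
#' @param sample_seed seed for the built-in demonstration sample.
#' @return list of [device_config()] objects.
#' @export
default_sim_config <- function(sample_seed = 42) {
  list(
    device_config("stage", "sim_stage"),
    device_config("camera", "sim_camera", sample_seed = sample_seed),
    device_config("laser488", "sim_laser", wavelength_nm = 488),
    device_config("wheel", "sim_filterwheel"),
    device_config("executor", "sim_executor"))
}

#' Build the default simulated depot
#' @inheritParams default_sim_config
#' @return a `scope_depot`.
#' @export
default_sim_depot <- function(sample_seed = 42)
  build_depot(default_sim_config(sample_seed))

#' Set the filter wheel position of a depot's wheel device
#'
#' @param depot a `scope_depot`.
#' @param position requested wheel position (wraps modulo the wheel size).
#' @return the depot, invisibly.
#' @export
set_depot_filter <- function(depot, position) {
  whs <- handlers_of_kind(depot, "filter_wheel")
  if (length(whs) == 0L) stop("depot has no filter wheel", call. = FALSE)
  st <- device_state(depot, whs[[1]]$device_name)
  st$wheel <- set_filter(st$wheel, position)
  invisible(depot)
}

#' Replace the source sample of a depot's simulated camera
#'
#' @param depot a `scope_depot`.
#' @param sample a [source_sample()].
#' @param camera_name optional camera device name (defaults to the first
#'   camera).
#' @return the depot, invisibly.
#' @export
set_camera_sample <- function(depot, sample, camera_name = NULL) {
  stopifnot(inherits(sample, "source_sample"))
  cam <- if (is.null(camera_name)) find_camera_device(depot)
         else get_handler(depot, camera_name)
  st <- device_state(depot, cam$device_name)
  st$sample <- sample
  invisible(depot)
}

#' Snap one image with the depot's current state
#'
#' Convenience acquisition at unit gain (100 ms reference exposure, full
#' light power) from the first camera, at the current macro stage position
#' and filter wheel setting.
#'
#' @param depot a `scope_depot`.
#' @param exposure_ms exposure, milliseconds.
#' @param blur_coeff defocus blur coefficient.
#' @return integer image matrix.
#' @export
snap <- function(depot, exposure_ms = REFERENCE_EXPOSURE_MS,
                 blur_coeff = 0.5) {
  cam <- find_camera_device(depot)
  st <- device_state(depot, cam$device_name)
  pos <- depot_position(depot)
  acquire(st$sample, st$camera, c(pos$x_um, pos$y_um, pos$z_um),
          wheel_state_of(depot), exposure_ms = exposure_ms,
          blur_coeff = blur_coeff)
}
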