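# Shared fixtures: everything is generated in code at test time.

# Small simulated depot: 32x32 sensor over a 300x300 2-channel sample with
# three planted disks, for fast end-to-end runs.
small_depot <- function(sample = NULL, sensor = 32L) {
  cfg <- list(
    device_config("stage", "sim_stage"),
    device_config("camera", "sim_camera", width = sensor, height = sensor),
    device_config("laser488", "sim_laser", wavelength_nm = 488),
    device_config("wheel", "sim_filterwheel", n_positions = 2,
                  channel_map = "0,1"),
    device_config("executor", "sim_executor"))
  depot <- build_depot(cfg)
  if (is.null(sample))
    sample <- generate_synthetic_sample(
      300, 300, 2,
      data.frame(x_px = c(80, 200, 150), y_px = c(90, 120, 230),
                 radius_px = c(12, 15, 10), peak = 3000),
      seed = 99, noise_sd = 30)
  set_camera_sample(depot, sample)
  depot
}

simple_channel <- function(name = "ch", filter = 0L, exposure_ms = 100,
                           power = 1) {
  channel_spec(name, "laser488:source", "camera:sensor",
               filter_position = filter, exposure_ms = exposure_ms,
               light_power_fraction = power)
}

# Independent expanding-spiral oracle: closed-form ring walk. Ring r is
# entered at (r, -(r-1)) and walked north, west, south, east; entirely
# different derivation from the run-length construction in the package.
oracle_spiral <- function(n) {
  out <- matrix(0L, nrow = n, ncol = 2)
  if (n == 1L) return(out)
  k <- 1L
  r <- 1L
  while (k < n) {
    ring <- rbind(
      cbind(r, -(r - 1L):r),          # north edge, entry upward
      cbind((r - 1L):(-r), r),        # west along the top
      cbind(-r, (r - 1L):(-r)),       # south down the left side
      cbind((-r + 1L):r, -r))         # east along the bottom
    take <- min(nrow(ring), n - k)
    out[(k + 1L):(k + take), ] <- ring[seq_len(take), ]
    k <- k + take
    r <- r + 1L
  }
  out
}

# Direct subregion crop oracle, independent index arithmetic (1-based).
oracle_crop <- function(sample, channel0, x_um, y_um, sensor) {
  px <- sample$pixel_size_um
  jc <- round((x_um - sample$origin_um[1]) / px)
  ic <- round((y_um - sample$origin_um[2]) / px)
  rows <- ic - floor(sensor / 2) + seq_len(sensor)      # 1-based
  cols <- jc - floor(sensor / 2) + seq_len(sensor)
  out <- matrix(0L, sensor, sensor)
  rok <- rows >= 1 & rows <= dim(sample$data)[1]
  cok <- cols >= 1 & cols <= dim(sample$data)[2]
  out[rok, cok] <- sample$data[rows[rok], cols[cok], channel0 + 1L]
  out
}

make_axes <- function(piezo_range = 100, coarse_range = c(-1000, 1000)) {
  hx <- handler("stage:x", "stage_axis", "stage")
  hy <- handler("stage:y", "stage_axis", "stage")
  hz <- handler("stage:z", "stage_axis", "stage")
  hp <- handler("piezo:z", "stage_axis", "piezo")
  list(axis_state(hx, "x", 0, coarse_range, 0L),
       axis_state(hy, "y", 0, coarse_range, 0L),
       axis_state(hz, "z", 0, coarse_range, 0L),
       axis_state(hp, "z", 0, c(-piezo_range / 2, piezo_range / 2), 1L))
}

expect_position_equal <- function(pos, x, y, z, tol = 1e-9) {
  expect_equal(pos$x_um, x, tolerance = tol)
  expect_equal(pos$y_um, y, tolerance = tol)
  expect_equal(pos$z_um, z, tolerance = tol)
}
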