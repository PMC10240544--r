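count_rising <- function(tab, kind_lines)
  sum(tab$type == "digital" & tab$value == 1 & tab$line %in% kind_lines)

test_that("a minimal experiment compiles to one edge of each kind", {
  depot <- small_depot()
  tab <- compile_experiment(experiment_spec(simple_channel()), depot)
  expect_equal(count_rising(tab, attr(tab, "camera_lines")), 1L)
  expect_equal(count_rising(tab, attr(tab, "light_lines")), 1L)
  expect_equal(sum(tab$line == attr(tab, "z_line")), 1L)
})

test_that("camera edges count T x C x Z and the Z staircase is exact", {
  depot <- small_depot()
  spec <- experiment_spec(list(simple_channel("a", 0L), simple_channel("b", 1L)),
                          z_start_um = 10, z_step_um = 0.5, n_slices = 5,
                          n_timepoints = 3, interval_ms = 5000)
  tab <- compile_experiment(spec, depot)
  expect_equal(count_rising(tab, attr(tab, "camera_lines")), 30L)
  zvals <- tab$value[tab$line == attr(tab, "z_line")]
  expect_equal(length(zvals), 15L)            # one analogue event per (t, z)
  expect_equal(unique(zvals), c(10, 10.5, 11, 11.5, 12))  # 5 levels per t
  expect_equal(sort(unique(zvals)), seq(10, 12, by = 0.5))
})

test_that("compilation is deterministic and validates cleanly", {
  depot <- small_depot()
  spec <- experiment_spec(list(simple_channel("a", 0L), simple_channel("b", 1L)),
                          z_step_um = 1, n_slices = 3, n_timepoints = 2,
                          interval_ms = 2000)
  t1 <- compile_experiment(spec, depot)
  t2 <- compile_experiment(spec, depot)
  expect_identical(t1, t2)
  rep <- validate_table(t1, depot)
  expect_true(rep$valid)
  expect_length(rep$violations, 0L)
})

test_that("random valid specs satisfy the counting and edge invariants", {
  depot <- small_depot()
  set.seed(31)
  for (k in 1:25) {
    nT <- sample(1:4, 1); nC <- sample(1:2, 1); nZ <- sample(1:12, 1)
    chs <- lapply(seq_len(nC), function(i)
      simple_channel(paste0("c", i), i - 1L,
                     exposure_ms = sample(c(10, 25, 50, 100), 1)))
    spec <- experiment_spec(chs, z_start_um = runif(1, -20, 20),
                            z_step_um = runif(1, 0.1, 2), n_slices = nZ,
                            n_timepoints = nT, interval_ms = 10000)
    tab <- suppressWarnings(compile_experiment(spec, depot))
    expect_equal(count_rising(tab, attr(tab, "camera_lines")), nT * nC * nZ)
    expect_false(is.unsorted(tab$time_us))
    expect_equal(length(unique(tab$value[tab$line == attr(tab, "z_line")])),
                 nZ)
    # every digital line ends low
    dig <- tab[tab$type == "digital", ]
    final <- tapply(dig$value, dig$line, function(v) v[length(v)])
    expect_true(all(final == 0))
    expect_true(validate_table(tab)$valid)
  }
})

test_that("validate_table flags malformed tables", {
  expect_true(validate_table(data.frame(time_us = integer(0),
                                        line = character(0),
                                        type = character(0),
                                        value = numeric(0)))$valid)
  bad <- data.frame(time_us = c(10L, 5L), line = "D1", type = "digital",
                    value = c(1, 0))
  expect_match(validate_table(bad)$violations, "non-monotonic time",
               all = FALSE)
  stuck <- data.frame(time_us = c(0L, 5L, 9L), line = "D1", type = "digital",
                      value = c(1, 0, 1))
  expect_match(validate_table(stuck)$violations, "left high", all = FALSE)
  odd <- data.frame(time_us = 0L, line = "A0", type = "analogue", value = NaN)
  expect_match(validate_table(odd)$violations, "non-finite", all = FALSE)
  unknown <- data.frame(time_us = 0L, line = "D99", type = "digital",
                        value = 1)
  expect_match(validate_table(unknown, small_depot())$violations,
               "unknown line", all = FALSE)
})

test_that("execution yields one indexed image per camera rising edge", {
  depot <- small_depot()
  depot_move_to(depot, macro_position(150, 150, 0))
  spec <- experiment_spec(list(simple_channel("a", 0L), simple_channel("b", 1L)),
                          z_start_um = 0, z_step_um = 2, n_slices = 3,
                          n_timepoints = 2, interval_ms = 0)
  tab <- suppressWarnings(compile_experiment(spec, depot))
  recs <- execute_table(tab, depot)
  expect_length(recs, 12L)
  idx <- data.frame(t = vapply(recs, function(r) as.numeric(r$t), numeric(1)),
                    c = vapply(recs, function(r) as.numeric(r$c), numeric(1)),
                    z = vapply(recs, function(r) as.numeric(r$z), numeric(1)))
  expect_setequal(unique(idx$t), 0:1)
  expect_setequal(unique(idx$c), 0:1)
  expect_setequal(unique(idx$z), 0:2)
  expect_equal(nrow(unique(idx)), 12L)
  ts <- vapply(recs, `[[`, numeric(1), "timestamp_us")
  expect_false(is.unsorted(ts))
  # defocus makes slices differ on a non-uniform scene
  z0 <- recs[[which(idx$z == 0 & idx$c == 0 & idx$t == 0)]]$image
  z2 <- recs[[which(idx$z == 2 & idx$c == 0 & idx$t == 0)]]$image
  expect_false(identical(z0, z2))
  expect_gt(var(as.vector(z0)), var(as.vector(z2)))
  # events on unregistered lines are execution errors
  broken <- tab
  broken$line[1] <- "A77"
  expect_error(execute_table(broken, depot), "unregistered line")
})

test_that("run_experiment assembles the 5D dataset and round-trips", {
  depot <- small_depot()
  depot_move_to(depot, macro_position(150, 150, 0))
  path <- withr::local_tempfile(fileext = ".dv")
  spec <- experiment_spec(list(simple_channel("a", 0L), simple_channel("b", 1L,
                                                                       exposure_ms = 50)),
                          z_start_um = -1, z_step_um = 1, n_slices = 4,
                          n_timepoints = 1, save_path = path)
  ds <- run_experiment(spec, depot)
  expect_equal(dim(ds$data), c(1L, 2L, 4L, 32L, 32L))
  expect_true(file.exists(path))
  back <- read_dv(path)
  expect_identical(back$data, ds$data)
  expect_equal(back$exposure_ms, c(100, 50))
  expect_equal(back$wavelengths_nm, c(488, 488))
  expect_equal(back$plane_metadata$z_um, ds$plane_metadata$z_um,
               tolerance = 1e-6)
})

test_that("zero-interval time-lapse spaces timepoints by volume duration", {
  depot <- small_depot()
  spec <- experiment_spec(simple_channel(), n_slices = 2, n_timepoints = 3,
                          interval_ms = 0, z_step_um = 1)
  tab <- suppressWarnings(compile_experiment(spec, depot))
  starts <- attr(tab, "t_starts")
  expect_equal(diff(starts), rep(attr(tab, "volume_us"), 2))
  # a generous interval takes precedence
  slow <- compile_experiment(
    experiment_spec(simple_channel(), n_slices = 2, n_timepoints = 3,
                    interval_ms = 4000, z_step_um = 1), depot)
  expect_equal(diff(attr(slow, "t_starts")), rep(4000000L, 2))
})

test_that("compile errors name unresolvable handlers and missing executors", {
  depot <- small_depot()
  bad <- channel_spec("x", "no:such", "camera:sensor")
  expect_error(compile_experiment(experiment_spec(bad), depot), "no:such")
  no_exec <- build_depot(list(device_config("stage", "sim_stage"),
                              device_config("camera", "sim_camera",
                                            width = 8, height = 8),
                              device_config("laser488", "sim_laser")))
  expect_error(compile_experiment(experiment_spec(simple_channel()), no_exec),
               "no executor")
  expect_error(experiment_spec(list()), "at least one channel")
})
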