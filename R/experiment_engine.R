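# Experiments compile to an "action table": the time-ordered list of
# digital levels and analogue values that a hardware timing device would
# replay. Here a software executor replays the same table on a virtual
# clock, making experiment timing a pure function of the table. The time
# base is integer microseconds; all durations are rounded half-up to 1 us.

DEFAULT_SETTLE_US <- 1000L    # wait after an analogue Z move
DEFAULT_READOUT_US <- 10000L  # camera readout after exposure

#' One imaging channel of an experiment
#'
#' @param name channel name (used in metadata).
#' @param light_handler name of the `light_source` handler to trigger.
#' @param camera_handler name of the `camera` handler to trigger.
#' @param filter_position 0-based filter wheel position for this channel.
#' @param exposure_ms exposure time, milliseconds (> 0).
#' @param light_power_fraction light power in `[0, 1]`.
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(name, light_handler, camera_handler,
                         filter_position = 0L, exposure_ms = 100,
                         light_power_fraction = 1) {
  stopifnot(exposure_ms > 0, light_power_fraction >= 0,
            light_power_fraction <= 1)
  structure(list(name = name, light_handler = light_handler,
                 camera_handler = camera_handler,
                 filter_position = as.integer(filter_position),
                 exposure_ms = exposure_ms,
                 light_power_fraction = light_power_fraction),
            class = "channel_spec")
}

#' A channels x Z-stack x time-lapse experiment
#'
#' @param channels non-empty list of [channel_spec()] (acquired innermost).
#' @param z_start_um first Z position, micrometres (macro Z).
#' @param z_step_um Z increment between slices.
#' @param n_slices number of Z slices (>= 1).
#' @param n_timepoints number of timepoints (>= 1).
#' @param interval_ms timepoint start-to-start interval, milliseconds; if a
#'   volume takes longer, the next timepoint starts immediately (with a
#'   warning at compile time).
#' @param save_path optional output '.dv' path for [run_experiment()].
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(channels, z_start_um = 0, z_step_um = 0,
                            n_slices = 1L, n_timepoints = 1L,
                            interval_ms = 0, save_path = NULL) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  if (length(channels) == 0L)
    stop("validation error: experiment needs at least one channel")
  stopifnot(n_slices >= 1L, n_timepoints >= 1L, interval_ms >= 0)
  structure(list(channels = channels, z_start_um = z_start_um,
                 z_step_um = z_step_um, n_slices = as.integer(n_slices),
                 n_timepoints = as.integer(n_timepoints),
                 interval_ms = interval_ms, save_path = save_path),
            class = "experiment_spec")
}

line_id <- function(handler, field) {
  v <- handler[[field]]
  if (is.null(v)) return(NULL)
  sprintf("%s%d", if (field == "digital_line") "D" else "A", v)
}

require_line <- function(handler, field) {
  id <- line_id(handler, field)
  if (is.null(id))
    stop(sprintf("compile error: handler '%s' has no %s assigned",
                 handler$name, field), call. = FALSE)
  id
}

#' Compile an experiment to an action table
#'
#' Loop nesting is timepoint (outermost), then Z slice, then channel
#' (innermost). Per slice: one analogue Z event, a settle wait, then per
#' channel a filter-wheel analogue event, a light-power analogue event,
#' simultaneous light and camera rising edges, both falling after the
#' channel exposure, and a readout wait. Compilation is deterministic.
#'
#' @param spec an [experiment_spec()].
#' @param depot a `scope_depot` containing an executor, the referenced
#'   camera and light handlers (with digital lines), and an analogue Z
#'   stage axis.
#' @param settle_us,readout_us timing overrides, microseconds; defaults
#'   come from the executor device settings (1000 and 10000).
#' @return an `action_table`: a data frame with columns `time_us` (integer),
#'   `line` (e.g. `"D2"`, `"A0"`), `type` (`"digital"`/`"analogue"`) and
#'   `value`, sorted by time then line, with the experiment layout attached
#'   as attributes.
#' @export
compile_experiment <- function(spec, depot, settle_us = NULL,
                               readout_us = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  execs <- handlers_of_kind(depot, "executor")
  if (length(execs) == 0L)
    stop("compile error: depot has no executor handler", call. = FALSE)
  exec_state <- device_state(depot, execs[[1]]$device_name)
  if (is.null(settle_us))
    settle_us <- if (!is.null(exec_state$settle_us)) exec_state$settle_us
                 else DEFAULT_SETTLE_US
  if (is.null(readout_us))
    readout_us <- if (!is.null(exec_state$readout_us)) exec_state$readout_us
                  else DEFAULT_READOUT_US
  settle_us <- as.integer(round(settle_us))
  readout_us <- as.integer(round(readout_us))

  nT <- spec$n_timepoints; nZ <- spec$n_slices; nC <- length(spec$channels)
  cam_lines <- character(nC); light_lines <- character(nC)
  exp_us <- integer(nC); filt <- integer(nC); power <- numeric(nC)
  for (k in seq_len(nC)) {
    ch <- spec$channels[[k]]
    cam <- get_handler(depot, ch$camera_handler)
    light <- get_handler(depot, ch$light_handler)
    if (cam$kind != "camera")
      stop(sprintf("compile error: '%s' is not a camera handler", cam$name))
    if (light$kind != "light_source")
      stop(sprintf("compile error: '%s' is not a light source handler", light$name))
    cam_lines[k] <- require_line(cam, "digital_line")
    light_lines[k] <- require_line(light, "digital_line")
    exp_us[k] <- as.integer(round(ch$exposure_ms * 1000))
    filt[k] <- ch$filter_position
    power[k] <- ch$light_power_fraction
  }
  axes <- stage_axes(depot)
  zax <- Filter(function(a) a$dim == "z" && !is.null(a$handler$analogue_line),
                axes)
  if (length(zax) == 0L)
    stop("compile error: no Z stage axis with an analogue line", call. = FALSE)
  zax <- zax[[order(vapply(zax, `[[`, integer(1), "rank"),
                    decreasing = TRUE)[1]]]
  z_line <- line_id(zax$handler, "analogue_line")
  wheels <- handlers_of_kind(depot, "filter_wheel")
  wheel_line <- if (length(wheels) && !is.null(wheels[[1]]$analogue_line))
    line_id(wheels[[1]], "analogue_line") else NULL
  power_lines <- vapply(seq_len(nC), function(k) {
    light <- get_handler(depot, spec$channels[[k]]$light_handler)
    ph <- Filter(function(h) h$kind == "light_power" &&
                   h$device_name == light$device_name, depot$handlers)
    if (length(ph) && !is.null(ph[[1]]$analogue_line))
      line_id(ph[[1]], "analogue_line") else NA_character_
  }, character(1))

  ch_off <- settle_us + c(0L, cumsum(exp_us + readout_us))[seq_len(nC)]
  zblock_us <- settle_us + sum(exp_us + readout_us)
  volume_us <- nZ * zblock_us
  interval_us <- as.integer(round(spec$interval_ms * 1000))
  t_starts <- integer(nT)
  if (nT > 1L) {
    if (interval_us < volume_us)
      warning(sprintf(paste0("interval (%d us) shorter than one volume ",
                             "(%d us); timepoints run back-to-back"),
                      interval_us, volume_us))
    for (t in 2:nT)
      t_starts[t] <- t_starts[t - 1L] + max(interval_us, volume_us)
  }
  z_levels <- spec$z_start_um + spec$z_step_um * (seq_len(nZ) - 1L)

  # vectorised event assembly; order of construction is irrelevant because
  # the table is sorted by (time, line) afterwards
  zb_start <- rep(t_starts, each = nZ) + rep((seq_len(nZ) - 1L) * zblock_us, nT)
  events <- list(
    data.frame(time_us = zb_start, line = z_line, type = "analogue",
               value = rep(z_levels, nT)))
  ch_start <- rep(zb_start, each = nC) + rep(ch_off, nT * nZ)
  rep_c <- rep(seq_len(nC), nT * nZ)
  if (!is.null(wheel_line))
    events[[length(events) + 1L]] <-
      data.frame(time_us = ch_start, line = wheel_line, type = "analogue",
                 value = filt[rep_c])
  has_pw <- !is.na(power_lines[rep_c])
  if (any(has_pw))
    events[[length(events) + 1L]] <-
      data.frame(time_us = ch_start[has_pw], line = power_lines[rep_c][has_pw],
                 type = "analogue", value = power[rep_c][has_pw])
  events[[length(events) + 1L]] <-
    data.frame(time_us = c(ch_start, ch_start + exp_us[rep_c]),
               line = rep(light_lines[rep_c], 2L), type = "digital",
               value = rep(c(1, 0), each = length(ch_start)))
  events[[length(events) + 1L]] <-
    data.frame(time_us = c(ch_start, ch_start + exp_us[rep_c]),
               line = rep(cam_lines[rep_c], 2L), type = "digital",
               value = rep(c(1, 0), each = length(ch_start)))
  table <- do.call(rbind, events)
  table <- table[order(table$time_us, table$line, method = "radix"), ,
                 drop = FALSE]
  rownames(table) <- NULL
  table$time_us <- as.integer(table$time_us)
  structure(table,
            layout = c(T = nT, C = nC, Z = nZ),
            z_levels = z_levels, z_line = z_line, wheel_line = wheel_line,
            camera_lines = cam_lines, light_lines = light_lines,
            filter_positions = filt, exposures_us = exp_us,
            light_powers = power,
            settle_us = settle_us, readout_us = readout_us,
            volume_us = volume_us, t_starts = t_starts,
            channel_names = vapply(spec$channels, `[[`, character(1), "name"),
            class = c("action_table", "data.frame"))
}

#' Validate an action table
#'
#' Report-based: checks monotone times, type-correct values, paired
#' rising/falling digital edges (every line returns low), and — when a
#' depot is supplied — that every referenced line is registered with a
#' handler.
#'
#' @param table an `action_table` (or plain data frame with the same
#'   columns).
#' @param depot optional `scope_depot` for the known-lines check.
#' @return list with `valid` and `violations` (character vector).
#' @export
validate_table <- function(table, depot = NULL) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  if (nrow(table) == 0L)
    return(list(valid = TRUE, violations = character(0)))
  if (any(table$time_us < 0)) note("negative event time")
  if (is.unsorted(table$time_us)) note("non-monotonic time")
  dig <- table$type == "digital"
  if (any(!table$value[dig] %in% c(0, 1)))
    note("digital event with non-boolean value")
  if (any(!is.finite(table$value[!dig])))
    note("analogue event with non-finite value")
  for (ln in unique(table$line[dig])) {
    vals <- table$value[dig & table$line == ln]
    expected <- rep(c(1, 0), length.out = length(vals))
    if (!all(vals == expected))
      note(sprintf("line %s: digital edges not strictly rise/fall paired", ln))
    else if (length(vals) %% 2L != 0L)
      note(sprintf("line %s: left high by the final event", ln))
  }
  if (!is.null(depot)) {
    known <- unlist(lapply(depot$handlers, function(h)
      c(line_id(h, "digital_line"), line_id(h, "analogue_line"))))
    bad <- setdiff(unique(table$line), known)
    if (length(bad))
      note(sprintf("unknown line(s): %s", paste(bad, collapse = ", ")))
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Export an action table as TSV
#'
#' Columns `time_us`, `line`, `value` — a human-inspectable rendering of
#' the compiled schedule.
#'
#' @param table an `action_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_action_table <- function(table, path) {
  df <- data.frame(time_us = table$time_us, line = table$line,
                   value = table$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

find_camera_device <- function(depot, line = NULL) {
  cams <- handlers_of_kind(depot, "camera")
  if (length(cams) == 0L) stop("no camera handler in depot", call. = FALSE)
  if (!is.null(line)) {
    for (h in cams)
      if (identical(line_id(h, "digital_line"), line)) return(h)
  }
  cams[[1]]
}

wheel_state_of <- function(depot) {
  whs <- handlers_of_kind(depot, "filter_wheel")
  if (length(whs) == 0L) return(filter_wheel_state(1L, 0L))
  device_state(depot, whs[[1]]$device_name)$wheel
}

#' Execute an action table against simulated devices
#'
#' Replays events in order on a virtual clock. Every camera rising edge
#' yields exactly one image acquired with the stage, filter and light state
#' prevailing at that clock time (events sharing a timestamp are applied
#' before any camera trigger at that timestamp); the exposure is the
#' rise-to-fall interval on the camera line. Timestamps equal the
#' triggering event times, so timing is a function of the table alone.
#'
#' @param table a compiled `action_table`.
#' @param depot a `scope_depot` with simulated devices.
#' @param blur_coeff defocus blur coefficient passed to [acquire()].
#' @return list of records `list(image, c, z, t, timestamp_us)` with
#'   0-based channel / slice / timepoint indices.
#' @export
execute_table <- function(table, depot, blur_coeff = 0.5) {
  line_map <- list()
  for (h in depot$handlers) {
    for (f in c("digital_line", "analogue_line")) {
      id <- line_id(h, f)
      if (!is.null(id)) line_map[[id]] <- h
    }
  }
  bad <- setdiff(unique(table$line), names(line_map))
  if (length(bad))
    stop(sprintf("execution error: event on unregistered line(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  layout <- attr(table, "layout")
  cam_rise <- table$type == "digital" & table$value == 1 &
    vapply(table$line, function(l) line_map[[l]]$kind == "camera", logical(1))
  # camera triggers fire after the other events sharing their timestamp
  ord <- order(table$time_us, cam_rise & TRUE, table$line, method = "radix")
  results <- list()
  k <- 0L
  light_power <- new.env(parent = emptyenv())  # per light device
  light_on <- new.env(parent = emptyenv())
  for (i in ord) {
    h <- line_map[[table$line[i]]]
    val <- table$value[i]
    st <- device_state(depot, h$device_name)
    if (table$type[i] == "analogue") {
      if (h$kind == "stage_axis") {
        nm <- vapply(st$axes, function(a) a$handler$name, character(1))
        ai <- which(nm == h$name)
        ax <- st$axes[[ai]]
        if (val < ax$limits_um[1] || val > ax$limits_um[2])
          stop(sprintf("execution error: analogue value %g outside limits of axis %s",
                       val, h$name))
        ax$position_um <- val
        st$axes[[ai]] <- ax
      } else if (h$kind == "filter_wheel") {
        st$wheel <- set_filter(st$wheel, round(val))
      } else if (h$kind == "light_power") {
        assign(h$device_name, val, envir = light_power)
      }
    } else {  # digital
      if (h$kind == "light_source") {
        assign(h$device_name, val == 1, envir = light_on)
      } else if (h$kind == "camera" && val == 1) {
        falls <- which(table$line == table$line[i] & table$value == 0 &
                         table$time_us >= table$time_us[i])
        exp_us <- if (length(falls))
          min(table$time_us[falls]) - table$time_us[i] else 1000L
        on_devs <- ls(light_on)[vapply(ls(light_on), get, logical(1),
                                       envir = light_on)]
        pw <- if (length(on_devs)) {
          p <- vapply(on_devs, function(d)
            if (exists(d, envir = light_power)) get(d, envir = light_power)
            else 1, numeric(1))
          max(p)
        } else 0
        cam_dev <- device_state(depot, h$device_name)
        pos <- depot_position(depot)
        img <- acquire(cam_dev$sample, cam_dev$camera,
                       c(pos$x_um, pos$y_um, pos$z_um),
                       wheel_state_of(depot),
                       exposure_ms = max(exp_us, 1L) / 1000,
                       light_power = pw, blur_coeff = blur_coeff)
        if (!is.null(layout)) {
          nC <- layout[["C"]]; nZ <- layout[["Z"]]
          rec <- list(image = img, c = k %% nC, z = (k %/% nC) %% nZ,
                      t = k %/% (nC * nZ), timestamp_us = table$time_us[i])
        } else {
          rec <- list(image = img, c = wheel_state_of(depot)$position,
                      z = 0L, t = 0L, timestamp_us = table$time_us[i])
        }
        k <- k + 1L
        results[[k]] <- rec
      }
    }
  }
  results
}

#' Compile, execute and save an experiment
#'
#' Runs the full pipeline: compile to an action table, validate it, replay
#' it against the simulated devices, assemble the `(T, C, Z, Y, X)`
#' dataset, and (when a save path is given) write it as a '.dv' file with
#' per-plane stage positions and timestamps in the extended header.
#'
#' @param spec an [experiment_spec()].
#' @param depot a `scope_depot`.
#' @param path output '.dv' path; defaults to `spec$save_path` (no file is
#'   written when both are `NULL`).
#' @param blur_coeff defocus blur coefficient.
#' @return a [dv_dataset()], invisibly carrying attribute `path` when
#'   written.
#' @export
run_experiment <- function(spec, depot, path = spec$save_path,
                           blur_coeff = 0.5) {
  table <- compile_experiment(spec, depot)
  report <- validate_table(table, depot)
  if (!report$valid)
    stop(sprintf("compiled table failed validation: %s",
                 paste(report$violations, collapse = "; ")))
  recs <- execute_table(table, depot, blur_coeff = blur_coeff)
  nT <- spec$n_timepoints; nC <- length(spec$channels); nZ <- spec$n_slices
  cam <- find_camera_device(depot)
  cam_dev <- device_state(depot, cam$device_name)
  h <- cam_dev$camera$sensor_shape[1]; w <- cam_dev$camera$sensor_shape[2]
  data <- array(0L, dim = c(nT, nC, nZ, h, w))
  nplanes <- nT * nC * nZ
  pm <- data.frame(x_um = rep(NA_real_, nplanes), y_um = NA_real_,
                   z_um = NA_real_, timestamp_s = NA_real_)
  pos <- depot_position(depot)
  zlv <- attr(table, "z_levels")
  for (r in recs) {
    data[r$t + 1L, r$c + 1L, r$z + 1L, , ] <- r$image
    p <- dv_plane_index(r$t + 1L, r$c + 1L, r$z + 1L, nZ, nC)
    pm[p, ] <- c(pos$x_um, pos$y_um, zlv[r$z + 1L], r$timestamp_us / 1e6)
  }
  pm[is.na(pm)] <- 0
  wl <- vapply(spec$channels, function(ch) {
    light <- get_handler(depot, ch$light_handler)
    st <- device_state(depot, light$device_name)
    if (!is.null(st$wavelength_nm)) as.numeric(st$wavelength_nm) else 0
  }, numeric(1))
  ds <- dv_dataset(
    data,
    pixel_size_um = c(cam_dev$camera$pixel_size_um,
                      cam_dev$camera$pixel_size_um,
                      if (spec$z_step_um != 0) abs(spec$z_step_um) else 1),
    wavelengths_nm = wl,
    exposure_ms = vapply(spec$channels, `[[`, numeric(1), "exposure_ms"),
    stage_origin_um = macro_position(pos$x_um, pos$y_um, spec$z_start_um),
    plane_metadata = pm,
    channel_names = vapply(spec$channels, `[[`, character(1), "name"))
  if (!is.null(path)) {
    write_dv(ds, path)
    attr(ds, "path") <- path
  }
  invisible(ds)
}
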