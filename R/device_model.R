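#' @importFrom stats var rnorm runif sd
#' @importFrom utils head tail modifyList
NULL

#' Handler kinds
#'
#' A handler is one addressable control facet of a device: a camera sensor,
#' a single stage axis, the on/off state of a light source, its power, a
#' filter wheel position, or the trigger executor. Every handler has exactly
#' one kind.
#'
#' @export
HANDLER_KINDS <- c("camera", "stage_axis", "light_source", "light_power",
                   "filter_wheel", "executor")

#' Create a device handler
#'
#' @param name unique handler name, conventionally `<device>:<facet>`.
#' @param kind one of [HANDLER_KINDS].
#' @param device_name name of the owning device.
#' @param digital_line optional non-negative integer trigger line index.
#' @param analogue_line optional non-negative integer analogue line index.
#' @return an object of class `scope_handler`.
#' @export
handler <- function(name, kind, device_name,
                    digital_line = NULL, analogue_line = NULL) {
  kind <- match.arg(kind, HANDLER_KINDS)
  if (!is.null(digital_line)) {
    digital_line <- as.integer(digital_line)
    if (digital_line < 0L) stop("digital_line must be non-negative")
  }
  if (!is.null(analogue_line)) {
    analogue_line <- as.integer(analogue_line)
    if (analogue_line < 0L) stop("analogue_line must be non-negative")
  }
  structure(list(name = name, kind = kind, device_name = device_name,
                 digital_line = digital_line, analogue_line = analogue_line),
            class = "scope_handler")
}

#' @export
print.scope_handler <- function(x, ...) {
  lines <- c(
    if (!is.null(x$digital_line)) sprintf("D%d", x$digital_line),
    if (!is.null(x$analogue_line)) sprintf("A%d", x$analogue_line))
  cat(sprintf("<handler %s [%s] on %s%s>\n", x$name, x$kind, x$device_name,
              if (length(lines)) paste0(" ", paste(lines, collapse = ",")) else ""))
  invisible(x)
}

#' Describe one device for depot construction
#'
#' @param device_name unique device name (becomes the handler name prefix).
#' @param device_type key into the device registry (see [device_types()]).
#' @param ... settings passed to the device constructor (axis limits, pixel
#'   size in micrometres, source sample path, trigger line indices, ...).
#' @return an object of class `device_config`.
#' @export
device_config <- function(device_name, device_type, ...) {
  structure(list(device_name = device_name, device_type = device_type,
                 settings = list(...)),
            class = "device_config")
}

# In-process device registry, populated at load time.  No network discovery:
# a registry entry is a constructor function(device_name, settings) returning
# list(handlers = <list of scope_handler>, state = <environment>).
.scope_registry <- new.env(parent = emptyenv())

#' Register a device type
#'
#' @param type registry key used by [device_config()].
#' @param constructor `function(device_name, settings)` returning
#'   `list(handlers = <list of handler>, state = <environment>)`.
#' @export
register_device_type <- function(type, constructor) {
  stopifnot(is.character(type), length(type) == 1L, is.function(constructor))
  assign(type, constructor, envir = .scope_registry)
  invisible(type)
}

#' List registered device types
#' @return character vector of registry keys.
#' @export
device_types <- function() sort(ls(.scope_registry))

setting <- function(settings, key, default = NULL, required = FALSE) {
  if (!is.null(settings[[key]])) return(settings[[key]])
  if (required) stop(sprintf("missing required setting '%s'", key), call. = FALSE)
  default
}

num_setting <- function(settings, key, default = NULL, required = FALSE) {
  v <- setting(settings, key, default, required)
  if (is.null(v)) return(NULL)
  as.numeric(v)
}

#' Build a depot from device configurations
#'
#' Constructs every configured device through the registry and aggregates
#' the handlers they expose. The depot is the only object the rest of the
#' system talks to; devices absent from the configuration are absent from
#' the depot.
#'
#' @param configs list of [device_config()] objects (may be empty).
#' @return an object of class `scope_depot` with elements `handlers`
#'   (named list of handlers) and `devices` (named list of device state
#'   environments, each carrying `$type`).
#' @export
build_depot <- function(configs = list()) {
  if (inherits(configs, "device_config")) configs <- list(configs)
  handlers <- list()
  devices <- list()
  for (cfg in configs) {
    if (!inherits(cfg, "device_config"))
      stop("build_depot expects a list of device_config objects")
    ctor <- .scope_registry[[cfg$device_type]]
    if (is.null(ctor))
      stop(sprintf("unknown device type '%s' for device '%s'",
                   cfg$device_type, cfg$device_name), call. = FALSE)
    if (cfg$device_name %in% names(devices))
      stop(sprintf("duplicate device name '%s'", cfg$device_name), call. = FALSE)
    built <- ctor(cfg$device_name, cfg$settings)
    if (length(built$handlers) == 0L)
      warning(sprintf("device '%s' exposes no handlers", cfg$device_name))
    for (h in built$handlers) {
      if (h$name %in% names(handlers))
        stop(sprintf("duplicate handler name '%s'", h$name), call. = FALSE)
      handlers[[h$name]] <- h
    }
    built$state$type <- cfg$device_type
    devices[[cfg$device_name]] <- built$state
  }
  # one owner per trigger line across the whole system
  for (field in c("digital_line", "analogue_line")) {
    lines <- unlist(lapply(handlers, function(h) h[[field]]))
    if (anyDuplicated(lines))
      stop(sprintf("conflicting %s assignment: line %d claimed twice",
                   field, lines[duplicated(lines)][1L]), call. = FALSE)
  }
  structure(list(handlers = handlers, devices = devices),
            class = "scope_depot")
}

#' Query depot handlers by kind
#'
#' @param depot a `scope_depot`.
#' @param kind one of [HANDLER_KINDS].
#' @return list of handlers of that kind, in name-sorted (deterministic)
#'   order.
#' @export
handlers_of_kind <- function(depot, kind) {
  kind <- match.arg(kind, HANDLER_KINDS)
  hs <- Filter(function(h) h$kind == kind, depot$handlers)
  if (length(hs) == 0L) return(list())
  hs[order(names(hs))]
}

#' Look up one handler by name
#' @param depot a `scope_depot`.
#' @param name handler name.
#' @return the handler; error if absent.
#' @export
get_handler <- function(depot, name) {
  h <- depot$handlers[[name]]
  if (is.null(h)) stop(sprintf("no handler named '%s'", name), call. = FALSE)
  h
}

device_state <- function(depot, device_name) {
  st <- depot$devices[[device_name]]
  if (is.null(st)) stop(sprintf("no device named '%s'", device_name), call. = FALSE)
  st
}

#' @export
print.scope_depot <- function(x, ...) {
  cat(sprintf("<depot: %d devices, %d handlers>\n",
              length(x$devices), length(x$handlers)))
  for (nm in sort(names(x$handlers))) {
    h <- x$handlers[[nm]]
    cat(sprintf("  %-24s %-12s %s\n", h$name, h$kind, h$device_name))
  }
  invisible(x)
}

#' Read a depot configuration file
#'
#' INI dialect: one `[section]` per device (the section name is the device
#' name), a `type` key selecting the registry entry, and remaining keys
#' passed through as settings. Blank lines and lines starting with `#` or
#' `;` are ignored.
#'
#' @param path path to the configuration file.
#' @return list of [device_config()] objects suitable for [build_depot()].
#' @export
read_depot_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  section <- NULL
  settings <- list()
  flush <- function() {
    if (is.null(section)) return()
    type <- settings[["type"]]
    if (is.null(type))
      stop(sprintf("device section [%s] has no 'type' key", section), call. = FALSE)
    settings[["type"]] <- NULL
    configs[[length(configs) + 1L]] <<-
      do.call(device_config, c(list(device_name = section, device_type = type),
                               settings))
  }
  for (raw in lines) {
    line <- trimws(raw)
    if (line == "" || startsWith(line, "#") || startsWith(line, ";")) next
    if (grepl("^\\[.+\\]$", line)) {
      flush()
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      settings <- list()
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(section))
        stop(sprintf("key outside any [section]: '%s'", line), call. = FALSE)
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      settings[[key]] <- val
    } else {
      stop(sprintf("unparseable config line: '%s'", line), call. = FALSE)
    }
  }
  flush()
  configs
}
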