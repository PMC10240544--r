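# Mosaic acquisition: tiles are collected in an expanding spiral around a
# start position and kept in an append-only store spanning all mosaics, so
# starting a new mosaic never discards earlier coverage. A CPU composite
# renderer stands in for GPU texture painting.

#' Expanding-spiral grid offsets
#'
#' The first offset is `(0, 0)`; the walk then steps east and proceeds
#' counter-clockwise ring by ring (run lengths 1, 1, 2, 2, 3, 3, ...), so
#' consecutive offsets always differ by one unit step and the first
#' `(2k+1)^2` offsets tile the full square `{-k..k}^2`.
#'
#' @param n number of offsets (>= 1).
#' @return integer matrix `n x 2` with columns `i` (east) and `j` (north,
#'   i.e. increasing stage y).
#' @export
spiral_offsets <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("validation error: n must be >= 1")
  if (n == 1L) return(matrix(0L, 1L, 2L, dimnames = list(NULL, c("i", "j"))))
  # direction sequence E, N, W, S with run lengths 1,1,2,2,3,3,...
  steps <- n - 1L
  runs <- rep(seq_len(steps), each = 2L)           # generous upper bound
  runs <- runs[cumsum(runs) - runs < steps]
  dirs <- matrix(c(1L, 0L, 0L, 1L, -1L, 0L, 0L, -1L), ncol = 2L, byrow = TRUE)
  di <- rep(dirs[(seq_along(runs) - 1L) %% 4L + 1L, 1L], runs)[seq_len(steps)]
  dj <- rep(dirs[(seq_along(runs) - 1L) %% 4L + 1L, 2L], runs)[seq_len(steps)]
  out <- cbind(i = c(0L, cumsum(di)), j = c(0L, cumsum(dj)))
  out
}

#' Create an empty tile store
#'
#' The store is append-only: tiles from every mosaic ever run and all
#' marked points accumulate; starting a new mosaic never removes previous
#' tiles.
#'
#' @return object of class `tile_store`.
#' @export
tile_store <- function() {
  structure(list(tiles = list(), marked = list(), next_mosaic_id = 1L),
            class = "tile_store")
}

#' @export
print.tile_store <- function(x, ...) {
  ids <- unique(vapply(x$tiles, `[[`, integer(1), "mosaic_id"))
  cat(sprintf("<tile store: %d tiles in %d mosaic(s), %d marked point(s)>\n",
              length(x$tiles), length(ids), length(x$marked)))
  invisible(x)
}

tile_footprint <- function(tile) {
  h <- nrow(tile$image); w <- ncol(tile$image)
  px <- tile$pixel_size_um
  # pixel (0,0) centre sits at centre - floor(dim/2) * px; the footprint
  # spans half a pixel beyond the outermost pixel centres
  x0 <- tile$centre$x_um - floor(w / 2) * px - px / 2
  y0 <- tile$centre$y_um - floor(h / 2) * px - px / 2
  c(x0 = x0, x1 = x0 + w * px, y0 = y0, y1 = y0 + h * px)
}

#' Acquire a mosaic of tiles in an expanding spiral
#'
#' Tile `k` is acquired at `start + spiral_offsets(n)[k, ] * step` where
#' `step = sensor_extent_um * (1 - overlap_fraction)`; Z is held at
#' `start$z_um` throughout and the stage returns to `start` afterwards.
#' If a move is rejected by the soft limits the mosaic stops cleanly at the
#' last good tile (partial mosaic retained) with a warning.
#'
#' @param store a [tile_store()].
#' @param start a [macro_position()]; the spiral centre.
#' @param n_tiles number of tiles (>= 1).
#' @param overlap_fraction fractional tile overlap in `[0, 1)`.
#' @param depot a `scope_depot` with a simulated camera and stage.
#' @param exposure_ms exposure per tile, milliseconds.
#' @param blur_coeff defocus blur coefficient.
#' @param filter_position optional wheel position selected before the scan
#'   (default: keep the wheel where it is).
#' @return updated store; the new mosaic's id is in attribute `mosaic_id`.
#' @export
run_mosaic <- function(store, start, n_tiles, overlap_fraction = 0, depot,
                       exposure_ms = REFERENCE_EXPOSURE_MS,
                       blur_coeff = 0.5, filter_position = NULL) {
  stopifnot(inherits(store, "tile_store"), inherits(start, "macro_position"),
            n_tiles >= 1L, overlap_fraction >= 0, overlap_fraction < 1)
  if (!is.null(filter_position)) set_depot_filter(depot, filter_position)
  cam <- find_camera_device(depot)
  cam_st <- device_state(depot, cam$device_name)
  h <- cam_st$camera$sensor_shape[1]; w <- cam_st$camera$sensor_shape[2]
  px <- cam_st$camera$pixel_size_um
  step_x <- w * px * (1 - overlap_fraction)
  step_y <- h * px * (1 - overlap_fraction)
  offs <- spiral_offsets(n_tiles)
  id <- store$next_mosaic_id
  home <- depot_position(depot)
  for (k in seq_len(n_tiles)) {
    target <- macro_position(start$x_um + offs[k, "i"] * step_x,
                             start$y_um + offs[k, "j"] * step_y,
                             start$z_um)
    ok <- tryCatch({ depot_move_to(depot, target); TRUE },
                   error = function(e) {
                     warning(sprintf("mosaic stopped after %d tile(s): %s",
                                     k - 1L, conditionMessage(e)))
                     FALSE
                   })
    if (!ok) break
    img <- snap(depot, exposure_ms = exposure_ms, blur_coeff = blur_coeff)
    store$tiles[[length(store$tiles) + 1L]] <-
      list(image = img, centre = depot_position(depot), pixel_size_um = px,
           mosaic_id = id, seq = k)
  }
  tryCatch(depot_move_to(depot, start),
           error = function(e) depot_move_to(depot, home))
  store$next_mosaic_id <- id + 1L
  attr(store, "mosaic_id") <- id
  store
}

mosaic_tiles <- function(store, mosaic_id) {
  tiles <- Filter(function(t) t$mosaic_id == mosaic_id, store$tiles)
  if (length(tiles) == 0L)
    stop(sprintf("lookup error: no mosaic with id %d", mosaic_id),
         call. = FALSE)
  tiles[order(vapply(tiles, `[[`, integer(1), "seq"))]
}

#' Save one mosaic as a '.dv' stack plus an XYZ sidecar
#'
#' The tiles are written as one '.dv' plane per tile (in acquisition
#' order, with each tile's stage position in the extended header), and a
#' plain-text sidecar with one tab-separated line per tile: `seq`, `x_um`,
#' `y_um`, `z_um` to three decimal places. The sidecar lives next to the
#' stack as `<path without extension>_positions.txt`.
#'
#' @param store a [tile_store()].
#' @param mosaic_id id of the mosaic to save.
#' @param path output '.dv' path.
#' @return invisibly, `list(dv = path, sidecar = sidecar_path)`.
#' @export
save_mosaic <- function(store, mosaic_id, path) {
  tiles <- mosaic_tiles(store, mosaic_id)
  h <- nrow(tiles[[1]]$image); w <- ncol(tiles[[1]]$image)
  n <- length(tiles)
  data <- array(0L, dim = c(1L, 1L, n, h, w))
  pm <- data.frame(x_um = numeric(n), y_um = numeric(n), z_um = numeric(n),
                   timestamp_s = seq_len(n))
  for (k in seq_len(n)) {
    data[1, 1, k, , ] <- tiles[[k]]$image
    pm$x_um[k] <- tiles[[k]]$centre$x_um
    pm$y_um[k] <- tiles[[k]]$centre$y_um
    pm$z_um[k] <- tiles[[k]]$centre$z_um
  }
  px <- tiles[[1]]$pixel_size_um
  ds <- dv_dataset(data, pixel_size_um = c(px, px, 1),
                   stage_origin_um = tiles[[1]]$centre, plane_metadata = pm)
  write_dv(ds, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), "_positions.txt")
  lines <- c("# seq\tx_um\ty_um\tz_um",
             sprintf("%d\t%.3f\t%.3f\t%.3f", seq_len(n),
                     pm$x_um, pm$y_um, pm$z_um))
  writeLines(lines, sidecar)
  invisible(list(dv = path, sidecar = sidecar))
}

#' Read a mosaic sidecar file
#' @param path sidecar path written by [save_mosaic()].
#' @return data frame with columns `seq`, `x_um`, `y_um`, `z_um`.
#' @export
read_mosaic_sidecar <- function(path) {
  utils::read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("seq", "x_um", "y_um", "z_um"))
}

#' Render a composite image of the stored tiles
#'
#' Paints every tile (across all mosaics) in acquisition order — later
#' tiles over earlier ones, as on the interactive guide map — resampled to
#' the requested output scale by nearest neighbour. Regions no tile covers
#' are zero.
#'
#' @param store a [tile_store()].
#' @param bounds_um numeric `(xmin, xmax, ymin, ymax)` region to render.
#' @param out_pixel_size_um output pixel size, micrometres (> 0).
#' @return numeric matrix of the composited region (rows = y, cols = x).
#' @export
render_region <- function(store, bounds_um, out_pixel_size_um) {
  stopifnot(length(bounds_um) == 4L, all(is.finite(bounds_um)),
            out_pixel_size_um > 0)
  xmin <- bounds_um[1]; xmax <- bounds_um[2]
  ymin <- bounds_um[3]; ymax <- bounds_um[4]
  stopifnot(xmax > xmin, ymax > ymin)
  s <- out_pixel_size_um
  nx <- max(1L, round((xmax - xmin) / s))
  ny <- max(1L, round((ymax - ymin) / s))
  xc <- xmin + (seq_len(nx) - 0.5) * s   # output pixel centres
  yc <- ymin + (seq_len(ny) - 0.5) * s
  out <- matrix(0, ny, nx)
  for (tile in store$tiles) {
    fp <- tile_footprint(tile)
    px <- tile$pixel_size_um
    cs <- which(xc >= fp["x0"] & xc < fp["x1"])
    rs <- which(yc >= fp["y0"] & yc < fp["y1"])
    if (!length(cs) || !length(rs)) next
    tc <- pmin(pmax(floor((xc[cs] - fp["x0"]) / px) + 1L, 1L), ncol(tile$image))
    tr <- pmin(pmax(floor((yc[rs] - fp["y0"]) / px) + 1L, 1L), nrow(tile$image))
    out[rs, cs] <- tile$image[tr, tc]
  }
  out
}

#' Mark a stage position for later revisit
#'
#' @param store a [tile_store()].
#' @param position a [macro_position()].
#' @param label free-text label.
#' @return updated store (marks are append-only; order is preserved).
#' @export
mark_point <- function(store, position, label = "") {
  stopifnot(inherits(store, "tile_store"), inherits(position, "macro_position"))
  store$marked[[length(store$marked) + 1L]] <-
    list(position = position, label = as.character(label))
  store
}

#' List marked points in mark order
#' @param store a [tile_store()].
#' @return data frame with columns `label`, `x_um`, `y_um`, `z_um`.
#' @export
list_marked <- function(store) {
  if (length(store$marked) == 0L)
    return(data.frame(label = character(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0)))
  data.frame(
    label = vapply(store$marked, `[[`, character(1), "label"),
    x_um = vapply(store$marked, function(m) m$position$x_um, numeric(1)),
    y_um = vapply(store$marked, function(m) m$position$y_um, numeric(1)),
    z_um = vapply(store$marked, function(m) m$position$z_um, numeric(1)))
}

#' Export marked points as a tab-separated file
#' @param store a [tile_store()].
#' @param path output path; columns `label`, `x_um`, `y_um`, `z_um`.
#' @return `path`, invisibly.
#' @export
write_marked_points <- function(store, path) {
  df <- list_marked(store)
  lines <- c("# label\tx_um\ty_um\tz_um",
             sprintf("%s\t%.3f\t%.3f\t%.3f", df$label, df$x_um, df$y_um,
                     df$z_um))
  writeLines(lines, path)
  invisible(path)
}
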