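# Nucleus detection in mosaic tiles: Gaussian blur to reduce noise,
# binarise (Otsu by default), then a circular Hough transform over the
# configured radius range. Detections are filtered by radius and by the
# circularity (4*pi*area/perimeter^2) of the thresholded component
# supporting the circle, converted to stage coordinates, and appended to
# the marked-point list.

#' Detection pipeline parameters
#'
#' @param radius_min_px,radius_max_px radius search range, pixels
#'   (`radius_min_px < radius_max_px`).
#' @param blur_sigma_px Gaussian pre-blur sigma, pixels (> 0).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method` is
#'   `"fixed"`.
#' @param circularity_min minimum circularity in `[0, 1]` of the supporting
#'   thresholded component (1 = perfect disk).
#' @param hough_accumulator_threshold minimum fraction of a circle's
#'   perimeter that must vote for it, in `(0, 1]`.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(radius_min_px, radius_max_px,
                             blur_sigma_px = 2,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             circularity_min = 0.7,
                             hough_accumulator_threshold = 0.35) {
  threshold_method <- match.arg(threshold_method)
  if (!is.numeric(blur_sigma_px) || blur_sigma_px <= 0)
    stop("validation error: blur_sigma_px must be positive")
  stopifnot(radius_min_px > 0, radius_min_px < radius_max_px,
            circularity_min >= 0, circularity_min <= 1,
            hough_accumulator_threshold > 0)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required when threshold_method = 'fixed'")
  structure(list(blur_sigma_px = blur_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 radius_min_px = radius_min_px,
                 radius_max_px = radius_max_px,
                 circularity_min = circularity_min,
                 hough_accumulator_threshold = hough_accumulator_threshold),
            class = "detection_params")
}

ring_kernel <- function(r) {
  R <- ceiling(r + 1)
  d <- sqrt(outer((-R:R)^2, (-R:R)^2, `+`))
  k <- (abs(d - r) <= 0.5) * 1
  k / sum(k)
}

boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  interior <- mask
  interior[2:(h - 1), 2:(w - 1)] <-
    mask[2:(h - 1), 2:(w - 1)] &
    mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
    mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  mask & !interior
}

#' Detect disk-like nuclei in one image
#'
#' Pipeline order is exactly blur, binarise, circular Hough. The Hough
#' accumulator for each candidate radius is the fraction of that circle's
#' perimeter covered by boundary pixels of the binary mask; peaks are
#' extracted greedily with a non-maximum-suppression radius of
#' `radius_min_px`. Centres are refined to the intensity-weighted centroid
#' of the mask inside the detected circle. Detections whose circle extends
#' beyond the image are dropped (detection at tile edges is a known
#' limitation of the pipeline).
#'
#' @param image 2D numeric/integer matrix (16-bit intensity scale).
#' @param params a [detection_params()].
#' @return data frame sorted by accumulator score (descending) with
#'   columns `row_px`, `col_px` (0-based centre), `radius_px`,
#'   `circularity`, `score`.
#' @export
detect_nuclei <- function(image, params) {
  stopifnot(inherits(params, "detection_params"))
  if (length(image) == 0L) stop("validation error: empty image")
  empty <- data.frame(row_px = numeric(0), col_px = numeric(0),
                      radius_px = numeric(0), circularity = numeric(0),
                      score = numeric(0))
  if (diff(range(image)) == 0) return(empty)
  blurred <- EBImage::gblur(image, sigma = params$blur_sigma_px,
                            boundary = "replicate")
  thr <- if (params$threshold_method == "otsu")
    EBImage::otsu(blurred, range = range(blurred), levels = 256L)
  else params$fixed_threshold
  mask <- blurred > thr
  if (!any(mask) || all(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  feats <- EBImage::computeFeatures.shape(labels)
  circ_of <- function(lab) {
    if (lab < 1 || lab > nrow(feats)) return(0)
    a <- feats[lab, "s.area"]; p <- feats[lab, "s.perimeter"]
    if (p <= 0) return(0)
    min(4 * pi * a / p^2, 1)
  }
  edges <- boundary_pixels(mask) * 1
  radii <- unique(round(seq(params$radius_min_px, params$radius_max_px,
                            by = 1)))
  acc <- array(0, dim = c(nrow(image), ncol(image), length(radii)))
  for (k in seq_along(radii))
    acc[, , k] <- EBImage::filter2(edges, ring_kernel(radii[k]),
                                   boundary = 0)
  h <- nrow(image); w <- ncol(image)
  dets <- empty
  nms <- params$radius_min_px
  repeat {
    peak <- which.max(acc)
    score <- acc[peak]
    if (length(score) == 0L || score < params$hough_accumulator_threshold)
      break
    idx <- arrayInd(peak, dim(acc))
    ri <- idx[1]; ci <- idx[2]; r <- radii[idx[3]]
    # suppress the neighbourhood regardless of whether the candidate passes
    # the filters, so weaker co-located circles are not re-reported
    rr <- max(1L, ri - ceiling(nms)):min(h, ri + ceiling(nms))
    cc <- max(1L, ci - ceiling(nms)):min(w, ci + ceiling(nms))
    acc[rr, cc, ] <- 0
    # edge policy: the full circle must lie inside the image
    if (ri - r < 1 || ri + r > h || ci - r < 1 || ci + r > w) next
    # refine centre: centroid of mask pixels inside the circle
    br <- max(1L, floor(ri - r)):min(h, ceiling(ri + r))
    bc <- max(1L, floor(ci - r)):min(w, ceiling(ci + r))
    sub <- mask[br, bc, drop = FALSE]
    dd <- sqrt(outer((br - ri)^2, (bc - ci)^2, `+`))
    inside <- sub & (dd <= r + 0.5)
    if (!any(inside)) next
    # supporting-component coherence: a genuine filled disk covers most of
    # its circle and its component area is commensurate with pi*r^2; an
    # Otsu mask of pure noise fails both
    fill <- sum(inside) / sum(dd <= r + 0.5)
    if (fill < 0.6) next
    row_c <- sum(row(inside)[inside] + br[1] - 1) / sum(inside)
    col_c <- sum(col(inside)[inside] + bc[1] - 1) / sum(inside)
    lab <- labels[ri, ci]
    if (lab == 0) {  # centre off the component: probe the refined centroid
      lab <- labels[round(row_c), round(col_c)]
    }
    if (lab >= 1 && lab <= nrow(feats)) {
      ratio <- feats[lab, "s.area"] / (pi * r^2)
      if (ratio < 0.4 || ratio > 2.5) next
    }
    circ <- circ_of(lab)
    if (circ < params$circularity_min) next
    dets <- rbind(dets, data.frame(row_px = row_c - 1, col_px = col_c - 1,
                                   radius_px = r, circularity = circ,
                                   score = score))
  }
  dets[order(-dets$score), , drop = FALSE]
}

#' Convert an image pixel to a stage coordinate
#'
#' Uses the package-wide convention: the tile centre addresses the sensor
#' centre pixel `(floor(h/2), floor(w/2))`; stage +x runs along columns,
#' +y along rows; Z is copied from the tile centre.
#'
#' @param centre_px numeric `(row, col)`, 0-based pixel position.
#' @param tile_centre a [macro_position()].
#' @param pixel_size_um tile pixel size, micrometres.
#' @param sensor_shape `(height, width)` of the tile, pixels.
#' @return a [macro_position()].
#' @export
image_to_stage <- function(centre_px, tile_centre, pixel_size_um,
                           sensor_shape) {
  stopifnot(length(centre_px) == 2L, length(sensor_shape) == 2L)
  if (centre_px[1] < 0 || centre_px[1] > sensor_shape[1] - 1 ||
      centre_px[2] < 0 || centre_px[2] > sensor_shape[2] - 1)
    stop("validation error: pixel position outside the sensor")
  macro_position(
    tile_centre$x_um + (centre_px[2] - floor(sensor_shape[2] / 2)) * pixel_size_um,
    tile_centre$y_um + (centre_px[1] - floor(sensor_shape[1] / 2)) * pixel_size_um,
    tile_centre$z_um)
}

#' Scan a mosaic and mark detected nuclei
#'
#' Runs an expanding-spiral mosaic from `start`, applies [detect_nuclei()]
#' to every acquired tile, transforms detections to stage coordinates and
#' appends each as a marked point labelled `nucleus-<k>`. Detections whose
#' stage position falls within one detection radius of an existing
#' nucleus mark (e.g. re-seen in an overlapping tile) are merged into the
#' existing mark.
#'
#' @param store a [tile_store()].
#' @param depot a `scope_depot`.
#' @param start a [macro_position()]; mosaic centre.
#' @param n_tiles number of tiles.
#' @param params a [detection_params()].
#' @param overlap_fraction fractional tile overlap.
#' @param blur_coeff defocus blur coefficient for acquisition.
#' @param filter_position optional wheel position selected before the scan
#'   (e.g. the DAPI filter).
#' @return updated store; the scanned mosaic's id is in attribute
#'   `mosaic_id`.
#' @export
scan_and_mark <- function(store, depot, start, n_tiles, params,
                          overlap_fraction = 0, blur_coeff = 0.5,
                          filter_position = NULL) {
  store <- run_mosaic(store, start, n_tiles, overlap_fraction, depot,
                      blur_coeff = blur_coeff,
                      filter_position = filter_position)
  id <- attr(store, "mosaic_id")
  existing <- list_marked(store)
  existing <- existing[startsWith(existing$label, "nucleus-"), , drop = FALSE]
  n_marks <- sum(startsWith(vapply(store$marked, `[[`, character(1), "label"),
                            "nucleus-"))
  for (tile in mosaic_tiles(store, id)) {
    dets <- detect_nuclei(tile$image, params)
    if (nrow(dets) == 0L) next
    shape <- dim(tile$image)
    for (d in seq_len(nrow(dets))) {
      pos <- image_to_stage(c(dets$row_px[d], dets$col_px[d]), tile$centre,
                            tile$pixel_size_um, shape)
      merge_um <- dets$radius_px[d] * tile$pixel_size_um
      if (nrow(existing) &&
          any(sqrt((existing$x_um - pos$x_um)^2 +
                   (existing$y_um - pos$y_um)^2) <= merge_um)) next
      n_marks <- n_marks + 1L
      store <- mark_point(store, pos, sprintf("nucleus-%d", n_marks))
      existing <- rbind(existing,
                        data.frame(label = sprintf("nucleus-%d", n_marks),
                                   x_um = pos$x_um, y_um = pos$y_um,
                                   z_um = pos$z_um))
    }
  }
  attr(store, "mosaic_id") <- id
  store
}
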