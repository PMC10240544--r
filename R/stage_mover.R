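#' Macro stage position
#'
#' The aggregate XYZ sample position: each coordinate is the sum of the
#' positions of every (possibly nested) axis assigned to that dimension,
#' e.g. a coarse Z stage plus a fine piezo Z stage.
#'
#' @param x_um,y_um,z_um coordinates in micrometres.
#' @return object of class `macro_position`.
#' @export
macro_position <- function(x_um = 0, y_um = 0, z_um = 0) {
  stopifnot(is.finite(x_um), is.finite(y_um), is.finite(z_um))
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 z_um = as.numeric(z_um)), class = "macro_position")
}

#' @export
print.macro_position <- function(x, ...) {
  cat(sprintf("<position x=%.3f y=%.3f z=%.3f um>\n", x$x_um, x$y_um, x$z_um))
  invisible(x)
}

#' @export
format.macro_position <- function(x, ...)
  sprintf("(%.3f, %.3f, %.3f)", x$x_um, x$y_um, x$z_um)

#' One translation axis of the macro stage
#'
#' @param handler the `stage_axis` handler controlling this axis.
#' @param dim dimension this axis moves: `"x"`, `"y"` or `"z"`.
#' @param position_um current position, micrometres; must lie within limits.
#' @param limits_um `(low, high)` soft travel limits, micrometres.
#' @param rank nesting rank: 0 = coarse, 1 = fine/piezo (higher = finer).
#' @return object of class `axis_state`.
#' @export
axis_state <- function(handler, dim, position_um = 0,
                       limits_um = c(-25000, 25000), rank = 0L) {
  dim <- match.arg(dim, c("x", "y", "z"))
  stopifnot(length(limits_um) == 2L, limits_um[1] < limits_um[2],
            position_um >= limits_um[1], position_um <= limits_um[2])
  structure(list(handler = handler, dim = dim,
                 position_um = as.numeric(position_um),
                 limits_um = as.numeric(limits_um), rank = as.integer(rank)),
            class = "axis_state")
}

#' Current macro position of a set of axes
#'
#' @param axes list of [axis_state()] covering all of x, y and z.
#' @return [macro_position()] whose coordinates are the per-dimension sums.
#' @export
current_position <- function(axes) {
  dims <- vapply(axes, `[[`, character(1), "dim")
  missing <- setdiff(c("x", "y", "z"), dims)
  if (length(missing))
    stop(sprintf("configuration error: no axis for dimension(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sums <- vapply(c("x", "y", "z"), function(d)
    sum(vapply(axes[dims == d], `[[`, numeric(1), "position_um")), numeric(1))
  macro_position(sums[["x"]], sums[["y"]], sums[["z"]])
}

# Split one dimension's move across its nested axes.  Fine-first policy:
# if the delta fits inside the finest axis's remaining travel, only the
# fine axis moves; otherwise the fine axis is re-centred mid-range and the
# coarsest axis absorbs the remainder (clamped to its limits, any residual
# going back to the fine axis).  Returns updated positions or NULL if the
# target is unreachable.
split_dimension_move <- function(states, target) {
  ord <- order(vapply(states, `[[`, integer(1), "rank"), decreasing = TRUE)
  states <- states[ord]
  pos <- vapply(states, `[[`, numeric(1), "position_um")
  fine <- states[[1L]]
  new_fine <- pos[1L] + (target - sum(pos))
  if (new_fine >= fine$limits_um[1] && new_fine <= fine$limits_um[2]) {
    pos[1L] <- new_fine
  } else if (length(states) == 1L) {
    return(NULL)
  } else {
    mid <- mean(fine$limits_um)
    coarse_idx <- length(states)          # lowest rank
    coarse <- states[[coarse_idx]]
    others <- sum(pos[-c(1L, coarse_idx)])
    want <- target - mid - others
    new_coarse <- min(max(want, coarse$limits_um[1]), coarse$limits_um[2])
    new_fine <- target - new_coarse - others
    if (new_fine < fine$limits_um[1] || new_fine > fine$limits_um[2])
      return(NULL)
    pos[1L] <- new_fine
    pos[coarse_idx] <- new_coarse
  }
  for (k in seq_along(states)) states[[k]]$position_um <- pos[k]
  states[order(ord)]
}

#' Move the macro stage to a target position
#'
#' All-or-nothing: either every axis ends at a position such that
#' [current_position()] equals the target (to 1e-9 um), or a soft-limit
#' error is raised and no axis moves. Within a dimension the finest-rank
#' axis absorbs the delta when it fits inside its remaining travel;
#' otherwise the coarse axis re-centres the fine axis mid-range and takes
#' the remainder, maximising future fine travel.
#'
#' @param axes list of [axis_state()].
#' @param target a [macro_position()].
#' @return updated list of axes.
#' @export
move_to <- function(axes, target) {
  stopifnot(inherits(target, "macro_position"))
  dims <- vapply(axes, `[[`, character(1), "dim")
  goal <- c(x = target$x_um, y = target$y_um, z = target$z_um)
  updated <- axes
  for (d in c("x", "y", "z")) {
    idx <- which(dims == d)
    if (!length(idx))
      stop(sprintf("configuration error: no axis for dimension %s", d),
           call. = FALSE)
    res <- split_dimension_move(axes[idx], goal[[d]])
    if (is.null(res))
      stop(sprintf("soft-limit error: target %s = %g um outside combined travel",
                   d, goal[[d]]), call. = FALSE)
    updated[idx] <- res
  }
  updated
}

# --- depot integration -----------------------------------------------------

#' Axes held by a depot's stage devices
#'
#' Collects the live [axis_state()] objects from every stage device in the
#' depot, in handler-name order.
#'
#' @param depot a `scope_depot`.
#' @return list of axis states.
#' @export
stage_axes <- function(depot) {
  axes <- list()
  for (st in depot$devices)
    if (!is.null(st$axes)) axes <- c(axes, st$axes)
  axes[order(vapply(axes, function(a) a$handler$name, character(1)))]
}

#' Write updated axis states back into the depot
#'
#' @param depot a `scope_depot`.
#' @param axes list of axis states (as returned by [move_to()]).
#' @return the depot, invisibly (device state is environment-backed).
#' @export
set_stage_axes <- function(depot, axes) {
  for (a in axes) {
    st <- device_state(depot, a$handler$device_name)
    nm <- vapply(st$axes, function(x) x$handler$name, character(1))
    st$axes[[which(nm == a$handler$name)]] <- a
  }
  invisible(depot)
}

#' Current macro position of a depot's stage
#' @param depot a `scope_depot`.
#' @return a [macro_position()].
#' @export
depot_position <- function(depot) current_position(stage_axes(depot))

#' Move a depot's stage to a target macro position
#' @param depot a `scope_depot`.
#' @param target a [macro_position()].
#' @return the depot, invisibly.
#' @export
depot_move_to <- function(depot, target) {
  set_stage_axes(depot, move_to(stage_axes(depot), target))
}
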