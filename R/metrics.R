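#' Geometric metrics of one track
#'
#' Length is the sum of all step displacements; displacement is the distance
#' between the first and last point; straightness is their ratio (1 for a
#' ballistic track, towards 0 for constrained ones, and defined as 0 when
#' the length is 0); mean speed is length over elapsed time. With
#' `window_s` set, the track is truncated to its first `window_s` seconds
#' before computing (a single per-track value, not a sliding window).
#'
#' @param traj A [trajectory()].
#' @param window_s Optional window in seconds.
#'
#' @return List of class `"track_metrics"`: `track_id`, `condition`,
#'   `window_s`, `length`, `displacement`, `straightness`, `mean_speed`.
#' @export
#' @examples
#' tr <- trajectory("L", times = 0:2, positions = rbind(c(0, 0), c(1, 0), c(1, 1)))
#' track_metrics(tr)$straightness  # 1/sqrt(2)
track_metrics <- function(traj, window_s = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  times <- traj$times
  pos <- traj$positions
  win <- if (is.null(window_s)) diff(range(times)) else window_s
  if (!is.null(window_s)) {
    keep <- times <= times[1] + window_s + 1e-9
    times <- times[keep]
    pos <- pos[keep, , drop = FALSE]
  }
  if (length(times) < 2L)
    stop("track ", traj$track_id,
         " has fewer than 2 points in the requested window")
  steps <- sqrt(rowSums(diff(pos)^2))
  len <- sum(steps)
  disp <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  structure(list(track_id = traj$track_id, condition = traj$condition,
                 window_s = win, length = len, displacement = disp,
                 straightness = if (len > 0) disp / len else 0,
                 mean_speed = len / (times[length(times)] - times[1])),
            class = "track_metrics")
}

#' Metrics table for a set of tracks
#'
#' @param trajectories List of [trajectory()].
#' @param window_s Optional window in seconds (see [track_metrics()]).
#' @return `data.frame` with columns `track_id`, `condition`, `window_s`,
#'   `length_um`, `displacement_um`, `straightness`, `speed_um_s`.
#' @export
metrics_table <- function(trajectories, window_s = NULL) {
  rows <- lapply(trajectories, function(tr) {
    m <- track_metrics(tr, window_s)
    data.frame(track_id = m$track_id, condition = m$condition,
               window_s = m$window_s, length_um = m$length,
               displacement_um = m$displacement,
               straightness = m$straightness, speed_um_s = m$mean_speed,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(track_id = character(), condition = character(),
                      window_s = numeric(), length_um = numeric(),
                      displacement_um = numeric(), straightness = numeric(),
                      speed_um_s = numeric()))
  do.call(rbind, rows)
}

#' Keep only tracks with enough recorded steps
#'
#' Tracks with fewer than `min_steps` displacement steps carry too little
#' information for MSD model fitting and are discarded before analysis.
#'
#' @param trajectories List of [trajectory()].
#' @param min_steps Minimum step count (default 6).
#' @param verbose Log the number of removed tracks.
#' @return Filtered list, with attribute `"n_removed"`.
#' @export
filter_min_steps <- function(trajectories, min_steps = 6L, verbose = FALSE) {
  keep <- vapply(trajectories, function(tr) n_steps(tr) >= min_steps,
                 logical(1))
  if (verbose && any(!keep))
    message(sum(!keep), " track(s) removed by the ", min_steps,
            "-step filter")
  structure(trajectories[keep], n_removed = sum(!keep))
}

#' Planar membrane model
#'
#' Signed-distance model of a flat plasma membrane at a fixed coordinate
#' value; positive distances are inside the cell. Used as the default
#' programmable stand-in for a manually drawn cell-interior region.
#'
#' @param level Membrane coordinate, um.
#' @param axis Coordinate axis the plane is normal to (1 = x, 2 = y,
#'   3 = z).
#' @param inside `"above"` if the cell interior has coordinates greater
#'   than `level`, `"below"` otherwise.
#' @return Function mapping a position vector to a signed distance (um).
#' @export
plane_membrane <- function(level = 0, axis = 3L, inside = c("above",
                                                            "below")) {
  inside <- match.arg(inside)
  sign <- if (inside == "above") 1 else -1
  function(point) {
    if (length(point) < axis) return(NA_real_)
    sign * (point[axis] - level)
  }
}

#' Remove membrane-proximal tracks
#'
#' Discards every track having at least one point closer than `margin` to
#' the membrane (granules within that distance belong to the
#' membrane-proximal pool, analyzed separately by TIRF). Removal is
#' whole-track: clipping single points would bias the MSD.
#'
#' @param trajectories List of [trajectory()].
#' @param membrane_model Function mapping a position to a signed distance,
#'   positive inside the cell (see [plane_membrane()]).
#' @param margin Exclusion margin, um (default 0.2).
#' @param verbose Log the number of removed tracks.
#' @return Filtered list, with attribute `"n_removed"`.
#' @export
exclude_membrane_proximal <- function(trajectories, membrane_model,
                                      margin = 0.2, verbose = FALSE) {
  stopifnot(is.function(membrane_model), margin >= 0)
  keep <- vapply(trajectories, function(tr) {
    d <- apply(tr$positions, 1L, membrane_model)
    if (anyNA(d))
      stop("membrane model undefined at point ",
           paste(round(tr$positions[which(is.na(d))[1], ], 4),
                 collapse = ", "),
           " of track ", tr$track_id)
    all(d >= margin)
  }, logical(1))
  if (verbose && any(!keep))
    message(sum(!keep), " membrane-proximal track(s) removed (margin ",
            margin, " um)")
  structure(trajectories[keep], n_removed = sum(!keep))
}
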