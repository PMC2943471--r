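#' Construct a single-particle trajectory
#'
#' A trajectory is the ordered sequence of positions (in micrometers) and
#' timestamps (in seconds) of one tracked granule, in 2 or 3 dimensions.
#'
#' @param track_id Identifier (coerced to character).
#' @param times Numeric vector of timestamps in seconds, strictly increasing.
#' @param positions Numeric matrix with one row per time point and `dim`
#'   columns (micrometers). A vector is accepted for 1-row input.
#' @param cell_id Optional cell identifier.
#' @param condition Optional free-text condition label.
#' @param true_label Optional ground-truth motion class (set by the
#'   simulator; never consulted by the classifier).
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `track_id`, `dim`, `times`, `positions`, `cell_id`, `condition` and
#'   (possibly `NA`) `true_label`.
#' @export
#' @examples
#' tr <- trajectory("t1", times = 0:3, positions = cbind(0:3, 0, 0))
#' n_steps(tr)
trajectory <- function(track_id, times, positions, cell_id = NA_character_,
                       condition = NA_character_, true_label = NA_character_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  times <- as.numeric(times)
  if (length(times) != nrow(positions))
    stop("positions count (", nrow(positions),
         ") must equal times count (", length(times), ")")
  if (length(times) < 2L)
    stop("a trajectory needs at least 2 points")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (track ", track_id, ")")
  if (anyNA(positions) || anyNA(times))
    stop("trajectory coordinates and times must be finite (track ",
         track_id, ")")
  dim <- ncol(positions)
  if (!dim %in% c(2L, 3L))
    stop("trajectories must be 2- or 3-dimensional, got dim = ", dim)
  structure(
    list(track_id = as.character(track_id), dim = dim, times = times,
         positions = positions, cell_id = as.character(cell_id),
         condition = as.character(condition),
         true_label = as.character(true_label)),
    class = "trajectory")
}

#' Number of displacement steps in a trajectory
#'
#' A track with n recorded points has n - 1 steps; downstream filters are
#' expressed in steps, matching the convention of tracking software.
#'
#' @param traj A [trajectory()].
#' @return Integer step count.
#' @export
n_steps <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  length(traj$times) - 1L
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> %dD, %d points, %.3g-%.3g s",
              x$track_id, x$dim, length(x$times),
              x$times[1], x$times[length(x$times)]))
  if (!is.na(x$condition)) cat(", condition:", x$condition)
  if (!is.na(x$true_label)) cat(", true label:", x$true_label)
  cat("\n")
  invisible(x)
}

# Deterministic child-seed derivation: one master seed, per-unit seeds by
# counter, so cohorts reproduce independently of generation order.
# Kept strictly below 2^31 - 1 (R integer range).
child_seed <- function(master, counter) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(counter) * 104729
  as.integer(s %% m) + 1L
}
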