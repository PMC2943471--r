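#' Movie geometry
#'
#' Field-of-view and sampling description for synthetic movies. Voxel
#' centers sit at integer indices; positions are reported in micrometers
#' from the center of voxel (0, 0, 0). Defaults mirror a spinning-disk
#' acquisition: 0.2 um axial steps at 1 s per stack (use `nz = 1` and
#' `frame_interval_s = 0.1` for 2D TIRF movies at 100 ms/frame).
#'
#' @param nx,ny,nz Field size in voxels (`nz = 1` gives a 2D movie).
#' @param pixel_size_um Lateral pixel size, um.
#' @param z_step_um Axial step, um.
#' @param frame_interval_s Time between frames/stacks, s.
#' @return List of class `"movie_geometry"`.
#' @export
movie_geometry <- function(nx = 64L, ny = 64L, nz = 1L,
                           pixel_size_um = 0.1, z_step_um = 0.2,
                           frame_interval_s = 1) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, pixel_size_um > 0, z_step_um > 0,
            frame_interval_s > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 frame_interval_s = frame_interval_s),
            class = "movie_geometry")
}

#' Detection and linking parameters
#'
#' Defaults follow the published tracking setup: estimated object diameter
#' 0.3 um (the lateral optical resolution), maximum frame-to-frame linking
#' distance 0.5 um, gaps bridged across up to 2 missing frames, and tracks
#' with fewer than 6 recorded steps discarded.
#'
#' @param estimated_diameter Object diameter, um.
#' @param max_distance Maximum link distance per frame interval, um.
#' @param max_gap_frames Maximum number of bridged missing frames; the
#'   search radius across a gap scales as `max_distance * (gap + 1)`.
#' @param min_steps Minimum recorded steps per kept track.
#' @return List of class `"linking_config"`.
#' @export
linking_config <- function(estimated_diameter = 0.3, max_distance = 0.5,
                           max_gap_frames = 2L, min_steps = 6L) {
  stopifnot(estimated_diameter > 0, max_distance > 0, max_gap_frames >= 0,
            min_steps > 0)
  structure(list(estimated_diameter = estimated_diameter,
                 max_distance = max_distance,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_steps = as.integer(min_steps)),
            class = "linking_config")
}

# position (um) -> 0-based voxel coordinates c(x, y, z)
voxel_coords <- function(point, geometry) {
  c(point[1] / geometry$pixel_size_um, point[2] / geometry$pixel_size_um,
    if (length(point) >= 3) point[3] / geometry$z_step_um else 0)
}

#' Render a synthetic movie from trajectories
#'
#' Draws every granule as an isotropic (in um) Gaussian intensity profile at
#' its true position, on a constant background, with optional Poisson shot
#' noise. The output array is indexed `[t, z, y, x]` (or `[t, y, x]` when
#' `nz = 1`).
#'
#' @param trajectories List of [trajectory()] whose positions fit inside the
#'   field of view.
#' @param geometry A [movie_geometry()].
#' @param psf_sigma Gaussian profile s.d., um.
#' @param amplitude Peak intensity of one granule, counts.
#' @param background Constant background level, counts.
#' @param noise_model `"none"` or `"poisson"`.
#' @param seed Seed for the noise.
#' @return Numeric array of class `"movie_stack"` with the geometry attached
#'   as attribute `"geometry"`.
#' @export
render_movie <- function(trajectories, geometry, psf_sigma = 0.15,
                         amplitude = 1000, background = 10,
                         noise_model = c("none", "poisson"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(geometry, "movie_geometry"), psf_sigma > 0)
  g <- geometry
  is3d <- g$nz > 1L
  t0 <- if (length(trajectories))
    min(vapply(trajectories, function(tr) tr$times[1], numeric(1))) else 0
  tmax <- if (length(trajectories))
    max(vapply(trajectories, function(tr) max(tr$times), numeric(1))) else 0
  n_frames <- max(1L, as.integer(round((tmax - t0) / g$frame_interval_s)) +
                    1L)
  stack <- array(background,
                 dim = if (is3d) c(n_frames, g$nz, g$ny, g$nx)
                 else c(n_frames, g$ny, g$nx))
  sig_vox <- c(psf_sigma / g$pixel_size_um, psf_sigma / g$pixel_size_um,
               psf_sigma / g$z_step_um)
  half <- ceiling(5 * sig_vox)
  for (tr in trajectories) {
    for (i in seq_along(tr$times)) {
      fr <- as.integer(round((tr$times[i] - t0) / g$frame_interval_s)) + 1L
      vc <- voxel_coords(tr$positions[i, ], g)
      lim <- c(g$nx, g$ny, if (is3d) g$nz else 1L) - 1L
      ndim <- if (is3d) 3L else 2L
      if (any(vc[1:ndim] < 0) || any(vc[1:ndim] > lim[1:ndim]))
        stop("track ", tr$track_id, " leaves the field of view at t = ",
             tr$times[i], " s")
      xr <- max(0, floor(vc[1] - half[1])):min(g$nx - 1L,
                                               ceiling(vc[1] + half[1]))
      yr <- max(0, floor(vc[2] - half[2])):min(g$ny - 1L,
                                               ceiling(vc[2] + half[2]))
      gx <- exp(-(xr - vc[1])^2 / (2 * sig_vox[1]^2))
      gy <- exp(-(yr - vc[2])^2 / (2 * sig_vox[2]^2))
      if (is3d) {
        zr <- max(0, floor(vc[3] - half[3])):min(g$nz - 1L,
                                                 ceiling(vc[3] + half[3]))
        gz <- exp(-(zr - vc[3])^2 / (2 * sig_vox[3]^2))
        blob <- amplitude * outer(gz, outer(gy, gx))
        stack[fr, zr + 1L, yr + 1L, xr + 1L] <-
          stack[fr, zr + 1L, yr + 1L, xr + 1L] + blob
      } else {
        blob <- amplitude * outer(gy, gx)
        stack[fr, yr + 1L, xr + 1L] <- stack[fr, yr + 1L, xr + 1L] + blob
      }
    }
  }
  if (noise_model == "poisson") {
    set.seed(seed)
    stack[] <- stats::rpois(length(stack), lambda = stack)
  }
  structure(stack, geometry = g, class = c("movie_stack", "array"))
}

# separable 1-D convolution of an array along one dimension, via a banded
# Toeplitz matrix; edges renormalized so flat regions stay flat.
conv_along <- function(arr, kernel, dim_idx) {
  d <- dim(arr)
  n <- d[dim_idx]
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -half:half) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- kernel[o + half + 1L]
  }
  K <- K / rowSums(K)
  perm <- c(dim_idx, setdiff(seq_along(d), dim_idx))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Detect spots in one frame
#'
#' Band-pass filtering (Gaussian smoothing at the object scale minus a
#' boxcar local background at twice the object diameter), local-maximum
#' candidate selection, and refinement by intensity-weighted center of mass
#' in a window matched to the estimated diameter. Positions are returned in
#' micrometers.
#'
#' @param frame One time point: a `[y, x]` matrix or `[z, y, x]` array.
#' @param config A [linking_config()].
#' @param geometry A [movie_geometry()].
#' @param threshold_rel Candidate threshold, as a fraction of the band-pass
#'   maximum.
#' @return `data.frame` with columns `x_um`, `y_um`, (`z_um`,) `intensity`;
#'   zero rows for an empty or constant frame (with a warning for the
#'   latter).
#' @export
detect_spots <- function(frame, config = linking_config(),
                         geometry = movie_geometry(),
                         threshold_rel = 0.2) {
  g <- geometry
  is3d <- length(dim(frame)) == 3L
  if (max(frame) - min(frame) <= 0) {
    warning("constant frame: no detections")
    return(empty_detections(is3d))
  }
  sig_px <- max(0.5, config$estimated_diameter / (4 * g$pixel_size_um))
  arr <- if (is3d) frame else array(frame, dim = c(1L, dim(frame)))
  sig <- c(if (is3d) max(0.5, config$estimated_diameter /
                           (4 * g$z_step_um)) else 0, sig_px, sig_px)
  smooth <- arr
  for (ax in 1:3) {
    if (dim(arr)[ax] == 1L || sig[ax] <= 0) next
    smooth <- conv_along(smooth, gaussian_kernel(sig[ax]), ax)
  }
  box <- smooth
  for (ax in 1:3) {
    if (dim(arr)[ax] == 1L) next
    w <- 2L * ceiling(config$estimated_diameter /
                        (if (ax == 1L) g$z_step_um else g$pixel_size_um)) +
      1L
    box <- conv_along(box, rep(1, w), ax)
  }
  bp <- pmax(smooth - box, 0)
  thr <- threshold_rel * max(bp)
  if (thr <= 0) return(empty_detections(is3d))
  cand <- which(bp >= thr, arr.ind = TRUE)
  dz <- dim(arr)[1]; dy <- dim(arr)[2]; dx <- dim(arr)[3]
  is_max <- apply(cand, 1L, function(ix) {
    z <- ix[1]; y <- ix[2]; x <- ix[3]
    nb <- bp[max(1, z - 1):min(dz, z + 1),
             max(1, y - 1):min(dy, y + 1),
             max(1, x - 1):min(dx, x + 1)]
    bp[z, y, x] >= max(nb)
  })
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty_detections(is3d))
  # merge maxima closer than one diameter, keep the brightest
  vals <- bp[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  scale <- c(g$z_step_um, g$pixel_size_um, g$pixel_size_um)
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    pos_i <- (cand[i, ] - 1) * scale
    too_close <- FALSE
    for (j in kept) {
      if (sqrt(sum(((cand[j, ] - 1) * scale - pos_i)^2)) <
          config$estimated_diameter) {
        too_close <- TRUE
        break
      }
    }
    if (!too_close) kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]
  # center-of-mass refinement on background-subtracted intensities
  bgr <- stats::median(arr)
  win <- pmax(1L, ceiling(config$estimated_diameter /
                            c(g$z_step_um, g$pixel_size_um,
                              g$pixel_size_um)))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
    zr <- if (dz > 1L) max(1, z - win[1]):min(dz, z + win[1]) else 1L
    yr <- max(1, y - win[2]):min(dy, y + win[2])
    xr <- max(1, x - win[3]):min(dx, x + win[3])
    sub <- pmax(arr[zr, yr, xr, drop = FALSE] - bgr, 0)
    tot <- sum(sub)
    if (tot <= 0) return(NULL)
    com <- function(axis_vals, axis) {
      w <- apply(sub, axis, sum)
      sum(axis_vals * w) / tot
    }
    cz <- if (dz > 1L) com(zr - 1L, 1L) else 0
    cy <- com(yr - 1L, 2L)
    cx <- com(xr - 1L, 3L)
    out <- data.frame(x_um = cx * g$pixel_size_um,
                      y_um = cy * g$pixel_size_um, intensity = tot)
    if (is3d) out$z_um <- cz * g$z_step_um
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_detections(is3d))
  out <- do.call(rbind, rows)
  if (is3d) out <- out[, c("x_um", "y_um", "z_um", "intensity")]
  out
}

empty_detections <- function(is3d) {
  if (is3d)
    data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
               intensity = numeric())
  else data.frame(x_um = numeric(), y_um = numeric(), intensity = numeric())
}

#' Detect spots in every frame of a movie
#'
#' @param stack A [render_movie()] result (or compatible array with a
#'   `"geometry"` attribute).
#' @param config A [linking_config()].
#' @param ... Passed to [detect_spots()].
#' @return List of per-frame detection tables.
#' @export
detect_movie <- function(stack, config = linking_config(), ...) {
  g <- attr(stack, "geometry")
  stopifnot(!is.null(g))
  nt <- dim(stack)[1]
  is3d <- length(dim(stack)) == 4L
  lapply(seq_len(nt), function(fr) {
    frame <- if (is3d) array(stack[fr, , , ], dim = dim(stack)[-1])
    else matrix(stack[fr, , ], dim(stack)[2], dim(stack)[3])
    detect_spots(frame, config, g, ...)
  })
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbor linking: at each frame, candidate
#' (track, detection) pairs within the allowed radius are accepted in order
#' of increasing distance, each track and detection at most once. A track
#' missing from up to `max_gap_frames` consecutive frames may be bridged,
#' with search radius `max_distance * (gap + 1)`; bridged positions are
#' omitted, not interpolated. Detections claimed by two tracks at exactly
#' equal distance are left unlinked and both tracks terminated
#' (conservative), counted in attribute `"n_ambiguous"`. Tracks with fewer
#' than `min_steps` steps are discarded.
#'
#' @param detections List of per-frame detection tables (from
#'   [detect_movie()] or [detect_spots()]), ordered in time.
#' @param config A [linking_config()].
#' @param frame_interval_s Time between consecutive frames, s.
#' @param condition Condition label for the output trajectories.
#' @return List of [trajectory()], with attribute `"n_ambiguous"`.
#' @export
link_detections <- function(detections, config = linking_config(),
                            frame_interval_s = 1,
                            condition = NA_character_) {
  stopifnot(inherits(config, "linking_config"))
  active <- list()   # each: list(pos = matrix, frames = int vector)
  done <- list()
  n_ambiguous <- 0L
  for (fr in seq_along(detections)) {
    det <- detections[[fr]]
    coords <- if (nrow(det))
      as.matrix(det[, intersect(c("x_um", "y_um", "z_um"), names(det)),
                    drop = FALSE])
    else matrix(numeric(), 0, 0)
    # expire tracks out of gap range
    if (length(active)) {
      last <- vapply(active, function(a) a$frames[length(a$frames)],
                     integer(1))
      expired <- fr - last > config$max_gap_frames + 1L
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    n_det <- nrow(det)
    linked_det <- rep(FALSE, n_det)
    if (length(active) && n_det) {
      pairs <- list()
      for (ti in seq_along(active)) {
        a <- active[[ti]]
        gap <- fr - a$frames[length(a$frames)]
        radius <- config$max_distance * gap
        p <- a$pos[nrow(a$pos), ]
        dists <- sqrt(rowSums((coords -
                                 matrix(p, n_det, length(p),
                                        byrow = TRUE))^2))
        ok <- which(dists <= radius)
        for (di in ok)
          pairs[[length(pairs) + 1L]] <- c(ti, di, dists[di])
      }
      if (length(pairs)) {
        pm <- do.call(rbind, pairs)
        pm <- pm[order(pm[, 3]), , drop = FALSE]
        used_t <- logical(length(active))
        closed_t <- logical(length(active))
        i <- 1L
        while (i <= nrow(pm)) {
          ti <- pm[i, 1]; di <- pm[i, 2]
          tie <- which(abs(pm[, 3] - pm[i, 3]) < 1e-12 & pm[, 2] == di &
                         pm[, 1] != ti & !used_t[pm[, 1]])
          if (length(tie) && !used_t[ti] && !linked_det[di]) {
            # two unlinked tracks claim one detection at equal distance
            n_ambiguous <- n_ambiguous + 1L
            closed_t[ti] <- TRUE
            closed_t[pm[tie, 1]] <- TRUE
            used_t[ti] <- TRUE
            used_t[pm[tie, 1]] <- TRUE
            i <- i + 1L
            next
          }
          if (!used_t[ti] && !linked_det[di]) {
            active[[ti]]$pos <- rbind(active[[ti]]$pos, coords[di, ])
            active[[ti]]$frames <- c(active[[ti]]$frames, fr)
            used_t[ti] <- TRUE
            linked_det[di] <- TRUE
          }
          i <- i + 1L
        }
        if (any(closed_t)) {
          done <- c(done, active[closed_t])
          active <- active[!closed_t]
        }
      }
    }
    for (di in which(!linked_det))
      active[[length(active) + 1L]] <- list(pos = coords[di, , drop = FALSE],
                                            frames = fr)
  }
  done <- c(done, active)
  done <- Filter(function(a) nrow(a$pos) - 1L >= config$min_steps, done)
  out <- lapply(seq_along(done), function(i) {
    a <- done[[i]]
    trajectory(sprintf("trk%04d", i),
               times = (a$frames - 1L) * frame_interval_s,
               positions = a$pos, condition = condition)
  })
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}
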