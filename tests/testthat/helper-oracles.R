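# Independent oracles and small fixture builders, kept deliberately naive.

# Brute-force time-averaged MSD: explicit double loop over all ordered index
# pairs, grouped by frame lag. Independent of compute_msd's vectorized path.
brute_msd <- function(times, positions, max_lag_fraction = 1) {
  dt <- min(diff(times))
  frames <- round((times - times[1]) / dt)
  span <- frames[length(frames)]
  max_lag <- max(1, floor(span * max_lag_fraction))
  sums <- numeric(max_lag)
  counts <- integer(max_lag)
  npt <- length(times)
  for (i in 1:(npt - 1)) {
    for (j in (i + 1):npt) {
      lag <- frames[j] - frames[i]
      if (lag > max_lag) next
      d2 <- sum((positions[j, ] - positions[i, ])^2)
      sums[lag] <- sums[lag] + d2
      counts[lag] <- counts[lag] + 1L
    }
  }
  keep <- counts > 0L
  list(lag_times = (seq_len(max_lag) * dt)[keep], msd = (sums / counts)[keep],
       n_pairs = counts[keep])
}

# Build an msd_curve directly from values (synthetic noise-free model curves).
make_curve <- function(msd, dim = 3, dt = 1, n_pairs = rep(10L, length(msd)),
                       track_id = "synth") {
  structure(list(track_id = track_id, dim = dim, dt = dt,
                 lag_times = seq_along(msd) * dt, msd = msd,
                 n_pairs = n_pairs),
            class = "msd_curve")
}

# Fake fit triple with prescribed r^2 values, for decision-rule tests.
make_fits <- function(r2_random, r2_directed, r2_caged) {
  structure(list(
    random = granmotion:::msd_fit_result("random", D = 0.01, k = 0,
                                         r_squared = r2_random),
    directed = granmotion:::msd_fit_result("directed", D = 0.01, v = 0.1,
                                           k = 0, r_squared = r2_directed),
    caged = granmotion:::msd_fit_result("caged", D = 0.01, R = 0.5, k = 0,
                                        r_squared = r2_caged)),
    class = "msd_fits")
}

# Rigid rotation about the origin (x-y plane) plus translation.
rigid_transform <- function(traj, angle = 0.7, shift = c(3, -2, 5)) {
  p <- traj$positions
  rot <- p
  rot[, 1] <- cos(angle) * p[, 1] - sin(angle) * p[, 2]
  rot[, 2] <- sin(angle) * p[, 1] + cos(angle) * p[, 2]
  rot <- sweep(rot, 2, shift[seq_len(ncol(p))], "+")
  trajectory(traj$track_id, traj$times, rot, traj$cell_id, traj$condition,
             traj$true_label)
}

# The four-regime benchmark cohort (granule-scale parameters).
benchmark_cohort_spec <- function(n_per_regime = 200L) {
  data.frame(model = c("immobile", "random", "directed", "caged"),
             count = n_per_regime,
             D = c(0, 0.02, 0.005, 0.05),
             v = c(0, 0, 0.15, 0),
             R = c(NA, NA, NA, 0.4),
             sigma_loc = 0.02, n_steps = 50L, dt = 1)
}
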