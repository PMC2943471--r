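#' Time-averaged mean square displacement of one track
#'
#' MSD(n*dt) is the average of |r(i+n) - r(i)|^2 over all ordered index
#' pairs at integer frame lag n. Tracks must sit on a uniform base frame
#' interval; missing frames (gaps) are allowed and handled by pair
#' exclusion, so a lag's average uses only the pairs actually observed.
#'
#' @param traj A [trajectory()] with at least 6 steps.
#' @param max_lag_fraction Largest lag retained, as a fraction of the track
#'   duration in frames (default 0.5: long-lag MSD estimates average few
#'   pairs and are noisy). Use 1 for threshold-style maximum-MSD tests.
#'
#' @return Object of class `"msd_curve"`: list with `track_id`, `dim`, `dt`,
#'   `lag_times` (s), `msd` (um^2) and `n_pairs` per retained lag.
#' @export
#' @examples
#' tr <- trajectory("drift", times = 0:6, positions = cbind(0:6, 0, 0))
#' compute_msd(tr, max_lag_fraction = 1)$msd  # n^2 for pure 1 um/s drift
compute_msd <- function(traj, max_lag_fraction = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_steps(traj) < 6L)
    stop("track ", traj$track_id, " has fewer than 6 steps")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]")
  times <- traj$times
  diffs <- diff(times)
  dt <- min(diffs)
  frames <- round((times - times[1]) / dt)
  if (max(abs(times - times[1] - frames * dt)) > 1e-6 * dt)
    stop("track ", traj$track_id,
         " has a non-uniform base frame interval; resample before MSD")
  span <- frames[length(frames)]
  max_lag <- max(1L, floor(span * max_lag_fraction))
  idx_of <- integer(span + 1L)
  idx_of[frames + 1L] <- seq_along(frames)
  pos <- traj$positions
  lags <- seq_len(max_lag)
  msd <- rep(NA_real_, max_lag)
  npairs <- integer(max_lag)
  for (n in lags) {
    i <- which(frames <= span - n)
    j <- idx_of[frames[i] + n + 1L]
    keep <- j > 0L
    i <- i[keep]; j <- j[keep]
    if (!length(i)) next
    d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    msd[n] <- mean(rowSums(d * d))
    npairs[n] <- length(i)
  }
  keep <- npairs >= 1L
  if (sum(keep) < 5L)
    stop("track ", traj$track_id, " too short for fitting: ",
         sum(keep), " retained lags (need >= 5)")
  structure(list(track_id = traj$track_id, dim = traj$dim, dt = dt,
                 lag_times = lags[keep] * dt, msd = msd[keep],
                 n_pairs = npairs[keep]),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve %s> %dD, %d lags (%.3g-%.3g s), max MSD %.4g um^2\n",
              x$track_id, x$dim, length(x$lag_times), x$lag_times[1],
              max(x$lag_times), max(x$msd)))
  invisible(x)
}

# Exact non-negative weighted least squares for <= 3 linear parameters, by
# enumerating active sets. Small p makes this both exact and fast; no NNLS
# package is assumed.
nnls_small <- function(X, y, w) {
  p <- ncol(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  best <- rep(0, p)
  best_ss <- sum(yw^2)
  for (mask in seq_len(2^p - 1L)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    Xf <- Xw[, free, drop = FALSE]
    cf <- tryCatch(solve(crossprod(Xf), crossprod(Xf, yw)),
                   error = function(e) NULL)
    if (is.null(cf) || any(cf < 0)) next
    ss <- sum((yw - Xf %*% cf)^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- rep(0, p)
      best[free] <- cf
    }
  }
  list(coef = best, ss = best_ss)
}

msd_fit_result <- function(model, D = 0, v = NA_real_, R = NA_real_, k = 0,
                           r_squared, converged = TRUE) {
  structure(list(model = model, D = D, v = v, R = R, k = k,
                 r_squared = r_squared, converged = converged),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit %s> D=%.4g", x$model, x$D))
  if (!is.na(x$v)) cat(sprintf(" v=%.4g", x$v))
  if (!is.na(x$R)) cat(sprintf(" R=%.4g", x$R))
  cat(sprintf(" k=%.4g r2=%.4g\n", x$k, x$r_squared))
  invisible(x)
}

caged_model <- function(t, R2, D, k, dim, a1, a2)
  R2 * (1 - a1 * exp(-2 * dim * a2 * D * t / R2)) + k

#' Fit the three diffusion models to an MSD curve
#'
#' Fits, by least squares weighted with the number of displacement pairs per
#' lag, the three standard MSD models with a constant localization offset k
#' (2D uses prefactor 4*D, 3D uses 6*D):
#' \describe{
#'   \item{random}{`MSD = 2*dim*D*t + k`}
#'   \item{directed}{`MSD = 2*dim*D*t + (v*t)^2 + k`}
#'   \item{caged}{`MSD = R^2 * (1 - a1*exp(-2*dim*a2*D*t / R^2)) + k`,
#'     with constants a1 = 0.99, a2 = 0.85 (confined-diffusion series
#'     approximation); here D is the cage diffusion coefficient.}
#' }
#' All parameters are constrained non-negative (R > 0). The linear models
#' are solved exactly by active-set non-negative least squares; the caged
#' model by bounded quasi-Newton optimization initialized at the plateau
#' estimate (mean of the last 3 MSD points), D from the first lag, k = 0.
#'
#' Goodness of fit is the coefficient of determination
#' `r2 = 1 - SS_res/SS_tot` with the same pair-count weights (SS_tot about
#' the weighted mean). A model whose optimizer fails is returned with
#' `r_squared = -Inf` and a warning; the other fits are unaffected.
#'
#' @param curve An [compute_msd()] result.
#' @param a1,a2 Constants of the confined-diffusion approximation.
#' @param prefactor Dimensional diffusion prefactor; default `2 * curve$dim`
#'   (4 in 2D, 6 in 3D). Override only to emulate non-standard conventions.
#'
#' @return Object of class `"msd_fits"`: named list of three `"msd_fit"`
#'   entries (`random`, `directed`, `caged`).
#' @export
fit_msd_models <- function(curve, a1 = 0.99, a2 = 0.85, prefactor = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  t <- curve$lag_times
  y <- curve$msd
  w <- curve$n_pairs
  dim <- curve$dim
  pf <- if (is.null(prefactor)) 2 * dim else prefactor
  wmean <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - wmean)^2)
  r2_of <- function(pred) {
    ss_res <- sum(w * (y - pred)^2)
    if (ss_tot <= 0) return(if (ss_res <= 1e-24) 1 else -Inf)
    1 - ss_res / ss_tot
  }

  fr <- nnls_small(cbind(pf * t, 1), y, w)
  random <- msd_fit_result("random", D = fr$coef[1], k = fr$coef[2],
                           r_squared = r2_of(cbind(pf * t, 1) %*% fr$coef))

  fd <- nnls_small(cbind(pf * t, t^2, 1), y, w)
  directed <- msd_fit_result("directed", D = fd$coef[1],
                             v = sqrt(fd$coef[2]), k = fd$coef[3],
                             r_squared =
                               r2_of(cbind(pf * t, t^2, 1) %*% fd$coef))

  caged <- tryCatch({
    plateau <- max(mean(utils::tail(y, 3L)), 1e-8)
    D0 <- max(y[1] / (pf * t[1]), 1e-10)
    obj <- function(p)
      sum(w * (y - caged_model(t, p[1], p[2], p[3], dim, a1, a2))^2)
    grad <- function(p) {
      e <- exp(-2 * dim * a2 * p[2] * t / p[1])
      resid <- y - (p[1] * (1 - a1 * e) + p[3])
      dR2 <- (1 - a1 * e) - a1 * e * (2 * dim * a2 * p[2] * t / p[1])
      dD <- a1 * e * 2 * dim * a2 * t
      c(-2 * sum(w * resid * dR2), -2 * sum(w * resid * dD),
        -2 * sum(w * resid))
    }
    best <- NULL
    for (init in list(c(plateau, D0, 0), c(plateau, 10 * D0, 0),
                      c(max(y), D0 / 10, 0))) {
      op <- tryCatch(
        stats::optim(init, obj, grad, method = "L-BFGS-B",
                     lower = c(1e-12, 0, 0),
                     control = list(factr = 1e1, pgtol = 0, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value))
        best <- op
    }
    if (is.null(best)) stop("all caged starts failed")
    # derivative-free polish: tightens exact-model recovery to ~1e-8
    pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    if (pol$value <= best$value && all(pol$par >= c(1e-12, 0, 0)))
      best <- pol
    pred <- caged_model(t, best$par[1], best$par[2], best$par[3], dim, a1, a2)
    msd_fit_result("caged", D = best$par[2], R = sqrt(best$par[1]),
                   k = best$par[3], r_squared = r2_of(pred))
  }, error = function(e) {
    warning("caged fit did not converge for track ", curve$track_id, ": ",
            conditionMessage(e))
    msd_fit_result("caged", R = NA_real_, r_squared = -Inf,
                   converged = FALSE)
  })

  structure(list(random = random, directed = directed, caged = caged),
            class = "msd_fits")
}

#' @export
print.msd_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Average MSD curves per class
#'
#' Unweighted mean of per-track MSD values at each lag, per class label,
#' restricted to lags present in at least 80% of the class's tracks (so the
#' average is not driven by the few longest tracks).
#'
#' @param curves List of [compute_msd()] results sharing one base lag grid.
#' @param class_labels Character vector, one label per curve.
#' @param min_presence Minimum fraction of tracks a lag must appear in.
#'
#' @return `data.frame` with columns `class`, `lag_s`, `msd_um2`, `n_tracks`.
#' @export
average_msd <- function(curves, class_labels, min_presence = 0.8) {
  stopifnot(length(curves) == length(class_labels))
  if (!length(curves))
    return(data.frame(class = character(), lag_s = numeric(),
                      msd_um2 = numeric(), n_tracks = integer()))
  dts <- vapply(curves, function(cu) cu$dt, numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("curves do not share a common base lag grid")
  out <- list()
  for (cl in unique(class_labels)) {
    sel <- curves[class_labels == cl]
    if (!length(sel)) {
      warning("class ", cl, " is empty; omitted")
      next
    }
    lag_tab <- table(unlist(lapply(sel, function(cu)
      round(cu$lag_times / cu$dt))))
    keep_lags <- as.integer(names(lag_tab))[lag_tab >= min_presence *
                                              length(sel)]
    if (!length(keep_lags)) next
    keep_lags <- sort(keep_lags)
    vals <- sapply(keep_lags, function(n) {
      v <- vapply(sel, function(cu) {
        i <- match(n, round(cu$lag_times / cu$dt))
        if (is.na(i)) NA_real_ else cu$msd[i]
      }, numeric(1))
      mean(v, na.rm = TRUE)
    })
    out[[cl]] <- data.frame(class = cl, lag_s = keep_lags * dts[1],
                            msd_um2 = vals,
                            n_tracks = length(sel),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(class = character(), lag_s = numeric(),
                      msd_um2 = numeric(), n_tracks = integer()))
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
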