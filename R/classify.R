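#' Motion classification thresholds
#'
#' Defaults reproduce the published decision procedure: a track whose MSD
#' never exceeds 0.2 um^2 within the 50 s observation window is immobile
#' (the 0.2 um^2 bound being the 95th percentile of per-track maximum MSD in
#' fixed cells); if every model fit has r^2 below 0.33 the movement is
#' complex; if the standard deviation of the three r^2 values is below 0.015
#' the movement is random (a guard so that nearly linear MSDs are not won by
#' the extra parameters of the directed/caged models); otherwise the model
#' with the highest r^2 wins.
#'
#' @param immobile_msd_max Maximum-MSD immobility bound, um^2.
#' @param observation_window Lag window for the immobility test, s.
#' @param complex_r2_cutoff All-fits r^2 cutoff below which a track is
#'   complex.
#' @param random_r2_std_cutoff r^2 standard-deviation cutoff below which a
#'   mobile track is random regardless of the best fit.
#' @param fixed_percentile Percentile (in %) of per-track maximum MSD used
#'   when recalibrating the immobility bound from fixed-cell tracks.
#' @param max_lag_fraction Lag fraction passed to [compute_msd()] for model
#'   fitting (the immobility test always uses the full lag range).
#'
#' @return List of class `"classification_config"`.
#' @export
classification_config <- function(immobile_msd_max = 0.2,
                                  observation_window = 50,
                                  complex_r2_cutoff = 0.33,
                                  random_r2_std_cutoff = 0.015,
                                  fixed_percentile = 95,
                                  max_lag_fraction = 0.5) {
  stopifnot(immobile_msd_max > 0, observation_window > 0,
            complex_r2_cutoff > 0, complex_r2_cutoff < 1,
            random_r2_std_cutoff > 0,
            fixed_percentile > 0, fixed_percentile <= 100)
  structure(list(immobile_msd_max = immobile_msd_max,
                 observation_window = observation_window,
                 complex_r2_cutoff = complex_r2_cutoff,
                 random_r2_std_cutoff = random_r2_std_cutoff,
                 fixed_percentile = fixed_percentile,
                 max_lag_fraction = max_lag_fraction),
            class = "classification_config")
}

#' Calibrate the immobility threshold from fixed-cell tracks
#'
#' Computes the `fixed_percentile`-th percentile of per-track maximum MSD
#' over a population of fixed-cell (immobile) tracks. With no fixed data the
#' published default of 0.2 um^2 is returned unchanged.
#'
#' @param fixed_tracks List of [trajectory()] from fixed cells, or `NULL`.
#' @param config A [classification_config()].
#' @param min_tracks Minimum population size for a meaningful percentile.
#'
#' @return Threshold in um^2.
#' @export
calibrate_immobile_threshold <- function(fixed_tracks = NULL,
                                         config = classification_config(),
                                         min_tracks = 20L) {
  if (is.null(fixed_tracks)) return(config$immobile_msd_max)
  if (!length(fixed_tracks)) stop("empty fixed-cell track set")
  if (length(fixed_tracks) < min_tracks)
    stop("need >= ", min_tracks, " fixed-cell tracks, got ",
         length(fixed_tracks))
  max_msd <- vapply(fixed_tracks, function(tr)
    max(compute_msd(tr, max_lag_fraction = 1)$msd), numeric(1))
  stats::quantile(max_msd, config$fixed_percentile / 100, names = FALSE,
                  type = 7)
}

#' Classify one track into the five motion classes
#'
#' Applies the decision procedure in order: (1) immobile if the maximum MSD
#' over all lags within the observation window does not exceed the
#' immobility bound; (2) complex if all three model r^2 fall below the
#' complex cutoff; (3) random if the standard deviation of the three r^2 is
#' below the random-override cutoff; (4) otherwise the model with the
#' highest r^2. Sentinel fits (`r_squared = -Inf`, from optimizer failure)
#' participate as negative infinity; if all three are sentinels the track is
#' complex, with a warning. Exact r^2 ties in step 4 go to the model with
#' fewer parameters (random, then caged, then directed).
#'
#' @param curve A full-lag [compute_msd()] curve (`max_lag_fraction = 1`),
#'   used for the maximum-MSD immobility test.
#' @param fits A [fit_msd_models()] result (typically fitted on the
#'   truncated curve).
#' @param config A [classification_config()].
#'
#' @return List of class `"motion_class"`: `label`, `rule_fired`, and the
#'   supporting `fit` (`NULL` for immobile/complex).
#' @export
classify_track <- function(curve, fits, config = classification_config()) {
  stopifnot(inherits(curve, "msd_curve"), inherits(fits, "msd_fits"),
            inherits(config, "classification_config"))
  in_window <- curve$lag_times <= config$observation_window + 1e-9
  max_msd <- max(curve$msd[in_window])
  if (max_msd <= config$immobile_msd_max)
    return(structure(list(label = "immobile", rule_fired = "max_msd",
                          fit = NULL), class = "motion_class"))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  if (all(!is.finite(r2)))
    warning("all three fits failed for track ", curve$track_id,
            "; classified complex")
  if (all(r2 < config$complex_r2_cutoff))
    return(structure(list(label = "complex", rule_fired = "all_r2_low",
                          fit = NULL), class = "motion_class"))
  r2_sd <- stats::sd(r2)
  if (is.finite(r2_sd) && r2_sd < config$random_r2_std_cutoff)
    return(structure(list(label = "random", rule_fired = "r2_std",
                          fit = fits$random), class = "motion_class"))
  # parsimony order breaks exact ties: random (2 par) < caged (3) < directed (3,
  # with the quadratic term the most permissive)
  order_pref <- c("random", "caged", "directed")
  best <- order_pref[which.max(r2[order_pref])]
  structure(list(label = best, rule_fired = "best_r2", fit = fits[[best]]),
            class = "motion_class")
}

#' @export
print.motion_class <- function(x, ...) {
  cat(sprintf("<motion_class> %s (rule: %s)\n", x$label, x$rule_fired))
  invisible(x)
}

#' Classify a cohort of trajectories
#'
#' Runs MSD computation, model fitting and [classify_track()] for every
#' trajectory and tabulates per-condition class fractions.
#'
#' @param trajectories List of [trajectory()] (already >= 6-step filtered).
#' @param config A [classification_config()].
#'
#' @return List with `table` (`data.frame`: `track_id`, `condition`,
#'   `label`, `rule_fired`, `best_model`, `D`, `v`, `R`, `k`, `r2`) and
#'   `fractions` (`data.frame`: `condition`, one column per class, `n`).
#'   An empty cohort yields empty tables with `fractions` flagged via 0 rows.
#' @export
classify_cohort <- function(trajectories, config = classification_config()) {
  classes <- c("immobile", "random", "directed", "caged", "complex")
  if (!length(trajectories)) {
    return(list(table = data.frame(track_id = character(),
                                   condition = character(),
                                   label = character(),
                                   rule_fired = character(),
                                   best_model = character(), D = numeric(),
                                   v = numeric(), R = numeric(),
                                   k = numeric(), r2 = numeric()),
                fractions = data.frame(condition = character())))
  }
  rows <- lapply(trajectories, function(tr) {
    full <- compute_msd(tr, max_lag_fraction = 1)
    fits <- fit_msd_models(compute_msd(tr, config$max_lag_fraction))
    mc <- classify_track(full, fits, config)
    f <- mc$fit
    data.frame(track_id = tr$track_id, condition = tr$condition,
               label = mc$label, rule_fired = mc$rule_fired,
               best_model = if (is.null(f)) NA_character_ else f$model,
               D = if (is.null(f)) NA_real_ else f$D,
               v = if (is.null(f)) NA_real_ else f$v,
               R = if (is.null(f)) NA_real_ else f$R,
               k = if (is.null(f)) NA_real_ else f$k,
               r2 = if (is.null(f)) NA_real_ else f$r_squared,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fracs <- do.call(rbind, lapply(split(tab, tab$condition), function(d) {
    counts <- table(factor(d$label, levels = classes))
    cbind(data.frame(condition = d$condition[1], stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts / nrow(d)))),
          data.frame(n = nrow(d)))
  }))
  rownames(fracs) <- NULL
  list(table = tab, fractions = fracs)
}
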