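#' Simulation parameters for one synthetic trajectory
#'
#' Bundles the kinematic regime and its parameters at lytic-granule scale.
#' The four regimes are: `"immobile"` (no true motion, localization noise
#' only), `"random"` (Brownian motion, per-axis step variance 2*D*dt),
#' `"directed"` (Brownian motion plus constant drift v), and `"caged"`
#' (Brownian motion reflected at a sphere/disc of radius R).
#'
#' Defaults follow the acquisition geometry of spinning-disk confocal
#' granule imaging: dt = 1 s per 3D stack (use dt = 0.1 s for 2D TIRF data)
#' and granule-scale magnitudes D ~ 0.001-0.05 um^2/s, v ~ 0.05-0.3 um/s,
#' R ~ 0.2-1 um.
#'
#' @param model One of `"immobile"`, `"random"`, `"directed"`, `"caged"`.
#' @param dim 2 or 3.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param v Drift velocity vector, um/s (directed only; recycled/truncated
#'   to `dim` entries).
#' @param R Cage radius, um (> 0; caged only).
#' @param sigma_loc Per-axis localization noise s.d., um (>= 0).
#' @param n_steps Number of displacement steps (>= 2); the track has
#'   `n_steps + 1` points.
#' @param dt Frame interval, s (> 0).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param origin Starting position (defaults to the origin).
#'
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(model, dim = 3, D = 0.01, v = c(0.1, 0, 0), R = 0.5,
                       sigma_loc = 0, n_steps = 50, dt = 1, seed = 1L,
                       origin = rep(0, dim)) {
  models <- c("immobile", "random", "directed", "caged")
  if (!is.character(model) || length(model) != 1L || !model %in% models)
    stop("unknown model label: ", deparse(model),
         " (expected one of ", paste(models, collapse = ", "), ")")
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3")
  if (!is.finite(D) || D < 0) stop("D must be >= 0, got ", D)
  if (model == "caged" && (!is.finite(R) || R <= 0))
    stop("R must be > 0 for the caged model")
  if (!is.finite(sigma_loc) || sigma_loc < 0) stop("sigma_loc must be >= 0")
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  v <- rep_len(as.numeric(v), dim)
  origin <- rep_len(as.numeric(origin), dim)
  structure(list(model = model, dim = dim, D = D, v = v, R = R,
                 sigma_loc = sigma_loc, n_steps = as.integer(n_steps),
                 dt = dt, seed = as.integer(seed), origin = origin),
            class = "sim_params")
}

#' Simulate one trajectory under a motion regime
#'
#' Generates true positions for the regime in `params`, then adds
#' independent per-axis Gaussian localization noise of s.d. `sigma_loc` to
#' every reported point. Caged motion uses a reflecting boundary on the
#' sphere (3D) or disc (2D) of radius R around the starting point.
#'
#' @param params A [sim_params()] object.
#' @param track_id,cell_id,condition Identifiers attached to the output.
#' @param keep_true If `TRUE`, the noise-free positions are attached as
#'   attribute `"true_positions"` (used by tests; never by the analysis).
#'
#' @return A [trajectory()] with `true_label` set to the regime.
#' @export
#' @examples
#' p <- sim_params("directed", dim = 3, D = 0, v = c(0.1, 0, 0),
#'                 sigma_loc = 0, n_steps = 10, dt = 1, seed = 7)
#' simulate_trajectory(p)
simulate_trajectory <- function(params, track_id = "sim1",
                                cell_id = NA_character_,
                                condition = NA_character_,
                                keep_true = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_steps
  d <- params$dim
  set.seed(params$seed)
  true_pos <- matrix(params$origin, n + 1L, d, byrow = TRUE)
  if (params$model != "immobile") {
    sd_step <- sqrt(2 * params$D * params$dt)
    steps <- matrix(stats::rnorm(n * d, 0, sd_step), n, d)
    if (params$model == "directed")
      steps <- steps + matrix(params$v * params$dt, n, d, byrow = TRUE)
    if (params$model == "caged") {
      centre <- params$origin
      p <- centre
      for (i in seq_len(n)) {
        p <- reflect_in_sphere(p + steps[i, ], centre, params$R)
        true_pos[i + 1L, ] <- p
      }
    } else {
      true_pos <- true_pos +
        rbind(0, apply(steps, 2L, cumsum))
    }
  }
  noise <- if (params$sigma_loc > 0)
    matrix(stats::rnorm((n + 1L) * d, 0, params$sigma_loc), n + 1L, d)
  else 0
  tr <- trajectory(track_id, times = (0:n) * params$dt,
                   positions = true_pos + noise, cell_id = cell_id,
                   condition = condition, true_label = params$model)
  if (keep_true) attr(tr, "true_positions") <- true_pos
  tr
}

# Radial reflection at the boundary |p - centre| = R, iterated so that even
# a step larger than R ends inside the cage.
reflect_in_sphere <- function(p, centre, R) {
  r <- sqrt(sum((p - centre)^2))
  while (r > R) {
    p <- centre + (p - centre) * (2 * R - r) / r
    r <- abs(2 * R - r)
  }
  p
}

#' Simulate a fixed-cell track population
#'
#' Immobile granules in chemically fixed cells still show apparent motion
#' from finite localization accuracy. This helper simulates such tracks
#' (pure Gaussian noise around a fixed point) so that an immobility
#' threshold can be re-derived as a percentile of per-track maximum MSD,
#' mirroring the fixed-cell calibration used on real data.
#'
#' @param sigma_loc Per-axis localization noise s.d., um (> 0 for a
#'   meaningful calibration; 0 is allowed and gives all-zero MSD).
#' @param n_tracks Number of tracks (>= 1).
#' @param n_steps Steps per track (>= 2).
#' @param dt Frame interval, s.
#' @param seed Master seed; per-track seeds are derived by counter.
#' @param dim 2 or 3.
#'
#' @return List of [trajectory()] objects with `true_label = "immobile"`
#'   and `condition = "fixed"`.
#' @export
simulate_fixed_cell_population <- function(sigma_loc, n_tracks, n_steps = 50,
                                           dt = 1, seed = 1L, dim = 3) {
  if (n_tracks < 1) stop("n_tracks must be >= 1")
  if (n_steps < 2) stop("n_steps must be >= 2")
  lapply(seq_len(n_tracks), function(i) {
    p <- sim_params("immobile", dim = dim, sigma_loc = sigma_loc,
                    n_steps = n_steps, dt = dt,
                    seed = child_seed(seed, i))
    simulate_trajectory(p, track_id = sprintf("fixed%04d", i),
                        condition = "fixed")
  })
}

#' Simulate a labelled multi-regime cohort
#'
#' Generates trajectories from a specification table, one row per regime
#' block, carrying ground-truth labels alongside (in each trajectory's
#' `true_label` and in the returned label table) — the labels are never
#' consulted by the classifier.
#'
#' Seed handling: each row receives a seed (the optional `seed` column, or a
#' child seed of `seed` by row counter), and each track within a row a child
#' seed of the row seed. Rows therefore reproduce independently of their
#' order whenever their seed column is kept.
#'
#' @param spec `data.frame` with columns `model` and `count`, plus optional
#'   per-row overrides `dim`, `D`, `v` (speed along x), `R`, `sigma_loc`,
#'   `n_steps`, `dt`, `condition`, `seed`.
#' @param seed Master seed used to derive missing per-row seeds.
#'
#' @return List with `trajectories` (list of [trajectory()]) and `labels`
#'   (`data.frame` of `track_id`, `true_label`, `condition`).
#' @export
#' @examples
#' sp <- data.frame(model = c("immobile", "directed"), count = c(2, 2),
#'                  v = c(0, 0.15))
#' coh <- simulate_cohort(sp, seed = 42)
#' coh$labels
simulate_cohort <- function(spec, seed = 1L) {
  spec <- as.data.frame(spec)
  if (nrow(spec) == 0L) stop("empty cohort spec")
  if (!all(c("model", "count") %in% names(spec)))
    stop("cohort spec needs columns 'model' and 'count'")
  if (any(spec$count < 1)) stop("counts must be >= 1")
  getcol <- function(row, nm, default)
    if (nm %in% names(spec) && !is.na(spec[[nm]][row])) spec[[nm]][row]
    else default
  trajs <- list()
  labels <- list()
  k <- 0L
  for (r in seq_len(nrow(spec))) {
    row_seed <- as.integer(getcol(r, "seed", child_seed(seed, r)))
    model <- as.character(spec$model[r])
    cond <- as.character(getcol(r, "condition", model))
    for (j in seq_len(spec$count[r])) {
      k <- k + 1L
      p <- sim_params(
        model, dim = getcol(r, "dim", 3), D = getcol(r, "D", 0.01),
        v = c(getcol(r, "v", 0.1), 0, 0), R = getcol(r, "R", 0.5),
        sigma_loc = getcol(r, "sigma_loc", 0),
        n_steps = getcol(r, "n_steps", 50), dt = getcol(r, "dt", 1),
        seed = child_seed(row_seed, j))
      id <- sprintf("r%02d_%s_%04d", r, model, j)
      trajs[[k]] <- simulate_trajectory(p, track_id = id, condition = cond)
      labels[[k]] <- data.frame(track_id = id, true_label = model,
                                condition = cond, stringsAsFactors = FALSE)
    }
  }
  list(trajectories = trajs, labels = do.call(rbind, labels))
}
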