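#' Pipeline configuration
#'
#' Bundles the stage toggles and per-module settings for [run_pipeline()].
#' Stages run in the order of the tracking workflow: simulate (or load),
#' filter, msd, classify, metrics, report.
#'
#' @param out_dir Run directory (created if absent).
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "filter", "msd", "classify", "metrics", "report")`.
#' @param cohort_spec Cohort table for the simulate stage (see
#'   [simulate_cohort()]); `NULL` with `input` set loads trajectories
#'   instead.
#' @param input Optional path to an existing trajectory table.
#' @param min_steps Step filter for the filter stage.
#' @param membrane Optional membrane model function for the filter stage.
#' @param membrane_margin Membrane exclusion margin, um.
#' @param classify A [classification_config()].
#' @param metrics_window_s Optional metrics window, s.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "filter", "msd",
                                       "classify", "metrics", "report"),
                            cohort_spec = NULL, input = NULL,
                            min_steps = 6L, membrane = NULL,
                            membrane_margin = 0.2,
                            classify = classification_config(),
                            metrics_window_s = NULL) {
  known <- c("simulate", "filter", "msd", "classify", "metrics", "report")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if ("simulate" %in% stages && is.null(cohort_spec) && is.null(input))
    stop("simulate stage needs a cohort_spec")
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 cohort_spec = cohort_spec, input = input,
                 min_steps = min_steps, membrane = membrane,
                 membrane_margin = membrane_margin, classify = classify,
                 metrics_window_s = metrics_window_s),
            class = "pipeline_config")
}

# polynomial rolling hash of the deparsed configuration, for the provenance
# manifest (stays within exact double-precision integer range)
config_hash <- function(config) {
  # out_dir is run-local and membrane is a closure; neither identifies the
  # analysis settings
  s <- paste(deparse(config[setdiff(names(config),
                                    c("membrane", "out_dir"))]),
             collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stage_table <- function(tab, path) {
  utils::write.table(format_table(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in workflow order, writing one tab-delimited
#' table per stage into the run directory plus a provenance manifest
#' (`manifest.json`) recording the package version, master seed, stage list,
#' configuration hash and per-stage drop counts. Outputs are deterministic:
#' re-running with the same configuration reproduces byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "granmotion",
                   version = as.character(utils::packageVersion("granmotion")),
                   seed = config$seed, stages = config$stages,
                   config_hash = config_hash(config), drops = list(),
                   outputs = character())
  res <- list()
  trajs <- NULL
  labels <- NULL
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", config$out_dir, ")",
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      if (!is.null(config$cohort_spec)) {
        coh <- simulate_cohort(config$cohort_spec, seed = config$seed)
        trajs <- coh$trajectories
        labels <- coh$labels
      } else {
        trajs <- read_trajectories(config$input)
      }
      p <- file.path(config$out_dir, "trajectories.tsv")
      write_trajectories(trajs, p)
      manifest$outputs <- c(manifest$outputs, "trajectories.tsv")
    })
  } else if (!is.null(config$input)) {
    trajs <- read_trajectories(config$input)
  }

  if ("filter" %in% config$stages) {
    run_stage("filter", {
      before <- length(trajs)
      trajs <- filter_min_steps(trajs, config$min_steps)
      manifest$drops$min_steps <- before - length(trajs)
      if (!is.null(config$membrane)) {
        before <- length(trajs)
        trajs <- exclude_membrane_proximal(trajs, config$membrane,
                                            config$membrane_margin)
        manifest$drops$membrane_proximal <- before - length(trajs)
      }
      p <- file.path(config$out_dir, "trajectories_filtered.tsv")
      write_trajectories(trajs, p)
      manifest$outputs <- c(manifest$outputs, "trajectories_filtered.tsv")
    })
  }

  if ("msd" %in% config$stages) {
    run_stage("msd", {
      curves <- lapply(trajs, compute_msd,
                       max_lag_fraction = config$classify$max_lag_fraction)
      res$curves <- curves
      msd_tab <- do.call(rbind, lapply(curves, function(cu)
        data.frame(track_id = cu$track_id, lag_s = cu$lag_times,
                   msd_um2 = cu$msd, n_pairs = cu$n_pairs,
                   stringsAsFactors = FALSE)))
      write_stage_table(msd_tab, file.path(config$out_dir,
                                           "msd_curves.tsv"))
      fits <- lapply(curves, fit_msd_models)
      res$fits <- fits
      fit_tab <- do.call(rbind, lapply(fits, function(fs)
        do.call(rbind, lapply(fs, function(f)
          data.frame(model = f$model, D = f$D, v = f$v, R = f$R, k = f$k,
                     r2 = f$r_squared, stringsAsFactors = FALSE)))))
      fit_tab <- cbind(track_id = rep(vapply(curves, function(cu)
        cu$track_id, character(1)), each = 3L), fit_tab)
      write_stage_table(fit_tab, file.path(config$out_dir, "msd_fits.tsv"))
      manifest$outputs <- c(manifest$outputs, "msd_curves.tsv",
                             "msd_fits.tsv")
    })
  }

  if ("classify" %in% config$stages) {
    run_stage("classify", {
      cl <- classify_cohort(trajs, config$classify)
      res$classification <- cl
      write_stage_table(cl$table, file.path(config$out_dir, "labels.tsv"))
      write_stage_table(cl$fractions,
                        file.path(config$out_dir, "class_fractions.tsv"))
      manifest$outputs <- c(manifest$outputs, "labels.tsv",
                             "class_fractions.tsv")
    })
  }

  if ("metrics" %in% config$stages) {
    run_stage("metrics", {
      mt <- metrics_table(trajs, config$metrics_window_s)
      res$metrics <- mt
      write_stage_table(mt, file.path(config$out_dir, "metrics.tsv"))
      manifest$outputs <- c(manifest$outputs, "metrics.tsv")
    })
  }

  if ("report" %in% config$stages) {
    run_stage("report", {
      mt <- res$metrics
      if (is.null(mt)) mt <- metrics_table(trajs, config$metrics_window_s)
      lab_tab <- if (!is.null(res$classification)) res$classification$table
      else NULL
      conds <- unique(mt$condition)
      summaries <- lapply(conds, function(cd)
        summarize_condition(mt, lab_tab, cd, boot_seed = config$seed))
      res$summaries <- summaries
      sum_tab <- do.call(rbind, lapply(summaries, function(s)
        cbind(condition = s$condition, s$stats)))
      write_stage_table(sum_tab, file.path(config$out_dir, "summary.tsv"))
      manifest$outputs <- c(manifest$outputs, "summary.tsv")
      if (!is.null(lab_tab)) {
        fb <- fraction_bars(lab_tab)
        write_stage_table(fb, file.path(config$out_dir,
                                        "fraction_bars.tsv"))
        manifest$outputs <- c(manifest$outputs, "fraction_bars.tsv")
      }
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 results = res))
}
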