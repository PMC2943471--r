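#' Summarize one condition
#'
#' Computes, for each numeric metric column, the mean, median, standard
#' error of the mean (SEM = s/sqrt(n)), a seeded bootstrap standard error of
#' the median, a Freedman-Diaconis histogram and the empirical cumulative
#' distribution. Track-level motion-class fractions are included when a
#' label table is supplied. Exponential-like metrics (track lengths,
#' displacements) are conventionally reported as median with a dispersion
#' estimate; both the SEM and the bootstrap SE of the median are emitted so
#' either convention can be read off.
#'
#' @param metrics `data.frame` from [metrics_table()].
#' @param labels Optional `data.frame` with `track_id` and `label`
#'   (from [classify_cohort()]`$table`).
#' @param condition Condition label to summarize (default: all rows).
#' @param boot_n Bootstrap resamples for the median SE.
#' @param boot_seed Seed for the bootstrap.
#'
#' @return Object of class `"condition_summary"`: list with `condition`,
#'   `n`, `stats` (`data.frame`: metric, mean, median, sem,
#'   median_boot_se), `fractions`, `histograms`, `ecdfs` and the raw
#'   `samples` (named list of numeric vectors, used by
#'   [compare_conditions()]).
#' @export
summarize_condition <- function(metrics, labels = NULL, condition = NULL,
                                boot_n = 1000L, boot_seed = 1L) {
  if (!is.null(condition))
    metrics <- metrics[metrics$condition == condition, , drop = FALSE]
  n <- nrow(metrics)
  if (n == 0L) stop("no tracks for condition ", deparse(condition))
  metric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  metric_cols <- setdiff(metric_cols, "window_s")
  stats_rows <- list()
  hists <- list()
  ecdfs <- list()
  samples <- list()
  set.seed(boot_seed)
  for (mcol in metric_cols) {
    x <- metrics[[mcol]]
    sem <- if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    boot_se <- if (n > 1L) {
      meds <- vapply(seq_len(boot_n), function(i)
        stats::median(sample(x, n, replace = TRUE)), numeric(1))
      stats::sd(meds)
    } else NA_real_
    stats_rows[[mcol]] <- data.frame(
      metric = mcol, n = n, mean = mean(x), median = stats::median(x),
      sem = sem, median_boot_se = boot_se, stringsAsFactors = FALSE)
    brks <- fd_breaks(x)
    h <- graphics::hist(x, breaks = brks, plot = FALSE)
    hists[[mcol]] <- data.frame(bin_lo = h$breaks[-length(h$breaks)],
                                bin_hi = h$breaks[-1], count = h$counts)
    xs <- sort(x)
    ecdfs[[mcol]] <- data.frame(value = xs,
                                cum_prob = seq_len(n) / n)
    samples[[mcol]] <- x
  }
  fractions <- NULL
  if (!is.null(labels)) {
    lab <- labels[labels$track_id %in% metrics$track_id, , drop = FALSE]
    classes <- c("immobile", "random", "directed", "caged", "complex")
    counts <- table(factor(lab$label, levels = classes))
    fractions <- as.data.frame(counts / max(nrow(lab), 1L),
                               stringsAsFactors = FALSE)
    names(fractions) <- c("class", "fraction")
  }
  structure(list(condition = if (is.null(condition)) "all" else condition,
                 n = n, stats = do.call(rbind, stats_rows),
                 fractions = fractions, histograms = hists, ecdfs = ecdfs,
                 samples = samples),
            class = "condition_summary")
}

# Freedman-Diaconis breaks with graceful fallback for degenerate samples.
fd_breaks <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr <= 0 || length(x) < 2L) return(max(1L, ceiling(sqrt(length(x)))))
  h <- 2 * iqr / length(x)^(1 / 3)
  max(1L, ceiling(diff(range(x)) / h))
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary %s> n = %d tracks\n", x$condition, x$n))
  print(x$stats, row.names = FALSE)
  if (!is.null(x$fractions)) {
    cat("class fractions:\n")
    print(x$fractions, row.names = FALSE)
  }
  invisible(x)
}

#' Compare one metric between two conditions
#'
#' Two-sided two-sample test of a metric between two condition summaries:
#' Student's (pooled-variance) t-test for normal-looking data, or the
#' Kolmogorov-Smirnov test for exponential-like data. The KS statistic D is
#' the maximum gap between the two empirical cumulative distributions,
#' computed from the package's own ECDFs; the p-value comes from the
#' standard two-sample KS distribution.
#'
#' @param a,b [summarize_condition()] objects.
#' @param metric Metric name present in both summaries.
#' @param test `"t"` or `"ks"`.
#'
#' @return List: `test`, `metric`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(a, b, metric, test = c("t", "ks")) {
  test <- match.arg(test)
  stopifnot(inherits(a, "condition_summary"),
            inherits(b, "condition_summary"))
  if (!metric %in% names(a$samples) || !metric %in% names(b$samples))
    stop("metric ", metric, " not present in both summaries")
  xa <- a$samples[[metric]]
  xb <- b$samples[[metric]]
  if (test == "t") {
    if (length(xa) < 2L || length(xb) < 2L)
      stop("t-test needs >= 2 observations per side")
    ht <- stats::t.test(xa, xb, var.equal = TRUE)
    out <- list(test = "t", statistic = unname(ht$statistic),
                p_value = ht$p.value)
  } else {
    D <- ks_statistic(xa, xb)
    p <- suppressWarnings(stats::ks.test(xa, xb)$p.value)
    out <- list(test = "ks", statistic = D, p_value = p)
  }
  c(out, list(metric = metric, n_a = length(xa), n_b = length(xb)))
}

# Max absolute gap between two empirical CDFs, evaluated at all data points.
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(Fx - Fy))
}

#' Motion-class fractions per condition
#'
#' Tabulates the relative occurrence of each motion class per condition,
#' with the number of tracking events n — the bar-plot summary form.
#'
#' @param labels_tables Named list of label `data.frame`s (columns
#'   `track_id`, `label`), one per condition; or a single `data.frame` with
#'   a `condition` column.
#' @return `data.frame`: `condition`, one column per class, `n`.
#' @export
fraction_bars <- function(labels_tables) {
  classes <- c("immobile", "random", "directed", "caged", "complex")
  if (is.data.frame(labels_tables))
    labels_tables <- split(labels_tables, labels_tables$condition)
  if (!length(labels_tables)) stop("no label tables supplied")
  rows <- lapply(names(labels_tables), function(cond) {
    d <- labels_tables[[cond]]
    if (!nrow(d)) stop("empty label table for condition ", cond)
    counts <- table(factor(d$label, levels = classes))
    cbind(data.frame(condition = cond, stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts / nrow(d)))),
          data.frame(n = nrow(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
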