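#' Write trajectories to a tab-delimited table
#'
#' One row per point, UTF-8, tab-delimited, with a mandatory header:
#' `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `z_um` (blank for 2D tracks),
#' `cell_id`, `condition`, `true_label`. Units are fixed in the column names
#' to prevent silent unit errors between 100 ms TIRF and 1 s confocal data.
#'
#' @param trajectories List of [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    n <- length(tr$times)
    dtbase <- min(diff(tr$times))
    data.frame(track_id = tr$track_id,
               frame = as.integer(round((tr$times - tr$times[1]) / dtbase)),
               t_s = tr$times,
               x_um = tr$positions[, 1],
               y_um = tr$positions[, 2],
               z_um = if (tr$dim == 3L) tr$positions[, 3] else NA_real_,
               cell_id = tr$cell_id,
               condition = tr$condition,
               true_label = tr$true_label,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = character(), frame = integer(), t_s = numeric(),
               x_um = numeric(), y_um = numeric(), z_um = numeric(),
               cell_id = character(), condition = character(),
               true_label = character())
  utils::write.table(format_table(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# full-precision, locale-independent number formatting for deterministic
# byte-identical outputs
format_table <- function(tab) {
  for (nm in names(tab)) {
    if (is.double(tab[[nm]])) {
      v <- sprintf("%.15g", tab[[nm]])
      v[is.na(tab[[nm]])] <- NA_character_
      tab[[nm]] <- v
    }
  }
  tab
}

#' Read trajectories from a tab-delimited table
#'
#' Inverse of [write_trajectories()]. Rows are sorted by
#' `(track_id, frame)`, so shuffled files load identically. A track must be
#' entirely 2D (blank `z_um`) or entirely 3D; mixtures are rejected, as are
#' non-monotone times within a track.
#'
#' @param path Input file path.
#' @return List of [trajectory()].
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "", fileEncoding = "UTF-8")
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"z_um" %in% names(tab)) tab$z_um <- NA_real_
  if (!"cell_id" %in% names(tab)) tab$cell_id <- NA_character_
  if (!"condition" %in% names(tab)) tab$condition <- NA_character_
  if (!"true_label" %in% names(tab)) tab$true_label <- NA_character_
  tab <- tab[order(tab$track_id, tab$frame), , drop = FALSE]
  lapply(split(tab, tab$track_id), function(d) {
    zna <- is.na(d$z_um)
    if (any(zna) && !all(zna))
      stop("track ", d$track_id[1], " mixes 2D and 3D rows")
    if (any(diff(d$t_s) <= 0))
      stop("non-monotone times in track ", d$track_id[1])
    pos <- if (all(zna)) cbind(d$x_um, d$y_um)
    else cbind(d$x_um, d$y_um, d$z_um)
    trajectory(d$track_id[1], times = d$t_s, positions = pos,
               cell_id = d$cell_id[1], condition = d$condition[1],
               true_label = d$true_label[1])
  })
}

#' Read a plain-text key/value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers where possible, otherwise kept as strings.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
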