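#' Read a marker trajectory from a tabular text file
#'
#' Reads a CSV with a `time` (seconds) or `frame` column plus three
#' displacement columns (named `x`, `y`, `z` in any case, or the first three
#' non-time numeric columns otherwise), converts the declared units to
#' metres, and validates the stream: time must be monotonic and consistent
#' with the declared rate, and marker dropouts (missing coordinates) inside
#' the record are an error that names the offending frames — analysis assumes
#' dropout-free spans.
#'
#' @param path CSV file path.
#' @param rate sampling rate in frames per second; when a `time` column is
#'   present it is checked against it.
#' @param units one of "m", "mm", "cm".
#' @param vertical_axis which displacement column (1-3) is vertical.
#' @param trial_id,foot_id labels; default to the file name.
#' @return A [trajectory3d()].
#' @export
read_trajectory_table <- function(path, rate, units = c("m", "mm", "cm"),
                                  vertical_axis = 2L,
                                  trial_id = basename(path),
                                  foot_id = NA_character_) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  tcol <- which(nm %in% c("time", "frame"))[1L]
  axis_cols <- which(nm %in% c("x", "y", "z"))
  if (length(axis_cols) == 3L) {
    axis_cols <- axis_cols[order(match(nm[axis_cols], c("x", "y", "z")))]
  } else {
    axis_cols <- setdiff(which(vapply(df, is.numeric, logical(1))),
                         tcol)[1:3]
  }
  if (anyNA(axis_cols) || length(axis_cols) < 3L)
    stop("need three displacement columns (x, y, z)", call. = FALSE)
  if (!is.na(tcol) && nm[tcol] == "time") {
    tt <- df[[tcol]]
    if (is.unsorted(tt, strictly = TRUE))
      stop("`time` column is not strictly increasing", call. = FALSE)
    dt <- stats::median(diff(tt))
    if (abs(dt * rate - 1) > 0.01)
      stop(sprintf("declared rate %g Hz disagrees with time column (%.4g s steps)",
                   rate, dt), call. = FALSE)
  }
  coords <- as.matrix(df[, axis_cols])
  bad <- which(rowSums(is.na(coords) | !is.finite(coords)) > 0L)
  if (length(bad))
    stop("marker dropout (missing coordinates) at frame(s) ",
         paste(utils::head(bad - 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  scale <- c(m = 1, mm = 1e-3, cm = 1e-2)[[units]]
  trajectory3d(coords * scale, rate = rate, vertical_axis = vertical_axis,
               trial_id = trial_id, foot_id = foot_id)
}

#' Write a trajectory to CSV
#'
#' @param traj a [trajectory3d()].
#' @param path output file.
#' @param units output units ("m", "mm" or "cm").
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path, units = c("m", "mm", "cm")) {
  units <- match.arg(units)
  scale <- c(m = 1, mm = 1e3, cm = 1e2)[[units]]
  n <- n_frames(traj)
  df <- data.frame(time = (seq_len(n) - 1L) / traj$rate,
                   x = traj$coords[, 1L] * scale,
                   y = traj$coords[, 2L] * scale,
                   z = traj$coords[, 3L] * scale)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a force series from a tabular text file
#'
#' Reads a CSV with an `fz` column (and optional `fx`, `fy`; a single-column
#' file is taken as `fz`). Calibrated files are ingested as newtons. Raw
#' analog acquisitions can be calibrated on ingest by supplying per-channel
#' `offset` and `scale`: each channel becomes `(raw - offset) * scale`, with
#' `gravity_n` then added to the vertical channel (the convention for plates
#' whose calibration removes the supported weight).
#'
#' @param path CSV file path.
#' @param rate sampling rate in samples per second.
#' @param offset,scale optional named numeric vectors (names among
#'   `fx`, `fy`, `fz`) applied as `(raw - offset) * scale`.
#' @param gravity_n constant added to `fz` after scaling.
#' @return A [force_series()] with `baseline_corrected = FALSE`.
#' @export
read_force_table <- function(path, rate, offset = NULL, scale = NULL,
                             gravity_n = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  get_chan <- function(chan) {
    i <- which(nm == chan)
    if (length(i) == 0L) return(NULL)
    v <- as.numeric(df[[i]])
    if (!is.null(offset) && chan %in% names(offset)) v <- v - offset[[chan]]
    if (!is.null(scale) && chan %in% names(scale)) v <- v * scale[[chan]]
    v
  }
  fz <- get_chan("fz")
  if (is.null(fz)) {
    num <- which(vapply(df, is.numeric, logical(1)) &
                   !nm %in% c("time", "frame"))
    if (ncol(df) == 1L || length(num) == 1L) {
      fz <- as.numeric(df[[num[1L]]])
      if (!is.null(offset) && "fz" %in% names(offset)) fz <- fz - offset[["fz"]]
      if (!is.null(scale) && "fz" %in% names(scale)) fz <- fz * scale[["fz"]]
    } else stop("no vertical force channel (`fz`) found", call. = FALSE)
  }
  fz <- fz + gravity_n
  force_series(fz, fx = get_chan("fx"), fy = get_chan("fy"), rate = rate)
}

#' Write a force series to CSV
#'
#' @param force a [force_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_force_table <- function(force, path) {
  df <- data.frame(time = (seq_along(force$fz) - 1L) / force$rate,
                   fz = force$fz)
  if (!is.null(force$fx)) df$fx <- force$fx
  if (!is.null(force$fy)) df$fy <- force$fy
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an event or difference table to CSV
#'
#' Serialises an event table ([segment_trial()], [detect_kinetic_events()] or
#' a truth table) or a method-difference table to a tidy CSV. Frames are
#' 0-based, times in seconds; quality flags are written verbatim. An empty
#' table yields a header-only file.
#'
#' @param events a data frame of events or differences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path CSV file path.
#' @return A data frame; `frame` (if present) is integer and 0-based.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("frame" %in% names(df)) df$frame <- as.integer(df$frame)
  for (col in c("trial_id", "foot_id", "kind", "method", "quality_flag"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df
}

#' Read a YAML configuration file
#'
#' Configuration keys mirror the arguments of [condition_profile()] and
#' [kinetic_config()] plus the detector tuning knobs of [segment_trial()]
#' (`presegment_v`, `smooth_window`, `plateau_v`, `sustain`,
#' `refine_radius`).
#'
#' @param path YAML file path.
#' @return A named list (empty when `path` is `NULL`).
#' @export
read_config <- function(path) {
  if (is.null(path)) return(list())
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping",
                          call. = FALSE)
  cfg
}
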