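#' 3D marker trajectory for one foot
#'
#' Container for the sampled 3D displacement of a single hoof-wall marker.
#' Coordinates are stored in metres in a global (lab) frame; one of the three
#' axes is tagged as vertical (by default the second axis, i.e. the `y`-up
#' convention with the horizontal plane spanned by axes 1 and 3; labs with a
#' `z`-up convention pass `vertical_axis = 3`). Frames are 0-based throughout
#' the package: frame `f` is sample `f + 1` of the coordinate matrix and
#' corresponds to time `f / rate` seconds.
#'
#' @param axis1,axis2,axis3 displacement components in metres, equal length
#'   (>= 2). Alternatively `axis1` may be an `n x 3` numeric matrix.
#' @param rate sampling rate in frames per second.
#' @param vertical_axis which axis (1, 2 or 3) is vertical.
#' @param trial_id,foot_id optional labels carried into event tables.
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(axis1, axis2 = NULL, axis3 = NULL, rate,
                         vertical_axis = 2L, trial_id = NA_character_,
                         foot_id = NA_character_) {
  if (is.matrix(axis1)) {
    if (ncol(axis1) != 3L) stop("coordinate matrix must have 3 columns",
                                call. = FALSE)
    coords <- axis1
  } else {
    if (is.null(axis2) || is.null(axis3))
      stop("supply three axis vectors or one n x 3 matrix", call. = FALSE)
    if (length(axis1) != length(axis2) || length(axis1) != length(axis3))
      stop("the three displacement components must have equal length",
           call. = FALSE)
    coords <- cbind(axis1, axis2, axis3)
  }
  storage.mode(coords) <- "double"
  if (nrow(coords) < 2L) stop("a trajectory needs at least 2 frames",
                              call. = FALSE)
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("trajectory coordinates must be finite (reject or repair marker ",
         "dropouts before constructing)", call. = FALSE)
  vertical_axis <- as.integer(vertical_axis)
  if (!vertical_axis %in% 1:3)
    stop("`vertical_axis` must be 1, 2 or 3", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be positive",
                                          call. = FALSE)
  colnames(coords) <- c("axis1", "axis2", "axis3")
  structure(
    list(coords = coords, rate = as.numeric(rate),
         vertical_axis = vertical_axis,
         trial_id = trial_id, foot_id = foot_id),
    class = "trajectory3d"
  )
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf(
    "<trajectory3d> %s/%s: %d frames @ %g Hz (%.2f s), vertical axis %d\n",
    x$trial_id, x$foot_id, nrow(x$coords), x$rate,
    (nrow(x$coords) - 1) / x$rate, x$vertical_axis))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory3d()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' Vertical displacement component of a trajectory
#' @param traj a [trajectory3d()].
#' @return A [sampled_series()] of the vertical coordinate in metres.
#' @export
vertical_displacement <- function(traj) {
  sampled_series(traj$coords[, traj$vertical_axis], traj$rate, units = "m")
}

# Indices of the two horizontal (non-vertical) axes.
horizontal_axes <- function(traj) setdiff(1:3, traj$vertical_axis)

#' Resultant marker speed
#'
#' Differentiates each displacement component by forward differences and takes
#' the per-sample Euclidean norm; optionally smooths the result with a centred
#' moving average (see [moving_average()]).
#'
#' @param traj a [trajectory3d()].
#' @param smooth_window optional moving-average width in frames; `NULL` keeps
#'   the raw resultant speed.
#' @return A [sampled_series()] of speed in m/s, one sample shorter than the
#'   trajectory, with `origin = 0`.
#' @export
resultant_speed <- function(traj, smooth_window = NULL) {
  vel <- lapply(1:3, function(k)
    diff(traj$coords[, k]) * traj$rate)
  v <- sampled_series(sqrt(vel[[1L]]^2 + vel[[2L]]^2 + vel[[3L]]^2),
                      traj$rate, units = "m/s")
  if (!is.null(smooth_window)) v <- moving_average(v, smooth_window)
  v
}
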