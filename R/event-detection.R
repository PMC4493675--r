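#' Per-stride search window
#'
#' A stride window anchors the event searches for one stride: it starts at the
#' pre-segmentation frame (the downward crossing of the smoothed resultant
#' speed), the foot-on search extends 0.2 s beyond it, and the foot-off search
#' spans 0.15 s from the detected start of breakover. Windows are specified in
#' seconds and converted to frames by rounding, so the canonical 20- and
#' 15-frame windows arise at 100 Hz but other rates work too.
#'
#' @param start 0-based frame at which the stride search begins.
#' @param rate sampling rate in frames per second.
#' @param foot_on_search_s foot-on search span after `start`, in seconds.
#' @param liftoff_search_s foot-off search span after breakover start, in
#'   seconds.
#' @return A list of class `stride_window` with elements `start`,
#'   `foot_on_search_end` and `liftoff_len` (all in frames).
#' @export
stride_window <- function(start, rate, foot_on_search_s = 0.2,
                          liftoff_search_s = 0.15) {
  start <- as.integer(start)
  if (start < 0L) stop("`start` must be >= 0", call. = FALSE)
  w <- list(start = start,
            foot_on_search_end = start + as.integer(round(foot_on_search_s * rate)),
            liftoff_len = max(1L, as.integer(round(liftoff_search_s * rate))))
  class(w) <- "stride_window"
  w
}

# One event row. Frames are 0-based; time = frame / rate.
footfall_event <- function(kind, frame, rate, method,
                           quality_flag = "ok", stride = NA_integer_) {
  frame <- as.integer(frame)
  data.frame(stride = as.integer(stride), kind = kind,
             frame = frame,
             time = ifelse(is.na(frame), NA_real_, frame / rate),
             method = method, quality_flag = quality_flag,
             stringsAsFactors = FALSE)
}

# Header-only event table (used when nothing is detected).
empty_events <- function() {
  data.frame(stride = integer(0), kind = character(0), frame = integer(0),
             time = numeric(0), method = character(0),
             quality_flag = character(0), stringsAsFactors = FALSE)
}

#' Pre-segment a trial into candidate strides
#'
#' Finds the frames at which the width-`window` moving average of the
#' resultant marker speed drops below `v_cut` (previous sample `>= v_cut`,
#' current sample `< v_cut`). Each downward crossing anchors one stride
#' window. An empty list is returned when the smoothed speed never crosses.
#'
#' @param traj a [trajectory3d()].
#' @param v_cut pre-segmentation speed threshold in m/s.
#' @param window moving-average width in frames.
#' @return A list of [stride_window()] objects, ordered and non-overlapping,
#'   with attribute `starts_below` marking a trial that begins mid-stance
#'   (smoothed speed already below `v_cut` at frame 0).
#' @export
presegment_strides <- function(traj, v_cut = 2.5, window = 10L) {
  sm <- moving_average(resultant_speed(traj), window)$values
  n <- length(sm)
  cross <- which(sm[-1L] < v_cut & sm[-n] >= v_cut) # index into sm[-1]
  frames <- cross # sm index (cross + 1) is frame (cross + 1) - 1 = cross
  wins <- lapply(frames, stride_window, rate = traj$rate)
  attr(wins, "starts_below") <- sm[1L] < v_cut
  wins
}

#' Foot-on detection by resultant-velocity threshold (method A)
#'
#' Scans the *raw* (unfiltered) resultant marker speed over
#' `[start, foot_on_search_end]` and returns the first frame strictly below
#' the condition's velocity threshold. If no sample falls below the threshold
#' the event is reported at the window end with `quality_flag =
#' "window_exhausted"` rather than dropped, mirroring per-stride bookkeeping.
#'
#' @param traj a [trajectory3d()].
#' @param win a [stride_window()].
#' @param profile a [condition_profile()] supplying `v_threshold`.
#' @return A one-row event data frame (`kind`, `frame`, `time`, `method`,
#'   `quality_flag`).
#' @export
detect_foot_on_threshold <- function(traj, win, profile) {
  v <- resultant_speed(traj)$values
  last <- length(v) - 1L # last available velocity frame (0-based)
  i0 <- win$start
  i1 <- min(win$foot_on_search_end, last)
  if (i0 > last) stop("stride window lies outside the trajectory",
                      call. = FALSE)
  seg <- v[(i0 + 1L):(i1 + 1L)]
  hit <- which(seg < profile$v_threshold)
  if (length(hit) == 0L)
    footfall_event("foot_on", i1, traj$rate, "A", "window_exhausted")
  else
    footfall_event("foot_on", i0 + hit[1L] - 1L, traj$rate, "A")
}

#' Locate the start of breakover after a foot-on event
#'
#' Breakover begins where the plateau of near-zero smoothed resultant speed
#' that characterises stance ends. The plateau end is the last frame with
#' smoothed speed below `plateau_v` that is followed by at least `sustain`
#' consecutive frames above it; the sustain requirement skips isolated noise
#' blips inside stance. The default ceiling of 0.35 m/s clears the stance
#' noise floor of the smoothed resultant speed: with 0.8 mm marker noise at
#' 100 Hz the *magnitude* of the velocity noise averages to about 0.18 m/s
#' (magnitudes do not cancel under smoothing), so the ceiling sits roughly
#' six smoothed-floor SDs above that while remaining below the 0.5 m/s
#' foot-on threshold. Both `plateau_v` and `sustain` are exposed for tuning.
#'
#' @param traj a [trajectory3d()].
#' @param foot_on 0-based foot-on frame from which to scan.
#' @param plateau_v stance-plateau speed ceiling in m/s.
#' @param sustain number of consecutive supra-threshold frames ending the
#'   plateau.
#' @param window moving-average width used to smooth the resultant speed.
#' @return The 0-based frame of the last plateau sample (breakover start).
#' @export
detect_breakover_start <- function(traj, foot_on, plateau_v = 0.35,
                                   sustain = 3L, window = 10L) {
  sm <- moving_average(resultant_speed(traj), window)$values
  n <- length(sm)
  i0 <- as.integer(foot_on) + 1L # 1-based index of foot-on frame
  if (i0 < 1L || i0 > n) stop("`foot_on` lies outside the trajectory",
                              call. = FALSE)
  in_plateau <- sm < plateau_v
  if (!any(in_plateau[i0:n]))
    stop("no stance plateau: smoothed speed never falls below `plateau_v` ",
         "after foot-on", call. = FALSE)
  for (i in i0:(n - 1L)) {
    if (!in_plateau[i]) next
    j1 <- i + 1L
    j2 <- min(n, i + sustain)
    if ((j2 - i) >= sustain && all(sm[j1:j2] > plateau_v))
      return(i - 1L)
  }
  stop("no breakover: the stance plateau is never followed by a sustained ",
       "speed rise", call. = FALSE)
}

#' Foot-off detection by trigonometric distance threshold (method B)
#'
#' During breakover the hoof rotates about its toe, so horizontal marker
#' translation is bounded by the rigid-body geometry: once the marker has
#' travelled horizontally further than its own height above the ground during
#' stance, the movement can no longer be attributed to rotation and the foot
#' must have lifted. The detector computes, for each frame in the 0.15 s
#' window after breakover start, the horizontal Euclidean distance between the
#' marker and its stance reference position, and returns the *last* frame at
#' which this distance is below the stance hoof-marker height.
#'
#' @param traj a [trajectory3d()].
#' @param foot_state list with `p_ref` (3D marker position at foot-on, or at
#'   end of stance for trials starting mid-stance) and `hoof_height` (vertical
#'   marker coordinate at the same frame, > 0), e.g. from [foot_state_at()].
#' @param breakover_start 0-based frame of breakover start.
#' @param win a [stride_window()] supplying `liftoff_len`.
#' @return A one-row event data frame; `quality_flag = "window_exhausted"`
#'   when the distance already exceeds the height at breakover start (event at
#'   that frame) or never reaches it inside the window (event at the last
#'   window frame).
#' @export
detect_foot_off_trig <- function(traj, foot_state, breakover_start, win) {
  h <- foot_state$hoof_height
  if (!is.finite(h) || h <= 0) stop("`hoof_height` must be positive",
                                    call. = FALSE)
  n <- n_frames(traj)
  bs <- as.integer(breakover_start)
  if (bs < 0L || bs > n - 1L)
    stop("`breakover_start` lies outside the trajectory", call. = FALSE)
  end <- min(bs + win$liftoff_len, n - 1L)
  ha <- horizontal_axes(traj)
  seg <- traj$coords[(bs + 1L):(end + 1L), , drop = FALSE]
  d <- sqrt((seg[, ha[1L]] - foot_state$p_ref[ha[1L]])^2 +
            (seg[, ha[2L]] - foot_state$p_ref[ha[2L]])^2)
  below <- d < h
  if (!below[1L])
    footfall_event("foot_off", bs, traj$rate, "B", "window_exhausted")
  else if (all(below))
    footfall_event("foot_off", end, traj$rate, "B", "window_exhausted")
  else
    footfall_event("foot_off", bs + max(which(below)) - 1L, traj$rate, "B")
}

#' Extract the stance reference state for the trigonometric detector
#'
#' @param traj a [trajectory3d()].
#' @param frame 0-based frame at which to read the marker position (the
#'   foot-on frame, or the end-of-stance frame for trials starting mid-stance).
#' @return A list with `p_ref` (3D position) and `hoof_height` (vertical
#'   coordinate at `frame`).
#' @export
foot_state_at <- function(traj, frame) {
  p <- traj$coords[as.integer(frame) + 1L, ]
  list(p_ref = p, hoof_height = unname(p[traj$vertical_axis]))
}

#' Foot-on detection by filtered acceleration peak (method C)
#'
#' Double-differentiates the marker displacement and locates the impact as the
#' maximum of the zero-lag low-pass-filtered acceleration inside
#' `[start, foot_on_search_end]`. The acceleration component and cut-off come
#' from the condition profile: vertical acceleration at 25 Hz (trot) / 20 Hz
#' (walk) by default, resultant acceleration at 15 Hz for the hind limbs on
#' the circle at trot, where vertical impact peaks are unreliable.
#'
#' @param traj a [trajectory3d()].
#' @param win a [stride_window()].
#' @param profile a [condition_profile()].
#' @return A one-row event data frame with `method = "C"`.
#' @export
detect_foot_on_accel <- function(traj, win, profile) {
  acc <- if (profile$accel_component == "vertical") {
    differentiate(differentiate(vertical_displacement(traj)))
  } else {
    a <- lapply(1:3, function(k)
      diff(diff(traj$coords[, k])) * traj$rate^2)
    sampled_series(sqrt(a[[1L]]^2 + a[[2L]]^2 + a[[3L]]^2), traj$rate)
  }
  filt <- lowpass_zero_lag(acc, profile$accel_cutoff_hz)$values
  last <- length(filt) - 1L
  i0 <- win$start
  i1 <- min(win$foot_on_search_end, last)
  if (i0 > i1)
    stop("stride window lies outside the differentiated signal",
         call. = FALSE)
  seg <- filt[(i0 + 1L):(i1 + 1L)]
  footfall_event("foot_on", i0 + which.max(seg) - 1L, traj$rate, "C")
}

#' Foot-off detection by vertical-velocity minimum (method D)
#'
#' Differentiates the vertical displacement, low-pass filters the vertical
#' velocity (zero-lag, 15 Hz default from the profile) and finds the first
#' local minimum after breakover start; the final event is then refined to the
#' minimum of the *raw* vertical velocity within `refine_radius` frames of the
#' preliminary minimum. The event sought is the point at which the vertical
#' velocity changes direction from downwards to upwards as the foot is lifted,
#' so the preliminary minimum must have a *negative* (downward) filtered
#' value; shallow dips while the marker is still rising during breakover are
#' not candidate events. The default radius of 3 frames is roughly half the
#' main lobe of the 15 Hz filter at 100 Hz. When no local minimum exists
#' before the trial end, the event is reported at the global minimum of the
#' searched span with `quality_flag = "no_local_minimum"`.
#'
#' @param traj a [trajectory3d()].
#' @param breakover_start 0-based frame of breakover start.
#' @param profile a [condition_profile()] supplying `vvel_cutoff_hz`.
#' @param refine_radius half-width in frames of the raw-signal refinement.
#' @return A one-row event data frame with `method = "D"`.
#' @export
detect_foot_off_velmin <- function(traj, breakover_start, profile,
                                   refine_radius = 3L) {
  vv <- differentiate(vertical_displacement(traj))
  raw <- vv$values
  filt <- lowpass_zero_lag(vv, profile$vvel_cutoff_hz)$values
  n <- length(filt)
  bs <- as.integer(breakover_start)
  if (bs < 0L || bs > n - 1L)
    stop("`breakover_start` lies outside the velocity signal", call. = FALSE)
  prelim <- NA_integer_
  i_from <- max(bs + 2L, 2L) # first candidate needs a left neighbour
  if (i_from <= n - 1L) {
    for (i in i_from:(n - 1L)) {
      if (filt[i] < 0 && filt[i] <= filt[i - 1L] && filt[i] < filt[i + 1L]) {
        prelim <- i - 1L # 0-based frame
        break
      }
    }
  }
  flag <- "ok"
  if (is.na(prelim)) {
    span <- (bs + 2L):n
    prelim <- span[which.min(filt[span])] - 1L
    flag <- "no_local_minimum"
  }
  lo <- max(prelim - refine_radius, 0L)
  hi <- min(prelim + refine_radius, n - 1L)
  idx <- (lo + 1L):(hi + 1L)
  frame <- lo + which.min(raw[idx]) - 1L
  footfall_event("foot_off", frame, traj$rate, "D", flag)
}

#' Segment a full trial into footfall events
#'
#' Orchestrates the whole kinematic pipeline for one trial: pre-segmentation,
#' the chosen foot-on detector (method "A", velocity threshold, or "C",
#' acceleration peak), breakover-start detection, and the chosen foot-off
#' detector (method "B", trigonometric distance, or "D", vertical-velocity
#' minimum). A trial that begins mid-stance (no initial contact in the record)
#' yields a leading stride with a foot-off event only, its hoof height taken
#' at the detected end of stance. Per-stride detection failures are propagated
#' as events flagged `"detection_failed"`; the trial is never aborted.
#'
#' @param traj a [trajectory3d()].
#' @param profile a [condition_profile()].
#' @param method_on "A" or "C".
#' @param method_off "B" or "D".
#' @param presegment_v pre-segmentation speed threshold in m/s.
#' @param smooth_window moving-average width for pre-segmentation and
#'   breakover detection.
#' @param plateau_v,sustain breakover-start parameters, see
#'   [detect_breakover_start()].
#' @param refine_radius method-D refinement radius in frames.
#' @return An `event_set`: a data frame with columns `trial_id`, `foot_id`,
#'   `stride`, `kind`, `frame` (0-based), `time` (s), `method`,
#'   `quality_flag`, sorted by frame, with the profile attached as attribute
#'   `profile`.
#' @export
segment_trial <- function(traj, profile, method_on = c("A", "C"),
                          method_off = c("B", "D"), presegment_v = 2.5,
                          smooth_window = 10L, plateau_v = 0.35, sustain = 3L,
                          refine_radius = 3L) {
  method_on <- match.arg(method_on)
  method_off <- match.arg(method_off)
  wins <- presegment_strides(traj, presegment_v, smooth_window)
  rows <- list()
  stride_no <- 0L

  run_off <- function(bs, state, win) {
    if (method_off == "B") detect_foot_off_trig(traj, state, bs, win)
    else detect_foot_off_velmin(traj, bs, profile, refine_radius)
  }

  if (isTRUE(attr(wins, "starts_below")) &&
      (length(wins) == 0L || wins[[1L]]$start > 0L)) {
    # trial starts mid-stance: leading stride has a foot-off only
    stride_no <- stride_no + 1L
    win0 <- stride_window(0L, traj$rate)
    ev <- tryCatch({
      bs <- detect_breakover_start(traj, 0L, plateau_v, sustain,
                                   smooth_window)
      run_off(bs, foot_state_at(traj, bs), win0)
    }, error = function(e)
      footfall_event("foot_off", NA_integer_, traj$rate, method_off,
                     "detection_failed"))
    ev$stride <- stride_no
    rows[[length(rows) + 1L]] <- ev
  }

  for (win in wins) {
    stride_no <- stride_no + 1L
    on_ev <- tryCatch({
      if (method_on == "A") detect_foot_on_threshold(traj, win, profile)
      else detect_foot_on_accel(traj, win, profile)
    }, error = function(e)
      footfall_event("foot_on", NA_integer_, traj$rate, method_on,
                     "detection_failed"))
    on_ev$stride <- stride_no
    rows[[length(rows) + 1L]] <- on_ev

    off_ev <- tryCatch({
      if (is.na(on_ev$frame)) stop("no foot-on anchor")
      bs <- detect_breakover_start(traj, on_ev$frame, plateau_v, sustain,
                                   smooth_window)
      ev <- run_off(bs, foot_state_at(traj, on_ev$frame), win)
      if (!is.na(ev$frame) && ev$frame <= on_ev$frame)
        ev$quality_flag <- "detection_failed" # violates foot_on < foot_off
      ev
    }, error = function(e)
      footfall_event("foot_off", NA_integer_, traj$rate, method_off,
                     "detection_failed"))
    off_ev$stride <- stride_no
    rows[[length(rows) + 1L]] <- off_ev
  }

  ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  ev <- cbind(trial_id = rep(traj$trial_id, nrow(ev)),
              foot_id = rep(traj$foot_id, nrow(ev)), ev,
              stringsAsFactors = FALSE)
  ev <- ev[order(is.na(ev$frame), ev$frame), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "profile") <- profile
  class(ev) <- c("event_set", "data.frame")
  ev
}
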