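#' Force-plate signal container
#'
#' Holds sampled ground-reaction-force components in newtons. Only the
#' vertical component `fz` is required; it alone defines the kinetic footfall
#' events (resultant force would raise the noise floor). Frames are 0-based as
#' everywhere in the package.
#'
#' @param fz vertical force (N).
#' @param fx,fy optional horizontal components (N), equal length to `fz`.
#' @param rate sampling rate in samples per second.
#' @param baseline_corrected has the sensor offset been removed yet?
#' @return An object of class `force_series`.
#' @export
force_series <- function(fz, fx = NULL, fy = NULL, rate,
                         baseline_corrected = FALSE) {
  fz <- as.numeric(fz)
  if (anyNA(fz) || any(!is.finite(fz)))
    stop("`fz` must be finite", call. = FALSE)
  for (comp in list(fx, fy))
    if (!is.null(comp) && length(comp) != length(fz))
      stop("force components must have equal length", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be positive",
                                          call. = FALSE)
  structure(
    list(fz = fz, fx = if (is.null(fx)) NULL else as.numeric(fx),
         fy = if (is.null(fy)) NULL else as.numeric(fy),
         rate = as.numeric(rate),
         baseline_corrected = isTRUE(baseline_corrected)),
    class = "force_series"
  )
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf(
    "<force_series> %d samples @ %g Hz (%.2f s), %s, baseline %scorrected\n",
    length(x$fz), x$rate, length(x$fz) / x$rate,
    if (is.null(x$fx)) "fz only" else "fz+fx+fy",
    if (x$baseline_corrected) "" else "NOT "))
  invisible(x)
}

#' Kinetic processing configuration
#'
#' @param threshold_n vertical-force event threshold in newtons. The 75 N
#'   default sits above typical plate noise plateaus (around 50 N) while the
#'   steep force rise at hoof impact keeps the induced timing bias small.
#' @param baseline_window_s length of the unloaded window used for offset
#'   correction (0.2 s, i.e. 200 frames at 1,000 Hz).
#' @param target_rate rate to decimate to before event detection (100 Hz,
#'   matching the kinematic stream).
#' @param loading_guard_n a candidate baseline window is rejected as "loaded"
#'   when its mean absolute vertical force exceeds this guard (default 25 N,
#'   below the smallest threshold of the sensitivity sweep).
#' @param min_contact_gap_s contacts separated by less than this span of
#'   sub-threshold force are merged, guarding against threshold chatter.
#' @return An object of class `kinetic_config`.
#' @export
kinetic_config <- function(threshold_n = 75, baseline_window_s = 0.2,
                           target_rate = 100, loading_guard_n = 25,
                           min_contact_gap_s = 0.1) {
  if (threshold_n <= 0 || baseline_window_s <= 0 || target_rate <= 0)
    stop("`threshold_n`, `baseline_window_s` and `target_rate` must be ",
         "positive", call. = FALSE)
  structure(list(threshold_n = threshold_n,
                 baseline_window_s = baseline_window_s,
                 target_rate = target_rate,
                 loading_guard_n = loading_guard_n,
                 min_contact_gap_s = min_contact_gap_s),
            class = "kinetic_config")
}

#' Offset-correct a force series against an unloaded window
#'
#' Subtracts from every component its mean over an unloaded window of
#' `baseline_window_s` seconds, taken at the start of the trial, or at the end
#' when the start already holds loading data (mean |fz| above the loading
#' guard). Errors when both candidate windows are loaded. The correction is
#' idempotent: a corrected trace has a near-zero baseline, so re-running
#' subtracts (numerically) nothing.
#'
#' @param force a [force_series()].
#' @param cfg a [kinetic_config()].
#' @return The corrected `force_series` with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(force, cfg = kinetic_config()) {
  n <- length(force$fz)
  w <- as.integer(round(cfg$baseline_window_s * force$rate))
  if (n <= w) stop("trial shorter than the baseline window", call. = FALSE)
  start_idx <- 1:w
  end_idx <- (n - w + 1L):n
  idx <- if (mean(abs(force$fz[start_idx])) <= cfg$loading_guard_n) start_idx
         else if (mean(abs(force$fz[end_idx])) <= cfg$loading_guard_n) end_idx
         else stop("both candidate baseline windows hold loading data",
                   call. = FALSE)
  shift <- function(comp) if (is.null(comp)) NULL else comp - mean(comp[idx])
  force_series(force$fz - mean(force$fz[idx]), shift(force$fx),
               shift(force$fy), force$rate, baseline_corrected = TRUE)
}

#' Decimate a force series to the kinematic rate
#'
#' Plain decimation keeping samples `0, k, 2k, ...` with
#' `k = rate / target_rate`, deliberately without anti-alias filtering so the
#' retained samples equal the raw recorded values. Users who prefer filtered
#' decimation can low-pass beforehand via `anti_alias = TRUE`.
#'
#' @param force a [force_series()].
#' @param cfg a [kinetic_config()] supplying `target_rate`.
#' @param anti_alias low-pass filter (zero-lag Butterworth at 80% of the
#'   target Nyquist) before decimating; off by default.
#' @return A `force_series` at `target_rate`.
#' @export
decimate_to <- function(force, cfg = kinetic_config(), anti_alias = FALSE) {
  k <- force$rate / cfg$target_rate
  if (abs(k - round(k)) > 1e-9)
    stop("`rate` must be an integer multiple of `target_rate`",
         call. = FALSE)
  k <- as.integer(round(k))
  take <- function(comp) {
    if (is.null(comp)) return(NULL)
    if (anti_alias)
      comp <- lowpass_zero_lag(comp, 0.8 * cfg$target_rate / 2,
                               rate = force$rate)
    comp[seq(1L, length(comp), by = k)]
  }
  force_series(take(force$fz), take(force$fx), take(force$fy),
               cfg$target_rate, baseline_corrected = force$baseline_corrected)
}

# Raw contact intervals: foot_on = first frame with fz > thr, foot_off =
# first subsequent frame with fz < thr. 0-based frames; off is NA when the
# trace ends while still loaded.
contact_intervals <- function(fz, threshold) {
  on <- integer(0); off <- integer(0)
  i <- 1L; n <- length(fz)
  while (i <= n) {
    k_on <- which(fz[i:n] > threshold)
    if (length(k_on) == 0L) break
    s <- i + k_on[1L] - 1L
    k_off <- which(fz[s:n] < threshold)
    e <- if (length(k_off) == 0L) NA_integer_ else s + k_off[1L] - 1L
    on <- c(on, s - 1L); off <- c(off, if (is.na(e)) NA_integer_ else e - 1L)
    if (is.na(e)) break
    i <- e + 1L
  }
  data.frame(on = on, off = off)
}

#' Detect reference footfall events from vertical force
#'
#' Foot on is the first frame in which the vertical force strictly exceeds
#' the threshold; foot off is the first subsequent frame in which it drops
#' strictly below (a frame exactly at the threshold belongs to neither
#' crossing). Contacts separated by less than `min_contact_gap_s` of
#' sub-threshold force are merged. The input must be baseline-corrected and
#' already at the target rate (see [baseline_correct()] and [decimate_to()]).
#'
#' @param force a [force_series()] with `baseline_corrected = TRUE`.
#' @param cfg a [kinetic_config()].
#' @return An `event_set`-style data frame with `method = "kinetic"`; one
#'   `foot_on` (and, when the trace unloads again, one `foot_off`) row per
#'   contact. Empty when the force never exceeds the threshold.
#' @export
detect_kinetic_events <- function(force, cfg = kinetic_config()) {
  if (!force$baseline_corrected)
    stop("run baseline_correct() before event detection", call. = FALSE)
  if (abs(force$rate - cfg$target_rate) > 1e-9)
    stop("decimate to `target_rate` before event detection", call. = FALSE)
  ci <- contact_intervals(force$fz, cfg$threshold_n)
  # merge chattering contacts
  if (nrow(ci) > 1L) {
    gap_frames <- cfg$min_contact_gap_s * force$rate
    keep_on <- ci$on[1L]; merged <- ci[0, ]
    for (r in seq_len(nrow(ci) - 1L)) {
      if (!is.na(ci$off[r]) && (ci$on[r + 1L] - ci$off[r]) < gap_frames) next
      merged <- rbind(merged, data.frame(on = keep_on, off = ci$off[r]))
      keep_on <- ci$on[r + 1L]
    }
    merged <- rbind(merged, data.frame(on = keep_on, off = ci$off[nrow(ci)]))
    ci <- merged
  }
  rows <- list()
  for (r in seq_len(nrow(ci))) {
    rows[[length(rows) + 1L]] <-
      footfall_event("foot_on", ci$on[r], force$rate, "kinetic",
                     stride = r)
    if (!is.na(ci$off[r]))
      rows[[length(rows) + 1L]] <-
        footfall_event("foot_off", ci$off[r], force$rate, "kinetic",
                       stride = r)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  class(ev) <- c("event_set", "data.frame")
  ev
}

#' Sensitivity of kinetic event timings to the force threshold
#'
#' Repeats kinetic event detection over a grid of thresholds (50 to 150 N in
#' 10 N steps by default) and expresses each contact's foot-on and foot-off
#' timing as the difference in milliseconds to the event found at the first
#' (reference) threshold. Positive differences mean the event occurs later
#' than at the reference threshold; raising the threshold can only delay foot
#' on and advance foot off. Contacts that become undetectable at a higher
#' threshold are recorded as missing, not as zero.
#'
#' @param force a baseline-corrected [force_series()] at the target rate.
#' @param thresholds ascending threshold grid in newtons; the first entry is
#'   the reference.
#' @param cfg a [kinetic_config()] (its `threshold_n` is ignored in favour of
#'   the grid).
#' @return A data frame with columns `threshold`, `contact`, `kind`
#'   (`foot_on`/`foot_off`) and `diff_ms`, covering every non-reference
#'   threshold.
#' @export
threshold_sweep <- function(force, thresholds = seq(50, 150, by = 10),
                            cfg = kinetic_config()) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be sorted ascending", call. = FALSE)
  events_at <- function(thr) {
    c2 <- cfg; c2$threshold_n <- thr
    ev <- detect_kinetic_events(force, c2)
    list(on = ev$time[ev$kind == "foot_on"],
         off = ev$time[ev$kind == "foot_off"],
         on_stride = ev$stride[ev$kind == "foot_on"],
         off_stride = ev$stride[ev$kind == "foot_off"])
  }
  ref <- events_at(thresholds[1L])
  n_contact <- length(ref$on)
  out <- list()
  for (thr in thresholds[-1L]) {
    cur <- events_at(thr)
    for (ct in seq_len(n_contact)) {
      t_on_ref <- ref$on[ct]
      t_off_ref <- if (ct <= length(ref$off)) ref$off[ct] else NA_real_
      # a higher-threshold contact lies inside its reference contact interval
      hit <- which(cur$on >= t_on_ref &
                   (is.na(t_off_ref) | cur$on <= t_off_ref))
      d_on <- d_off <- NA_real_
      if (length(hit) > 0L) {
        j <- hit[1L]
        d_on <- (cur$on[j] - t_on_ref) * 1000
        if (!is.na(t_off_ref) && j <= length(cur$off))
          d_off <- (cur$off[j] - t_off_ref) * 1000
      }
      out[[length(out) + 1L]] <- data.frame(
        threshold = thr, contact = ct,
        kind = c("foot_on", "foot_off"), diff_ms = c(d_on, d_off))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
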