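#' Gait condition presets for the synthetic generator
#'
#' Six presets describe the study conditions (gait x path x circle side).
#' Stride and stance durations (means and SDs) are the observed values for
#' walking and trotting horses on the straight and on a 3 m radius circle;
#' forward speeds, hoof geometry and impact velocities are generator choices
#' of realistic magnitude. Stride duration on the circle is common to the
#' inside and outside limb of the same gait.
#'
#' @param name one of `"straight_walk"`, `"straight_trot"`,
#'   `"circle_walk_inside"`, `"circle_walk_outside"`, `"circle_trot_inside"`,
#'   `"circle_trot_outside"`.
#' @return For `gait_preset()`, a single preset (class `gait_preset`); for
#'   `gait_presets()`, the named list of all six.
#' @export
gait_presets <- function() {
  base <- list(
    straight_walk = list(gait = "walk", path = "straight",
                         circle_side = "n/a", stride_ms = 1153,
                         stride_sd_ms = 55, stance_fore_ms = 734,
                         stance_fore_sd_ms = 41, stance_hind_ms = 722,
                         stance_hind_sd_ms = 39, speed = 1.4),
    straight_trot = list(gait = "trot", path = "straight",
                         circle_side = "n/a", stride_ms = 722,
                         stride_sd_ms = 31, stance_fore_ms = 328,
                         stance_fore_sd_ms = 24, stance_hind_ms = 283,
                         stance_hind_sd_ms = 11, speed = 3.4),
    circle_walk_inside = list(gait = "walk", path = "circle",
                              circle_side = "inside", stride_ms = 1189,
                              stride_sd_ms = 64, stance_fore_ms = 772,
                              stance_fore_sd_ms = 48, stance_hind_ms = 769,
                              stance_hind_sd_ms = 41, speed = 1.25),
    circle_walk_outside = list(gait = "walk", path = "circle",
                               circle_side = "outside", stride_ms = 1189,
                               stride_sd_ms = 64, stance_fore_ms = 764,
                               stance_fore_sd_ms = 59, stance_hind_ms = 742,
                               stance_hind_sd_ms = 45, speed = 1.25),
    circle_trot_inside = list(gait = "trot", path = "circle",
                              circle_side = "inside", stride_ms = 783,
                              stride_sd_ms = 26, stance_fore_ms = 394,
                              stance_fore_sd_ms = 25, stance_hind_ms = 345,
                              stance_hind_sd_ms = 15, speed = 3.0),
    circle_trot_outside = list(gait = "trot", path = "circle",
                               circle_side = "outside", stride_ms = 783,
                               stride_sd_ms = 26, stance_fore_ms = 373,
                               stance_fore_sd_ms = 25, stance_hind_ms = 310,
                               stance_hind_sd_ms = 13, speed = 3.0)
  )
  lapply(stats::setNames(names(base), names(base)), function(nm) {
    p <- base[[nm]]
    p$name <- nm
    p$hoof_height <- 0.05        # marker height on the proximal hoof wall (m)
    p$breakover_fraction <- 0.2  # fraction of stance spent in breakover
    p$swing_peak_m <- if (p$gait == "walk") 0.06 else 0.12
    p$v_impact <- if (p$gait == "walk") 0.8 else 1.6  # vertical, m/s
    p$vx_impact <- if (p$gait == "walk") 0.2 else 0.3 # horizontal, m/s
    p$body_mass_kg <- 448
    class(p) <- "gait_preset"
    p
  })
}

#' @rdname gait_presets
#' @export
gait_preset <- function(name) {
  ps <- gait_presets()
  if (!name %in% names(ps))
    stop("unknown preset; one of: ", paste(names(ps), collapse = ", "),
         call. = FALSE)
  ps[[name]]
}

#' @export
print.gait_preset <- function(x, ...) {
  cat(sprintf(
    "<gait_preset> %s: stride %g (%g) ms, stance fore %g / hind %g ms, %g m/s\n",
    x$name, x$stride_ms, x$stride_sd_ms, x$stance_fore_ms, x$stance_hind_ms,
    x$speed))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Quintic polynomial interpolation with prescribed endpoint position,
# velocity and acceleration; evaluated at times `t` in [0, T].
quintic <- function(t, T, p0, p1, v0 = 0, v1 = 0, a0 = 0, a1 = 0) {
  dp <- p1 - p0 - v0 * T - a0 * T^2 / 2
  dv <- v1 - v0 - a0 * T
  da <- a1 - a0
  M <- rbind(c(T^3, T^4, T^5),
             c(3 * T^2, 4 * T^3, 5 * T^4),
             c(6 * T, 12 * T^2, 20 * T^3))
  cf <- solve(M, c(dp, dv, da))
  p0 + v0 * t + a0 * t^2 / 2 + cf[1L] * t^3 + cf[2L] * t^4 + cf[3L] * t^5
}

# Breakover geometry: the marker sits a horizontal distance `beta * h`
# behind the toe pivot at height `h`, and the hoof rotates (accelerating,
# angle ~ s^2) from the stance angle to `alpha_f` chosen so the horizontal
# marker translation reaches exactly `h` at toe-off -- the premise of the
# trigonometric foot-off detector. Because `alpha_f` lies past the marker
# zenith, the vertical velocity dips into a pronounced negative trough at
# toe-off, the event the velocity-minimum detector keys on.
breakover_geometry <- function(h, beta = 0.6) {
  r <- h * sqrt(1 + beta^2)
  list(beta = beta, r = r,
       alpha0 = atan2(1, beta),
       alpha_f = acos((beta - 1) / sqrt(1 + beta^2)))
}

# Swing-phase marker path from the breakover-end state to the next contact.
# Horizontal: quintic blending the breakover exit velocity into a small
# forward impact velocity. Vertical: quintic from the breakover-end descent
# to the stance height with a prescribed downward impact velocity, plus a
# sin^2 arch for ground clearance (the arch lifts the foot immediately after
# toe-off, closing the vertical-velocity trough).
swing_path <- function(t, T, x0, vx0, x1, vx1, y0, vy0, y1, vy1, peak) {
  s <- t / T
  x <- quintic(t, T, x0, x1, v0 = vx0, v1 = vx1)
  y <- quintic(t, T, y0, y1, v0 = vy0, v1 = -abs(vy1)) + peak * sin(pi * s)^2
  cbind(x = x, y = y)
}

# Draw per-stride timing (seconds) for one trial, quantised to frames.
draw_stride_timing <- function(preset, limb, n_strides, rate) {
  st_mean <- if (limb == "fore") preset$stance_fore_ms else
    preset$stance_hind_ms
  st_sd <- if (limb == "fore") preset$stance_fore_sd_ms else
    preset$stance_hind_sd_ms
  stride_s <- stats::rnorm(n_strides, preset$stride_ms, preset$stride_sd_ms) / 1000
  stance_s <- stats::rnorm(n_strides, st_mean, st_sd) / 1000
  stance_s <- pmin(pmax(stance_s, 0.15), 0.85 * stride_s)
  stride_f <- pmax(as.integer(round(stride_s * rate)), 20L)
  stance_f <- pmax(as.integer(round(stance_s * rate)), 10L)
  break_f <- pmax(3L, as.integer(round(preset$breakover_fraction * stance_f)))
  data.frame(stride_f = stride_f, stance_f = stance_f, break_f = break_f)
}

#' Generate a synthetic single-marker hoof trajectory with known events
#'
#' Builds a marker path with the movement structure the detectors assume:
#' a stance plateau at constant position and marker height `hoof_height`;
#' a breakover phase in which a rigid hoof rotates (accelerating) about a toe
#' pivot, past the marker zenith, with the geometry chosen so the horizontal
#' marker translation reaches exactly `hoof_height` at toe-off and the
#' vertical velocity dips into a negative trough there; a smooth swing arc
#' fast enough mid-swing to trigger pre-segmentation; and a sharp impact in
#' which the marker velocity collapses to zero within one frame. Truth foot-on is the first stance frame of each stride, truth
#' foot-off the last breakover frame. Gaussian marker noise (default 0.8 mm,
#' the calibrated linear accuracy of optical capture) is added to all axes.
#'
#' @param preset a [gait_preset()] (or its name).
#' @param n_strides number of complete strides.
#' @param limb "fore" or "hind" (selects the stance duration model).
#' @param noise_sd marker noise SD in metres.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param rate sampling rate in frames per second.
#' @param trial_id,foot_id labels for the output objects.
#' @return A list with `trajectory` ([trajectory3d()]) and `truth` (event
#'   data frame with 0-based frames, `method = "truth"`).
#' @export
make_stride_trajectory <- function(preset, n_strides = 1L, limb = "fore",
                                   noise_sd = 0.0008, seed = NULL,
                                   rate = 100, trial_id = "synthetic",
                                   foot_id = paste0(limb, "_left")) {
  if (is.character(preset)) preset <- gait_preset(preset)
  limb <- match.arg(limb, c("fore", "hind"))
  with_seed(seed, {
    tm <- draw_stride_timing(preset, limb, n_strides, rate)
    h <- preset$hoof_height
    geo <- breakover_geometry(h)

    # contact frames on a virtual timeline that starts one stride early
    contact <- integer(n_strides + 1L)
    contact[1L] <- tm$stride_f[1L] # virtual stride 0 precedes contact 1
    for (i in seq_len(n_strides))
      contact[i + 1L] <- contact[i] + tm$stride_f[i]
    n_total <- contact[n_strides + 1L] # frames up to (excl.) virtual contact N+1
    # open and close the record in the fast mid-swing region, where the
    # resultant speed is safely above the pre-segmentation threshold
    swing1_f <- tm$stride_f[1L] - tm$stance_f[1L]
    swingN_f <- tm$stride_f[n_strides] - tm$stance_f[n_strides]
    lead_f <- min(as.integer(round(0.25 * rate)),
                  as.integer(round(0.6 * swing1_f)))
    tail_f <- as.integer(round(0.55 * swingN_f))
    start <- contact[1L] - lead_f
    last_break <- contact[n_strides] + tm$stance_f[n_strides]
    end <- min(last_break + tail_f, n_total - 1L)

    x <- numeric(n_total); y <- numeric(n_total)
    X <- cumsum(c(0, tm$stride_f / rate * preset$speed)) # contact x-positions

    fill_stride <- function(i, Xc, Xn, stance_f, break_f, stride_f, c0) {
      # stance flat
      flat_f <- stance_f - break_f
      if (flat_f > 0L) {
        idx <- (c0 + 1L):(c0 + flat_f)
        x[idx] <<- Xc; y[idx] <<- h
      }
      # breakover: frames c0+flat_f .. c0+stance_f, s in [0, 1]
      bidx <- (c0 + flat_f):(c0 + stance_f) + 1L
      s <- seq(0, 1, length.out = break_f + 1L)
      alpha <- geo$alpha0 + (geo$alpha_f - geo$alpha0) * s^2
      px <- Xc + geo$beta * h # toe pivot
      x[bidx] <<- px - geo$r * cos(alpha)
      y[bidx] <<- geo$r * sin(alpha)
      # swing: frames c0+stance_f+1 .. c0+stride_f-1
      T_b <- break_f / rate
      T_sw <- (stride_f - stance_f) / rate
      alpha_dot <- 2 * (geo$alpha_f - geo$alpha0) / T_b
      vx0 <- geo$r * sin(geo$alpha_f) * alpha_dot
      vy0 <- geo$r * cos(geo$alpha_f) * alpha_dot # negative: past zenith
      sidx <- if (c0 + stance_f + 1L <= c0 + stride_f - 1L)
        (c0 + stance_f + 1L):(c0 + stride_f - 1L) else integer(0)
      if (length(sidx)) {
        t_s <- (sidx - (c0 + stance_f + 1L) + 1L) / rate
        sw <- swing_path(t_s, T_sw,
                         x0 = px - geo$r * cos(geo$alpha_f), vx0 = vx0,
                         x1 = Xn, vx1 = preset$vx_impact,
                         y0 = geo$r * sin(geo$alpha_f), vy0 = vy0, y1 = h,
                         vy1 = preset$v_impact, peak = preset$swing_peak_m)
        x[sidx + 1L] <<- sw[, "x"]; y[sidx + 1L] <<- sw[, "y"]
      }
      invisible(NULL)
    }

    # virtual leading stride (only its swing tail is kept)
    fill_stride(0L, X[1L], X[2L], tm$stance_f[1L], tm$break_f[1L],
                tm$stride_f[1L], 0L)
    for (i in seq_len(n_strides)) {
      Xn <- if (i < n_strides) X[i + 2L] else X[i + 1L] +
        tm$stride_f[i] / rate * preset$speed
      fill_stride(i, X[i + 1L], Xn, tm$stance_f[i], tm$break_f[i],
                  tm$stride_f[i], contact[i])
    }

    keep <- (start + 1L):(end + 1L)
    n_keep <- length(keep)
    coords <- cbind(x[keep], y[keep], numeric(n_keep))
    if (noise_sd > 0)
      coords <- coords + matrix(stats::rnorm(3L * n_keep, 0, noise_sd),
                                ncol = 3L)
    traj <- trajectory3d(coords, rate = rate, vertical_axis = 2L,
                         trial_id = trial_id, foot_id = foot_id)

    truth <- do.call(rbind, lapply(seq_len(n_strides), function(i) {
      rbind(
        footfall_event("foot_on", contact[i] - start, rate, "truth",
                       stride = i),
        footfall_event("foot_off", contact[i] + tm$stance_f[i] - start, rate,
                       "truth", stride = i))
    }))
    truth <- cbind(trial_id = trial_id, foot_id = foot_id, truth,
                   stringsAsFactors = FALSE)
    class(truth) <- c("event_set", "data.frame")
    list(trajectory = traj, truth = truth, timing = tm)
  })
}

# Vertical-force envelope for one contact, evaluated at times `t` (s).
# Rises steeply from 5 ms before contact, carries a double-hump load plateau
# scaled to body weight, and offloads over `fall_s` with linear (steep,
# fore-like) or quadratic (gradual, hind-like) shape, reaching zero exactly
# at `t_off`.
contact_force <- function(t, t_on, t_off, peak_n, shoulder_n = 1200,
                          offload = c("steep", "gradual")) {
  offload <- match.arg(offload)
  rise_s <- 0.015
  fall_s <- if (offload == "steep") 0.03 else 0.08
  a <- t_on - 0.005
  t1 <- a + rise_s
  c0 <- t_off - fall_s
  f <- numeric(length(t))
  i <- t >= a & t < t1
  f[i] <- shoulder_n * (t[i] - a) / rise_s
  i <- t >= t1 & t < c0
  s <- (t[i] - t1) / (c0 - t1)
  env <- sin(pi * s)^0.9 * (1 - 0.25 * sin(pi * s)^8)
  f[i] <- shoulder_n + (peak_n - shoulder_n) * env
  i <- t >= c0 & t < t_off
  u <- (t[i] - c0) / fall_s
  f[i] <- shoulder_n * (if (offload == "steep") (1 - u) else (1 - u)^2)
  f
}

#' Generate a synthetic vertical ground-reaction-force trace
#'
#' Produces a 1,000 Hz force trace for one or more contacts with a steep
#' onset (several hundred newtons within ~10 ms of touch-down, so the 75 N
#' upward crossing matches the kinematic contact frame within one 100 Hz
#' frame after decimation), a double-hump load plateau scaled to body weight,
#' and a configurable offload: `"steep"` emulates forelimb-like rapid
#' unloading, `"gradual"` the more gradual hind-limb tailing-off that makes
#' foot-off timings sensitive to the force threshold. Optional zero-mean
#' sensor noise and a constant sensor offset support baseline-correction
#' testing.
#'
#' @param preset a [gait_preset()] (or its name).
#' @param t_on,t_off contact and lift-off times in seconds (equal length).
#'   Defaults draw a single contact of the preset's fore-limb stance duration
#'   after a 0.3 s unloaded lead-in.
#' @param duration_s total trace duration; defaults to the last `t_off` plus
#'   0.3 s.
#' @param offload `"steep"` (fore-like) or `"gradual"` (hind-like).
#' @param noise_n sensor noise SD in newtons.
#' @param offset_n constant sensor offset in newtons.
#' @param seed integer seed.
#' @param rate sampling rate (Hz).
#' @return A [force_series()] with attribute `truth` holding `t_on`/`t_off`.
#' @export
make_force_trace <- function(preset, t_on = NULL, t_off = NULL,
                             duration_s = NULL,
                             offload = c("steep", "gradual"), noise_n = 2,
                             offset_n = 0, seed = NULL, rate = 1000) {
  if (is.character(preset)) preset <- gait_preset(preset)
  offload <- match.arg(offload)
  if (is.null(t_on)) t_on <- 0.3
  if (is.null(t_off)) t_off <- t_on + preset$stance_fore_ms / 1000
  stopifnot(length(t_on) == length(t_off), all(t_off > t_on))
  if (is.null(duration_s)) duration_s <- max(t_off) + 0.3
  with_seed(seed, {
    t <- seq(0, duration_s, by = 1 / rate)
    bw_n <- preset$body_mass_kg * 9.81
    peak_frac <- if (preset$gait == "walk") 0.6 else 1.1
    fz <- numeric(length(t))
    for (k in seq_along(t_on)) {
      jit <- 1 + stats::rnorm(1L, 0, 0.05)
      fz <- fz + contact_force(t, t_on[k], t_off[k],
                               peak_n = max(1500, peak_frac * bw_n * jit),
                               offload = offload)
    }
    if (noise_n > 0) fz <- fz + stats::rnorm(length(fz), 0, noise_n)
    fz <- fz + offset_n
    out <- force_series(fz, rate = rate, baseline_corrected = FALSE)
    attr(out, "truth") <- data.frame(t_on = t_on, t_off = t_off)
    out
  })
}

#' Generate a complete synthetic trial (trajectory + force + truth)
#'
#' Couples [make_stride_trajectory()] with a time-aligned
#' [make_force_trace()]: the force contacts start and end exactly at the
#' trajectory's truth foot-on/foot-off times.
#'
#' @inheritParams make_stride_trajectory
#' @param force_noise_n,force_offset_n,offload forwarded to
#'   [make_force_trace()].
#' @param force_rate force sampling rate (Hz).
#' @return An object of class `synthetic_trial`: a list with `trajectory`,
#'   `force`, `truth`, plus the generator settings.
#' @export
make_trial <- function(preset, n_strides = 5L, limb = "fore",
                       noise_sd = 0.0008, seed = NULL, rate = 100,
                       force_rate = 1000, offload = c("steep", "gradual"),
                       force_noise_n = 2, force_offset_n = 0,
                       trial_id = "synthetic", foot_id = paste0(limb, "_left")) {
  if (is.character(preset)) preset <- gait_preset(preset)
  offload <- match.arg(offload)
  with_seed(seed, {
    kin <- make_stride_trajectory(preset, n_strides, limb, noise_sd,
                                  seed = NULL, rate = rate,
                                  trial_id = trial_id, foot_id = foot_id)
    tr <- kin$truth
    t_on <- tr$time[tr$kind == "foot_on"]
    t_off <- tr$time[tr$kind == "foot_off"]
    # the force record may extend past the marker record: an unloaded span
    # after the last lift-off guarantees a valid end baseline window
    dur <- max((n_frames(kin$trajectory) - 1L) / rate, max(t_off) + 0.35)
    force <- make_force_trace(preset, t_on, t_off, duration_s = dur,
                              offload = offload, noise_n = force_noise_n,
                              offset_n = force_offset_n, seed = NULL,
                              rate = force_rate)
    structure(
      list(trajectory = kin$trajectory, force = force, truth = tr,
           preset = preset, limb = limb, noise_sd = noise_sd, seed = seed),
      class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %s (%s limb): %d truth events, noise %.2g mm\n",
    x$preset$name, x$limb, nrow(x$truth), x$noise_sd * 1000))
  print(x$trajectory)
  invisible(x)
}

#' Simulate a cohort of horses with known event-timing perturbations
#'
#' Generates event-level data for a cohort: per horse, truth foot-on/foot-off
#' times follow the preset's stride and stance model with a horse-specific
#' stride-duration offset; the kinetic (reference) events equal the truth,
#' while the kinematic events are shifted by a global bias `bias_ms`, a small
#' horse-specific bias (SD `horse_bias_sd_ms`) and per-event Gaussian timing
#' noise (SD `noise_sd_ms`). Because the method difference is kinetic minus
#' kinematic, an injected bias of +b ms is recovered as an accuracy of -b ms,
#' and the timing-noise SD is recovered as the within-horse precision.
#'
#' @param preset a [gait_preset()] (or its name).
#' @param n_horses,strides_per_horse cohort size.
#' @param bias_ms global kinematic bias (ms, positive = kinematic late).
#' @param noise_sd_ms per-event kinematic timing noise SD (ms).
#' @param horse_bias_sd_ms SD of the horse-specific kinematic bias (ms).
#' @param limb "fore" or "hind".
#' @param seed integer seed.
#' @return An object of class `synthetic_cohort` with an `events` data frame
#'   (`horse_id`, `stride`, `kind`, `t_truth`, `t_kinetic`, `t_kinematic`)
#'   and the generating parameters.
#' @export
make_cohort <- function(preset, n_horses = 8L, strides_per_horse = 20L,
                        bias_ms = 0, noise_sd_ms = 2, horse_bias_sd_ms = 0.5,
                        limb = "fore", seed = NULL) {
  if (is.character(preset)) preset <- gait_preset(preset)
  if (n_horses < 1L) stop("`n_horses` must be >= 1", call. = FALSE)
  limb <- match.arg(limb, c("fore", "hind"))
  st_mean <- if (limb == "fore") preset$stance_fore_ms else
    preset$stance_hind_ms
  st_sd <- if (limb == "fore") preset$stance_fore_sd_ms else
    preset$stance_hind_sd_ms
  with_seed(seed, {
    rows <- lapply(seq_len(n_horses), function(hrs) {
      stride_mu <- stats::rnorm(1L, preset$stride_ms, preset$stride_sd_ms / 2)
      u_h <- stats::rnorm(1L, 0, horse_bias_sd_ms)
      strides <- stats::rnorm(strides_per_horse, stride_mu,
                              preset$stride_sd_ms / 2)
      t_on <- 0.5 + cumsum(strides) / 1000
      stance <- pmax(stats::rnorm(strides_per_horse, st_mean, st_sd), 100)
      t_off <- t_on + stance / 1000
      truth <- c(rbind(t_on, t_off))
      kinds <- rep(c("foot_on", "foot_off"), strides_per_horse)
      eps <- stats::rnorm(length(truth), 0, noise_sd_ms)
      data.frame(horse_id = sprintf("horse%02d", hrs),
                 stride = rep(seq_len(strides_per_horse), each = 2L),
                 kind = kinds, t_truth = truth, t_kinetic = truth,
                 t_kinematic = truth + (bias_ms + u_h + eps) / 1000,
                 horse_bias_ms = u_h)
    })
    structure(
      list(events = do.call(rbind, rows), preset = preset, limb = limb,
           bias_ms = bias_ms, noise_sd_ms = noise_sd_ms,
           horse_bias_sd_ms = horse_bias_sd_ms, seed = seed),
      class = "synthetic_cohort")
  })
}

#' Method-comparison summary for a simulated cohort
#'
#' Runs the full comparison pipeline on a [make_cohort()] object: per horse,
#' kinematic and kinetic events are paired with [pair_events()], then the
#' pooled per-stride differences are summarised with [horse_level_stats()]
#' separately for foot-on and foot-off events.
#'
#' @param cohort a `synthetic_cohort`.
#' @param max_gap_ms pairing tolerance forwarded to [pair_events()].
#' @return A list with one [horse_level_stats()] summary per event kind
#'   (`foot_on`, `foot_off`).
#' @export
cohort_agreement <- function(cohort, max_gap_ms = 100) {
  ev <- cohort$events
  diffs <- do.call(rbind, lapply(split(ev, ev$horse_id), function(d) {
    pr <- pair_events(
      data.frame(kind = d$kind, time = d$t_kinematic),
      data.frame(kind = d$kind, time = d$t_kinetic),
      max_gap_ms = max_gap_ms)
    if (nrow(pr$differences) == 0L) return(NULL)
    cbind(horse_id = d$horse_id[1L], pr$differences)
  }))
  lapply(stats::setNames(c("foot_on", "foot_off"), c("foot_on", "foot_off")),
         function(kd) horse_level_stats(diffs[diffs$kind == kd, ,
                                              drop = FALSE]))
}
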