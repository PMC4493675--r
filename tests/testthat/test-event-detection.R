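# build a trajectory whose raw resultant speed equals `v` (m/s) by walking
# along the first axis; vertical axis stays at `height`
traj_from_speed <- function(v, rate = 100, height = 0.05) {
  x <- cumsum(c(0, v)) / rate
  trajectory3d(x, rep(height, length(x)), rep(0, length(x)), rate = rate)
}

# build a trajectory with a given vertical-displacement vector
traj_from_vertical <- function(y, rate = 100) {
  trajectory3d(rep(0, length(y)), y, rep(0, length(y)), rate = rate)
}

test_that("condition profiles carry the validated thresholds and cut-offs", {
  p <- condition_profile("walk", "straight", "fore")
  expect_equal(p$v_threshold, 0.5)
  expect_equal(p$accel_component, "vertical")
  expect_equal(p$accel_cutoff_hz, 20)
  expect_equal(p$vvel_cutoff_hz, 15)
  expect_equal(condition_profile("trot", "straight", "hind")$accel_cutoff_hz,
               25)
  pin_f <- condition_profile("trot", "circle", "fore", "inside")
  expect_equal(pin_f$v_threshold, 1.0)
  pin_h <- condition_profile("trot", "circle", "hind", "inside")
  expect_equal(pin_h$v_threshold, 1.2)
  expect_equal(pin_h$accel_component, "resultant")
  expect_equal(pin_h$accel_cutoff_hz, 15)
  # resultant acceleration applies to both hind limbs on the circle at trot
  pout_h <- condition_profile("trot", "circle", "hind", "outside")
  expect_equal(pout_h$accel_component, "resultant")
  expect_equal(pout_h$v_threshold, 0.5)
  expect_error(condition_profile("walk", "circle", "fore"), "circle_side")
  expect_error(condition_profile("walk", "straight", "fore", "inside"),
               "n/a")
})

test_that("limb side and rein resolve to inside/outside", {
  # on the right rein (clockwise) the left limbs are on the outside
  expect_equal(resolve_condition_profile("trot", "circle", "fore",
                                         "left", "right")$circle_side,
               "outside")
  expect_equal(resolve_condition_profile("trot", "circle", "fore",
                                         "left", "left")$circle_side,
               "inside")
  expect_equal(resolve_condition_profile("walk", "circle", "hind",
                                         "right", "right")$circle_side,
               "inside")
  expect_equal(resolve_condition_profile("walk", "straight",
                                         "fore")$circle_side, "n/a")
  expect_error(resolve_condition_profile("walk", "straight", "fore",
                                         rein = "left"), "n/a")
})

test_that("pre-segmentation fires on downward crossings of the smoothed speed", {
  # constant speed above the threshold: no strides
  expect_length(presegment_strides(traj_from_speed(rep(3, 200))), 0L)
  # two step dips
  v <- rep(3, 200)
  v[41:60] <- 0.3
  v[141:160] <- 0.3
  wins <- presegment_strides(traj_from_speed(v))
  sm <- moving_average(resultant_speed(traj_from_speed(v)), 10)$values
  expected <- which(sm[-1] < 2.5 & sm[-length(sm)] >= 2.5) # 0-based frames
  expect_length(wins, 2L)
  expect_equal(vapply(wins, `[[`, integer(1), "start"), expected)
  expect_true(abs(wins[[1]]$start - 40L) <= 4L)
  expect_equal(wins[[1]]$foot_on_search_end, wins[[1]]$start + 20L)
  expect_equal(wins[[1]]$liftoff_len, 15L)
})

test_that("noisy oscillation around the threshold segments like smooth-then-scan", {
  set.seed(51)
  v <- 2.5 + 0.4 * sin((1:400) / 6) + rnorm(400, 0, 0.2)
  v <- pmax(v, 0.01)
  wins <- presegment_strides(traj_from_speed(v))
  sm <- moving_average(v, 10) # equals the smoothed resultant speed here
  expected <- which(sm[-1] < 2.5 & sm[-length(sm)] >= 2.5)
  expect_equal(vapply(wins, `[[`, integer(1), "start"), expected)
})

test_that("velocity-threshold foot-on finds the first raw sub-threshold frame", {
  v <- c(rep(3, 10), 2.0, 1.0, 0.4, 0.1, rep(0.05, 26))
  traj <- traj_from_speed(v)
  ev <- detect_foot_on_threshold(traj, stride_window(10L, 100),
                                 walk_profile())
  expect_equal(ev$frame, 12L) # window-relative frame 2
  expect_equal(ev$quality_flag, "ok")
  expect_equal(ev$method, "A")
  expect_equal(ev$time, 0.12)
  # nothing below threshold: flagged, event at the window end
  traj2 <- traj_from_speed(rep(2, 40))
  ev2 <- detect_foot_on_threshold(traj2, stride_window(5L, 100),
                                  walk_profile())
  expect_equal(ev2$quality_flag, "window_exhausted")
  expect_equal(ev2$frame, 25L)
})

test_that("raising the velocity threshold never delays the foot-on frame", {
  set.seed(77)
  for (rep_i in 1:25) {
    v <- abs(3 - cumsum(rnorm(40, 0.12, 0.3)))
    traj <- traj_from_speed(v)
    win <- stride_window(0L, 100)
    frames <- vapply(c(0.3, 0.5, 0.8, 1.2), function(thr) {
      p <- condition_profile("walk", "straight", "fore", v_threshold = thr)
      detect_foot_on_threshold(traj, win, p)$frame
    }, integer(1))
    expect_true(all(diff(frames) <= 0L))
  }
})

test_that("breakover start is the end of the stance plateau", {
  v <- c(seq(2, 0.05, length.out = 10), rep(0.05, 51),
         pmin(seq(0.15, by = 0.1, length.out = 60), 3))
  traj <- traj_from_speed(v)
  bs <- detect_breakover_start(traj, 10L)
  # oracle: scan the smoothed signal for the sustain rule
  sm <- moving_average(v, 10)
  exp_bs <- NA_integer_
  for (i in 11:(length(sm) - 3)) {
    if (sm[i] < 0.35 && all(sm[(i + 1):(i + 3)] > 0.35)) {
      exp_bs <- i - 1L
      break
    }
  }
  expect_equal(bs, exp_bs)
  expect_true(abs(bs - 60L) <= 3L)
  # speed never below the plateau ceiling: no stance plateau
  expect_error(detect_breakover_start(traj_from_speed(rep(1, 60)), 0L),
               "no stance plateau")
})

test_that("a one-frame blip inside stance does not end the plateau", {
  v <- c(rep(0.05, 61), seq(0.5, 3, length.out = 30))
  v[36] <- 0.6 # blip
  traj <- traj_from_speed(v)
  bs <- detect_breakover_start(traj, 0L, window = 1L) # unsmoothed: isolate sustain rule
  expect_equal(bs, 60L)
})

test_that("trigonometric foot-off takes the last frame inside the hoof-height radius", {
  d <- c(0, 0.01, 0.03, 0.049, 0.051, 0.09, seq(0.13, 1, length.out = 14))
  x <- 0.1 + d
  traj <- trajectory3d(x, rep(0.05, length(x)), rep(0, length(x)), rate = 100)
  st <- foot_state_at(traj, 0L)
  expect_equal(st$hoof_height, 0.05)
  ev <- detect_foot_off_trig(traj, st, 0L, stride_window(0L, 100))
  expect_equal(ev$frame, 3L)
  expect_equal(ev$quality_flag, "ok")
  expect_equal(ev$method, "B")
  # stationary marker: distance stays below height for the whole window
  traj2 <- trajectory3d(rep(0.1, 30), rep(0.05, 30), rep(0, 30), rate = 100)
  ev2 <- detect_foot_off_trig(traj2, foot_state_at(traj2, 0L), 2L,
                              stride_window(0L, 100))
  expect_equal(ev2$quality_flag, "window_exhausted")
  expect_equal(ev2$frame, 17L) # breakover start + 15-frame window
  # distance already beyond the height at breakover start
  st3 <- list(p_ref = c(0, 0.05, 0), hoof_height = 0.05)
  ev3 <- detect_foot_off_trig(traj, st3, 2L, stride_window(0L, 100))
  expect_equal(ev3$quality_flag, "window_exhausted")
  expect_equal(ev3$frame, 2L)
})

test_that("acceleration-peak foot-on equals an explicit filter-then-scan oracle", {
  set.seed(101)
  for (rep_i in 1:20) {
    n <- 120
    y <- 0.05 + cumsum(cumsum(rnorm(n, 0, 1e-4))) # smooth random walk
    k <- sample(40:70, 1)
    y[(k + 1):n] <- y[k + 1] # hard stop: acceleration spike near k
    traj <- traj_from_vertical(y + rnorm(n, 0, 1e-5))
    win <- stride_window(30L, 100)
    prof <- walk_profile()
    ev <- detect_foot_on_accel(traj, win, prof)
    acc <- diff(diff(y + (traj$coords[, 2] - y))) * 100^2
    filt <- lowpass_zero_lag(acc, prof$accel_cutoff_hz, rate = 100)
    i0 <- win$start; i1 <- min(win$foot_on_search_end, length(filt) - 1L)
    best <- i0
    for (f in i0:i1) if (filt[f + 1] > filt[best + 1]) best <- f
    expect_equal(ev$frame, best)
  }
})

test_that("acceleration-peak frame is invariant to amplitude scaling", {
  set.seed(55)
  tr <- make_trial("straight_trot", 2, noise_sd = 0, seed = 15)
  prof <- condition_profile("trot", "straight", "fore")
  win <- presegment_strides(tr$trajectory)[[1]]
  f1 <- detect_foot_on_accel(tr$trajectory, win, prof)$frame
  scaled <- tr$trajectory
  scaled$coords <- scaled$coords * 3.7
  f2 <- detect_foot_on_accel(scaled, win, prof)$frame
  expect_equal(f1, f2)
})

test_that("velocity-minimum foot-off refines the filtered minimum on the raw signal", {
  f <- 0:99
  vv <- -0.3 * exp(-((f - 30) / 6)^2) # smooth trough at frame 30
  vv[32] <- vv[32] - 0.08             # raw minimum one frame later
  y <- 0.2 + cumsum(c(0, vv)) / 100
  traj <- traj_from_vertical(y)
  ev <- detect_foot_off_velmin(traj, 10L, walk_profile())
  raw <- differentiate(vertical_displacement(traj))$values
  filt <- lowpass_zero_lag(raw, 15, rate = 100)
  expect_equal(ev$frame, oracle_velmin(filt, raw, 10L))
  expect_equal(ev$frame, 31L)
  expect_equal(ev$quality_flag, "ok")
})

test_that("velocity-minimum foot-off finds a sampled sinusoid trough", {
  # vertical velocity 0.5 sin(2 pi f t), f = 1.25 Hz: downward zero crossing
  # at 0.4 s, trough 3/(4f) = 0.6 s after the origin
  t <- (0:119) / 100
  y <- 0.2 - (0.5 / (2 * pi * 1.25)) * cos(2 * pi * 1.25 * t)
  ev <- detect_foot_off_velmin(traj_from_vertical(y), 41L, walk_profile())
  expect_true(abs(ev$frame - 60L) <= 1L)
})

test_that("monotonically decreasing vertical velocity yields the flagged span minimum", {
  y <- 0.5 - 0.001 * (0:80)^2 / 2 # velocity strictly decreasing
  ev <- detect_foot_off_velmin(traj_from_vertical(y), 5L, walk_profile())
  expect_equal(ev$quality_flag, "no_local_minimum")
  expect_true(ev$frame >= 5L)
})

test_that("segment_trial recovers generator truth on a zero-noise walk trial", {
  tr <- make_trial("straight_walk", 5, noise_sd = 0, seed = 99,
                   force_noise_n = 0)
  prof <- condition_profile("walk", "straight", "fore")
  for (m in list(c("A", "B"), c("C", "D"))) {
    ev <- segment_trial(tr$trajectory, prof, m[1], m[2])
    expect_equal(sum(ev$kind == "foot_on"), 5L)
    expect_equal(sum(ev$kind == "foot_off"), 5L)
    for (kd in c("foot_on", "foot_off")) {
      expect_true(all(abs(ev$frame[ev$kind == kd] -
                            tr$truth$frame[tr$truth$kind == kd]) <= 1L))
    }
    expect_true(all(ev$quality_flag == "ok"))
    # foot_on precedes foot_off within every stride
    for (s in 1:5) {
      on <- ev$frame[ev$stride == s & ev$kind == "foot_on"]
      off <- ev$frame[ev$stride == s & ev$kind == "foot_off"]
      expect_lt(on, off)
    }
  }
})

test_that("a trial starting mid-stance yields a leading foot-off-only stride", {
  tr <- make_trial("straight_walk", 3, noise_sd = 0, seed = 7,
                   force_noise_n = 0)
  on1 <- tr$truth$frame[tr$truth$kind == "foot_on"][1]
  off1 <- tr$truth$frame[tr$truth$kind == "foot_off"][1]
  crop <- on1 + 10L # drop the first contact: record opens mid-stance
  traj <- trajectory3d(tr$trajectory$coords[(crop + 1):n_frames(tr$trajectory), ],
                       rate = 100, trial_id = "cropped")
  ev <- segment_trial(traj, condition_profile("walk", "straight", "fore"))
  first_stride <- ev[ev$stride == 1L, ]
  expect_equal(first_stride$kind, "foot_off")
  expect_true(abs(first_stride$frame - (off1 - crop)) <= 2L)
  expect_equal(sum(ev$kind == "foot_on"), 2L) # remaining full strides
})

test_that("threshold- and event-based pipelines segment the same stride count", {
  tr <- make_trial("circle_trot_outside", 4, limb = "hind",
                   noise_sd = 0.0008, seed = 31)
  prof <- condition_profile("trot", "circle", "hind", "outside")
  ab <- segment_trial(tr$trajectory, prof, "A", "B")
  cd <- segment_trial(tr$trajectory, prof, "C", "D")
  expect_equal(max(ab$stride), max(cd$stride))
  expect_equal(nrow(ab), nrow(cd))
})

test_that("events stay inside their declared search windows", {
  tr <- make_trial("straight_trot", 4, noise_sd = 0.0008, seed = 13)
  prof <- condition_profile("trot", "straight", "fore")
  wins <- presegment_strides(tr$trajectory)
  for (win in wins) {
    a <- detect_foot_on_threshold(tr$trajectory, win, prof)
    expect_true(a$frame >= win$start && a$frame <= win$foot_on_search_end)
    cc <- detect_foot_on_accel(tr$trajectory, win, prof)
    expect_true(cc$frame >= win$start && cc$frame <= win$foot_on_search_end)
    bs <- detect_breakover_start(tr$trajectory, a$frame)
    b <- detect_foot_off_trig(tr$trajectory, foot_state_at(tr$trajectory,
                                                           a$frame), bs, win)
    expect_true(b$frame >= bs && b$frame <= bs + win$liftoff_len)
  }
})

test_that("detection is invariant to horizontal translation and vertical-axis rotation", {
  tr <- make_trial("straight_walk", 3, noise_sd = 0.0008, seed = 21)
  prof <- condition_profile("walk", "straight", "fore")
  ref <- segment_trial(tr$trajectory, prof, "A", "B")
  ref2 <- segment_trial(tr$trajectory, prof, "C", "D")
  th <- 0.83
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- tr$trajectory
  moved$coords <- tr$trajectory$coords %*% R +
    matrix(c(12.3, 0, -4.5), n_frames(tr$trajectory), 3, byrow = TRUE)
  expect_equal(segment_trial(moved, prof, "A", "B")$frame, ref$frame)
  expect_equal(segment_trial(moved, prof, "C", "D")$frame, ref2$frame)
})
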