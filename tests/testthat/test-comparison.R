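events_df <- function(times, kind = "foot_on") {
  data.frame(kind = kind, time = times)
}

test_that("identical event lists pair with zero differences", {
  tt <- c(0.5, 1.6, 2.7)
  pr <- pair_events(events_df(tt), events_df(tt))
  expect_equal(pr$differences$diff_ms, rep(0, 3))
  expect_equal(nrow(pr$unpaired), 0L)
})

test_that("a uniform kinematic delay appears as a negative difference", {
  tt <- c(0.5, 1.6, 2.7, 3.9)
  pr <- pair_events(events_df(tt + 0.010), events_df(tt))
  expect_equal(pr$differences$diff_ms, rep(-10, 4)) # kinetic minus kinematic
})

test_that("spurious events without a partner are reported unpaired", {
  kin <- events_df(c(0.5, 1.05, 1.6)) # extra event between strides
  ref <- events_df(c(0.5, 1.6))
  pr <- pair_events(kin, ref)
  expect_equal(nrow(pr$differences), 2L)
  expect_equal(pr$unpaired$time, 1.05)
  expect_equal(pr$unpaired$source, "kinematic")
  # flagged events are excluded from pairing
  kin2 <- data.frame(kind = "foot_on", time = c(0.5, 1.6),
                     quality_flag = c("ok", "detection_failed"))
  pr2 <- pair_events(kin2, ref)
  expect_equal(nrow(pr2$differences), 1L)
})

test_that("limits of agreement are mean +/- 2 sample SD", {
  expect_equal(unlist(limits_of_agreement(rep(4.2, 10))[c("low", "high")]),
               c(low = 4.2, high = 4.2))
  loa <- limits_of_agreement(c(-1, 1))
  expect_equal(loa$low, -2 * sqrt(2))
  expect_equal(loa$high, 2 * sqrt(2))
  expect_error(limits_of_agreement(3), "at least 2")
})

test_that("the LoA interval covers about 95% of normal differences", {
  set.seed(12)
  d <- rnorm(1e5, 3, 7)
  loa <- limits_of_agreement(d)
  coverage <- mean(d >= loa$low & d <= loa$high)
  expect_gte(coverage, 0.95)
  expect_equal(loa$high - loa$low, 4 * sd(d)) # width is 4 pooled SDs exactly
})

test_that("horse-level statistics follow the two-stage mean/SD scheme", {
  d <- data.frame(horse_id = c("h1", "h1", "h2", "h2"),
                  diff_ms = c(0, 2, 4, 6))
  s <- horse_level_stats(d)
  expect_equal(s$accuracy, 3)
  expect_equal(s$precision_between, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(s$precision_within, sqrt(2), tolerance = 1e-12)
  expect_equal(s$n_strides, 4L)
  expect_equal(s$n_horses, 2L)
  # identical differences: zero spread
  same <- horse_level_stats(data.frame(horse_id = rep(c("a", "b"), each = 3),
                                       diff_ms = rep(5, 6)))
  expect_equal(same$accuracy, 5)
  expect_equal(same$precision_between, 0)
  expect_equal(same$precision_within, 0)
  # single horse: between-horse precision undefined
  one <- horse_level_stats(data.frame(horse_id = "solo",
                                      diff_ms = c(1, 2, 3)))
  expect_true(is.na(one$precision_between))
  # a single-stride horse contributes a mean but no SD
  mix <- horse_level_stats(data.frame(horse_id = c("a", "a", "b"),
                                      diff_ms = c(0, 2, 10)))
  expect_equal(mix$accuracy, mean(c(1, 10)))
  expect_equal(mix$precision_within, sd(c(0, 2)))
})

test_that("horse-level statistics equal a brute-force group-by oracle", {
  set.seed(66)
  for (rep_i in 1:50) {
    n_h <- sample(2:8, 1)
    d <- data.frame(
      horse_id = sample(sprintf("h%02d", seq_len(n_h)), 60, replace = TRUE),
      diff_ms = rnorm(60, -3, 6))
    s <- horse_level_stats(d)
    orc <- oracle_group_stats(d$horse_id, d$diff_ms)
    expect_equal(s$accuracy, orc$accuracy)
    expect_equal(s$precision_between, orc$between)
    expect_equal(s$precision_within, orc$within)
  }
})

test_that("adding a constant to kinematic times shifts accuracy only", {
  set.seed(24)
  base <- data.frame(
    horse_id = rep(sprintf("h%d", 1:6), each = 15),
    diff_ms = rnorm(90, 2, 5))
  shifted <- base
  shifted$diff_ms <- base$diff_ms - 7 # +7 ms on kinematic times
  s0 <- horse_level_stats(base)
  s1 <- horse_level_stats(shifted)
  expect_equal(s1$accuracy, s0$accuracy - 7)
  expect_equal(s1$precision_between, s0$precision_between)
  expect_equal(s1$precision_within, s0$precision_within)
  expect_equal(s1$loa$high - s1$loa$low, s0$loa$high - s0$loa$low)
})

test_that("introduced time shift is the accuracy gap scaled by stride duration", {
  ts <- introduced_time_shift(-3, 1, 1000)
  expect_equal(ts$shift_ms, -4)
  expect_equal(ts$shift_pct, -0.4)
  expect_equal(introduced_time_shift(5, 5, 800)$shift_ms, 0)
  ts2 <- introduced_time_shift(7, 0, 700)
  expect_equal(ts2$shift_ms, 7)
  expect_equal(ts2$shift_pct, 1)
  expect_error(introduced_time_shift(1, 2, 0), "positive")
})

test_that("stride and stance durations come from successive and paired events", {
  kin <- data.frame(kind = rep("foot_on", 3), time = c(0.0, 1.15, 2.30))
  ket <- data.frame(stride = c(1L, 1L), kind = c("foot_on", "foot_off"),
                    time = c(0.10, 0.83))
  dur <- stride_and_stance_durations(kin, ket)
  expect_equal(dur$stride_ms, c(1150, 1150))
  expect_equal(dur$stance_ms, 730)
  expect_equal(dur$stride_mean, 1150)
  # too few events: empty, not an error
  empty <- stride_and_stance_durations(events_df(0.5), ket[0, ])
  expect_length(empty$stride_ms, 0L)
  expect_true(is.na(empty$stance_mean))
})

test_that("generated stride durations converge to the preset means", {
  co <- make_cohort("straight_walk", n_horses = 8L, strides_per_horse = 100L,
                    seed = 2)
  ev <- co$events
  dur <- do.call(rbind, lapply(split(ev, ev$horse_id), function(d) {
    s <- stride_and_stance_durations(
      data.frame(kind = d$kind, time = d$t_kinematic),
      data.frame(kind = d$kind, time = d$t_kinetic))
    data.frame(stride = s$stride_mean, stance = s$stance_mean)
  }))
  # horse stride means vary (SD 27.5 ms); their grand mean has SD ~10 ms
  expect_lt(abs(mean(dur$stride) - 1153), 30)
  expect_lt(abs(mean(dur$stance) - 734), 10)
})

test_that("injected bias and timing noise are recovered by the pipeline", {
  co <- make_cohort("straight_walk", n_horses = 8L, strides_per_horse = 20L,
                    bias_ms = 10, noise_sd_ms = 5, seed = 14)
  ag <- cohort_agreement(co)
  for (kd in c("foot_on", "foot_off")) {
    expect_lt(abs(ag[[kd]]$accuracy - (-10)), 1)
    expect_lt(abs(ag[[kd]]$precision_within - 5) / 5, 0.2)
  }
  # no perturbation: accuracy ~ 0
  co0 <- make_cohort("straight_walk", n_horses = 4L, strides_per_horse = 10L,
                     bias_ms = 0, noise_sd_ms = 0, horse_bias_sd_ms = 0,
                     seed = 3)
  ag0 <- cohort_agreement(co0)
  expect_equal(ag0$foot_on$accuracy, 0)
})
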