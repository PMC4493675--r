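# Independent brute-force oracles used by the oracle-equivalence tests.
# These deliberately re-derive each scanning rule with plain loops, separate
# from the package implementations.

# method A: first index (0-based) in [start, end] with v < threshold
oracle_first_below <- function(v, start, end, threshold) {
  for (f in start:end) if (v[f + 1L] < threshold) return(f)
  NA_integer_
}

# method B: last index (0-based) in [start, end] with distance < height
oracle_last_below <- function(d_by_frame, start, end, height) {
  hit <- NA_integer_
  for (f in start:end) if (d_by_frame[f + 1L] < height) hit <- f
  hit
}

# method D: first negative-valued local minimum of `filt` after frame bs,
# refined to the argmin of `raw` within +/- radius (0-based frames)
oracle_velmin <- function(filt, raw, bs, radius = 3L) {
  n <- length(filt)
  prelim <- NA_integer_
  for (i in max(bs + 2L, 2L):(n - 1L)) {
    if (filt[i] < 0 && filt[i] <= filt[i - 1L] && filt[i] < filt[i + 1L]) {
      prelim <- i - 1L
      break
    }
  }
  if (is.na(prelim)) return(NA_integer_)
  lo <- max(prelim - radius, 0L); hi <- min(prelim + radius, n - 1L)
  best <- lo
  for (f in lo:hi) if (raw[f + 1L] < raw[best + 1L]) best <- f
  best
}

# kinetic events: strict threshold crossings, one pass
oracle_kinetic <- function(fz, thr) {
  on <- integer(0); off <- integer(0); loaded <- FALSE
  for (i in seq_along(fz)) {
    if (!loaded && fz[i] > thr) { on <- c(on, i - 1L); loaded <- TRUE }
    else if (loaded && fz[i] < thr) { off <- c(off, i - 1L); loaded <- FALSE }
  }
  list(on = on, off = off)
}

# two-pass group-by oracle for accuracy / between / within
oracle_group_stats <- function(horse_id, diff_ms) {
  ids <- unique(horse_id)
  means <- sds <- numeric(0)
  for (h in ids) {
    x <- diff_ms[horse_id == h]
    means <- c(means, sum(x) / length(x))
    if (length(x) >= 2L) {
      m <- sum(x) / length(x)
      sds <- c(sds, sqrt(sum((x - m)^2) / (length(x) - 1L)))
    }
  }
  list(accuracy = sum(means) / length(means),
       between = if (length(means) >= 2L) {
         mm <- sum(means) / length(means)
         sqrt(sum((means - mm)^2) / (length(means) - 1L))
       } else NA_real_,
       within = if (length(sds)) sum(sds) / length(sds) else NA_real_)
}

# direct convolution moving average with symmetric shrink (odd width)
oracle_moving_average <- function(x, w) {
  if (w %% 2L == 0L) w <- w - 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - r):(i + r)])
  }
  out
}

# convenience: a condition profile for plain straight walking
walk_profile <- function() condition_profile("walk", "straight", "fore")
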