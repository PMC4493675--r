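#' Sampled signal with an explicit rate and frame origin
#'
#' A `sampled_series` holds one uniformly sampled real-valued signal together
#' with its sampling rate and the 0-based offset (`origin`) of its first value
#' relative to frame 0 of the parent trial. Derivative operators shorten a
#' series but preserve `origin`, so a value at position `k` of the series
#' always refers to trial frame `origin + k - 1` (0-based).
#'
#' @param values numeric vector of finite sample values.
#' @param rate sampling rate in samples per second (> 0).
#' @param origin 0-based frame offset of the first value (>= 0).
#' @param units optional unit string (e.g. "m", "m/s", "N"), carried along
#'   for display only.
#' @return An object of class `sampled_series`.
#' @export
#' @examples
#' s <- sampled_series(c(0, 0.01, 0.03), rate = 100, units = "m")
#' differentiate(s)
sampled_series <- function(values, rate, origin = 0L, units = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite and non-missing", call. = FALSE)
  origin <- as.integer(origin)
  if (length(origin) != 1L || is.na(origin) || origin < 0L)
    stop("`origin` must be a single non-negative integer", call. = FALSE)
  structure(
    list(values = values, rate = as.numeric(rate), origin = origin,
         units = units),
    class = "sampled_series"
  )
}

#' @export
print.sampled_series <- function(x, ...) {
  u <- if (is.null(x$units)) "" else paste0(" [", x$units, "]")
  cat(sprintf("<sampled_series> %d samples @ %g Hz, origin frame %d%s\n",
              length(x$values), x$rate, x$origin, u))
  invisible(x)
}

#' @export
length.sampled_series <- function(x) length(x$values)

# Coerce a sampled_series or bare numeric vector to its values.
series_values <- function(x) {
  if (inherits(x, "sampled_series")) x$values else as.numeric(x)
}

#' First-order forward-difference derivative
#'
#' Differentiates a sampled series by forward differences scaled by the
#' sampling rate: output value `k` is `(x[k+1] - x[k]) * rate` and is assigned
#' the frame of the *earlier* input sample, so the output keeps the input's
#' `origin` and is one sample shorter. Because of this alignment, applying the
#' operator twice shifts the empirical peak of a smooth second derivative one
#' frame earlier than its analytic location; downstream detectors deliberately
#' do not correct for this shift (the subsequent zero-lag low-pass filtering
#' nudges peaks in the opposite direction).
#'
#' @param series a [sampled_series()], or a numeric vector with `rate` given.
#' @param rate sampling rate, only used when `series` is a bare numeric vector.
#' @return A `sampled_series` of length `length(series) - 1`.
#' @export
differentiate <- function(series, rate = NULL) {
  if (!inherits(series, "sampled_series")) {
    if (is.null(rate)) stop("`rate` is required for a bare numeric vector",
                            call. = FALSE)
    series <- sampled_series(series, rate)
  }
  if (length(series$values) < 2L)
    stop("cannot differentiate a series shorter than 2 samples", call. = FALSE)
  sampled_series(diff(series$values) * series$rate, series$rate,
                 origin = series$origin)
}

#' Elementwise Euclidean norm of three component signals
#'
#' @param c1,c2,c3 component signals ([sampled_series()] or numeric vectors)
#'   of equal length (and equal rate if series).
#' @return The per-sample resultant magnitude, as a `sampled_series` when the
#'   inputs are series, otherwise a numeric vector.
#' @export
resultant_magnitude <- function(c1, c2, c3) {
  is_series <- inherits(c1, "sampled_series")
  v1 <- series_values(c1); v2 <- series_values(c2); v3 <- series_values(c3)
  if (length(v1) != length(v2) || length(v1) != length(v3))
    stop("component signals must have equal length", call. = FALSE)
  if (is_series) {
    rates <- c(c1$rate,
               if (inherits(c2, "sampled_series")) c2$rate else c1$rate,
               if (inherits(c3, "sampled_series")) c3$rate else c1$rate)
    if (diff(range(rates)) > 1e-9)
      stop("component signals must share one sampling rate", call. = FALSE)
  }
  res <- sqrt(v1^2 + v2^2 + v3^2)
  if (is_series) sampled_series(res, c1$rate, origin = c1$origin) else res
}

#' Centred moving-average smoothing
#'
#' Smooths with a centred window that shrinks symmetrically near the edges, so
#' the output has the same length as the input and constants are preserved.
#' Even window widths are reduced to the next lower odd width so the window
#' stays centred (Matlab `smooth` semantics; a width of 10 therefore averages
#' over 9 samples away from the edges).
#'
#' @param series a [sampled_series()] or numeric vector.
#' @param window window width in samples (>= 1).
#' @return Smoothed signal of the same class and length as the input.
#' @export
moving_average <- function(series, window) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("`window` must be a single integer >= 1", call. = FALSE)
  x <- series_values(series)
  n <- length(x)
  w <- if (window %% 2L == 0L) window - 1L else window
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  r <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  sm <- (cs[i + r + 1L] - cs[i - r]) / (2L * r + 1L)
  if (inherits(series, "sampled_series"))
    sampled_series(sm, series$rate, origin = series$origin,
                   units = series$units)
  else sm
}

# One causal IIR pass started from the steady state of the signal's first
# value, so a constant signal passes through a DC-gain-1 filter unchanged.
iir_steady <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], length(b) - 1L),
                            init.y = rep(x[1L], length(a) - 1L)))
}

#' Zero-lag Butterworth low-pass filter
#'
#' Low-pass filters a series with a Butterworth design applied forward and
#' backward, giving zero net phase shift and unit DC gain. By default `order`
#' names the *effective* magnitude order of the combined pass (the common
#' biomechanics reporting convention): a requested 4th-order zero-lag filter
#' is realised as a 2nd-order design run forward then backward. Set
#' `design_is_effective = FALSE` to design at `order` directly (effective
#' magnitude order `2 * order`). Edges are handled by point-reflected padding
#' on both ends plus steady-state initialisation from the border value;
#' padding is stripped after the backward pass. The padding length is
#' `3 * design_order` cut-off periods (`3 * design_order * rate / cutoff_hz`
#' samples), long enough for the filter transient to decay so that the
#' forward-backward output is time-reversal symmetric to numerical precision
#' throughout, edges included.
#'
#' @param series a [sampled_series()], or numeric vector with `rate` given.
#' @param cutoff_hz -3 dB cut-off frequency in Hz (0 < cutoff < rate / 2).
#' @param order requested filter order (even when `design_is_effective`).
#' @param design_is_effective interpret `order` as the effective
#'   forward-backward order (default) or as the one-pass design order.
#' @param rate sampling rate, only used for a bare numeric vector.
#' @return Filtered signal, same class and length as the input.
#' @export
lowpass_zero_lag <- function(series, cutoff_hz, order = 4L,
                             design_is_effective = TRUE, rate = NULL) {
  is_series <- inherits(series, "sampled_series")
  if (!is_series) {
    if (is.null(rate)) stop("`rate` is required for a bare numeric vector",
                            call. = FALSE)
  } else rate <- series$rate
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  order <- as.integer(order)
  if (design_is_effective) {
    if (order < 2L || order %% 2L != 0L)
      stop("effective `order` must be an even integer >= 2", call. = FALSE)
    n_design <- order %/% 2L
  } else {
    if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
    n_design <- order
  }
  x <- series_values(series)
  n <- length(x)
  pad <- as.integer(ceiling(3 * n_design * rate / cutoff_hz))
  if (n <= pad + 1L)
    stop(sprintf("series too short for edge padding (need > %d samples)",
                 pad + 1L), call. = FALSE)
  bf <- signal::butter(n_design, cutoff_hz / (rate / 2), type = "low")
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_steady(bf$b, bf$a, xp)
  y <- rev(iir_steady(bf$b, bf$a, rev(y)))
  out <- y[(pad + 1L):(pad + n)]
  if (is_series)
    sampled_series(out, rate, origin = series$origin, units = series$units)
  else out
}
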