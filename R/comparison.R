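#' Pair kinematic events with kinetic reference events
#'
#' Matches events of the same kind (foot on with foot on, foot off with foot
#' off) between a kinematic and a kinetic event table by greedy
#' nearest-neighbour pairing: candidate pairs closer than `max_gap_ms` are
#' assigned in order of increasing absolute time difference, each event used
#' at most once. The method difference is always kinetic minus kinematic, in
#' milliseconds. Unpaired events (e.g. a spurious detection between strides)
#' are reported alongside, never silently dropped, and are excluded from
#' downstream statistics. The 100 ms default gap is under half the shortest
#' expected stance duration, so events cannot jump strides.
#'
#' @param kinematic,kinetic event data frames with columns `kind` and `time`
#'   (seconds), e.g. from [segment_trial()] and [detect_kinetic_events()].
#' @param max_gap_ms maximum pairing distance in milliseconds.
#' @return A list of class `event_pairing` with `differences` (data frame:
#'   `kind`, `time_kinematic`, `time_kinetic`, `diff_ms`) and `unpaired`
#'   (data frame: `source`, `kind`, `time`).
#' @export
pair_events <- function(kinematic, kinetic, max_gap_ms = 100) {
  ok_flags <- c("ok", "no_local_minimum", "window_exhausted")
  usable <- function(df) {
    if (!is.null(df$quality_flag))
      df <- df[df$quality_flag %in% ok_flags, , drop = FALSE]
    df[!is.na(df$time), , drop = FALSE]
  }
  kinematic <- usable(kinematic); kinetic <- usable(kinetic)
  diffs <- list(); unpaired <- list()
  for (kd in c("foot_on", "foot_off")) {
    ta <- kinematic$time[kinematic$kind == kd]
    tb <- kinetic$time[kinetic$kind == kd]
    if (length(ta) == 0L && length(tb) == 0L) next
    cand <- expand.grid(i = seq_along(ta), j = seq_along(tb))
    if (nrow(cand) > 0L) {
      cand$d <- abs(tb[cand$j] - ta[cand$i]) * 1000
      cand <- cand[cand$d <= max_gap_ms, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
    }
    used_a <- logical(length(ta)); used_b <- logical(length(tb))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- used_b[j] <- TRUE
      diffs[[length(diffs) + 1L]] <- data.frame(
        kind = kd, time_kinematic = ta[i], time_kinetic = tb[j],
        diff_ms = (tb[j] - ta[i]) * 1000)
    }
    if (any(!used_a))
      unpaired[[length(unpaired) + 1L]] <- data.frame(
        source = "kinematic", kind = kd, time = ta[!used_a])
    if (any(!used_b))
      unpaired[[length(unpaired) + 1L]] <- data.frame(
        source = "kinetic", kind = kd, time = tb[!used_b])
  }
  structure(
    list(differences = if (length(diffs)) do.call(rbind, diffs) else
           data.frame(kind = character(0), time_kinematic = numeric(0),
                      time_kinetic = numeric(0), diff_ms = numeric(0)),
         unpaired = if (length(unpaired)) do.call(rbind, unpaired) else
           data.frame(source = character(0), kind = character(0),
                      time = numeric(0))),
    class = "event_pairing")
}

#' @export
print.event_pairing <- function(x, ...) {
  cat(sprintf("<event_pairing> %d pairs, %d unpaired\n",
              nrow(x$differences), nrow(x$unpaired)))
  invisible(x)
}

#' Limits of agreement
#'
#' Computes mean +/- 2 SD over pooled per-stride method differences, the
#' interval expected to contain about 95% of individual differences. The SD
#' is the sample (n - 1) standard deviation.
#'
#' @param diffs numeric vector of method differences (ms), or a data frame
#'   with a `diff_ms` column.
#' @return A list with `low`, `high`, `mean`, `sd` and `n`.
#' @export
limits_of_agreement <- function(diffs) {
  d <- if (is.data.frame(diffs)) diffs$diff_ms else as.numeric(diffs)
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    stop("at least 2 differences are required for limits of agreement",
         call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  list(low = m - 2 * s, high = m + 2 * s, mean = m, sd = s, n = length(d))
}

#' Hierarchical accuracy and precision of method differences
#'
#' Summarises per-stride method differences across subjects the way method
#' comparison studies report them: for each horse the mean and SD of its
#' differences are computed first, then accuracy is the overall mean of the
#' horse-based means, between-horse precision the SD across horse-based
#' means, and within-horse precision the average horse-based SD. Unequal
#' per-horse stride counts are retained as-is. A horse with fewer than 2
#' strides contributes a mean but no SD (noted in the `horses` table);
#' between-horse precision is `NA` with fewer than 2 horses.
#'
#' @param diffs data frame with columns `horse_id` and `diff_ms` (pooled over
#'   the limb pair sharing a loading condition).
#' @return An object of class `agreement_summary`: a list with `accuracy`,
#'   `precision_between`, `precision_within`, `loa` (see
#'   [limits_of_agreement()]), `n_strides`, `n_horses` and the per-horse
#'   table `horses`.
#' @export
horse_level_stats <- function(diffs) {
  stopifnot(is.data.frame(diffs), all(c("horse_id", "diff_ms") %in%
                                        names(diffs)))
  d <- diffs[!is.na(diffs$diff_ms), , drop = FALSE]
  if (nrow(d) == 0L) stop("no differences to summarise", call. = FALSE)
  by_horse <- split(d$diff_ms, d$horse_id)
  horses <- data.frame(
    horse_id = names(by_horse),
    n = vapply(by_horse, length, integer(1)),
    mean = vapply(by_horse, mean, numeric(1)),
    sd = vapply(by_horse, function(x)
      if (length(x) >= 2L) stats::sd(x) else NA_real_, numeric(1)),
    row.names = NULL)
  structure(
    list(accuracy = mean(horses$mean),
         precision_between = if (nrow(horses) >= 2L) stats::sd(horses$mean)
                             else NA_real_,
         precision_within = if (any(!is.na(horses$sd)))
           mean(horses$sd, na.rm = TRUE) else NA_real_,
         loa = if (nrow(d) >= 2L) limits_of_agreement(d$diff_ms) else NULL,
         n_strides = nrow(d), n_horses = nrow(horses), horses = horses),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_summary> %d strides, %d horses\n",
           "  accuracy %.2f ms | precision between %.2f ms | within %.2f ms\n"),
    x$n_strides, x$n_horses, x$accuracy, x$precision_between,
    x$precision_within))
  if (!is.null(x$loa))
    cat(sprintf("  limits of agreement [%.2f, %.2f] ms\n",
                x$loa$low, x$loa$high))
  invisible(x)
}

#' Time shift introduced into stance and swing durations
#'
#' A kinematic pipeline whose foot-on and foot-off biases differ shifts the
#' derived stance/swing split even when each event is individually close to
#' the kinetic reference. The shift is the foot-on accuracy minus the
#' foot-off accuracy, also expressed as a percentage of the mean stride
#' duration; zero means stance and swing durations are on average unbiased.
#'
#' @param acc_on,acc_off mean accuracy (ms) for foot-on and foot-off
#'   detection.
#' @param mean_stride_ms mean stride duration in ms (> 0).
#' @return A list with `shift_ms` and `shift_pct`.
#' @export
introduced_time_shift <- function(acc_on, acc_off, mean_stride_ms) {
  if (!is.finite(mean_stride_ms) || mean_stride_ms <= 0)
    stop("`mean_stride_ms` must be positive", call. = FALSE)
  shift <- acc_on - acc_off
  list(shift_ms = shift, shift_pct = 100 * shift / mean_stride_ms)
}

#' Stride and stance durations from event tables
#'
#' Stride durations are the intervals between successive kinematic foot-on
#' events of the reference foot; stance durations are kinetic foot-off minus
#' foot-on per contact. Entries with too few events come back empty rather
#' than erroring.
#'
#' @param kinematic event data frame with kinematic `foot_on` rows.
#' @param kinetic event data frame with kinetic `foot_on`/`foot_off` rows
#'   (paired per contact via the `stride` column when present, by order
#'   otherwise).
#' @return A list with vectors `stride_ms` and `stance_ms` and their means
#'   and SDs (`NA` when fewer than 1/2 values are available).
#' @export
stride_and_stance_durations <- function(kinematic, kinetic) {
  t_on <- sort(kinematic$time[kinematic$kind == "foot_on" &
                                !is.na(kinematic$time)])
  stride_ms <- if (length(t_on) >= 2L) diff(t_on) * 1000 else numeric(0)
  on <- kinetic[kinetic$kind == "foot_on" & !is.na(kinetic$time), ,
                drop = FALSE]
  off <- kinetic[kinetic$kind == "foot_off" & !is.na(kinetic$time), ,
                 drop = FALSE]
  if (!is.null(on$stride) && !anyNA(on$stride)) {
    key <- intersect(on$stride, off$stride)
    stance_ms <- (off$time[match(key, off$stride)] -
                    on$time[match(key, on$stride)]) * 1000
  } else {
    k <- min(nrow(on), nrow(off))
    stance_ms <- if (k > 0L) (sort(off$time)[1:k] - sort(on$time)[1:k]) * 1000
                 else numeric(0)
  }
  list(stride_ms = stride_ms, stance_ms = stance_ms,
       stride_mean = if (length(stride_ms)) mean(stride_ms) else NA_real_,
       stride_sd = if (length(stride_ms) >= 2L) stats::sd(stride_ms)
                   else NA_real_,
       stance_mean = if (length(stance_ms)) mean(stance_ms) else NA_real_,
       stance_sd = if (length(stance_ms) >= 2L) stats::sd(stance_ms)
                   else NA_real_)
}
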