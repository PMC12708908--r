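#' Construct a signal interval
#'
#' One channel of one participant in one interval: the atomic unit consumed by
#' the peak detectors and feature extractors.
#'
#' @param samples numeric vector of samples (EDA in microsiemens).
#' @param sampling_rate sampling rate in Hz.
#' @param channel one of `"ecg"`, `"eda"`, `"resp"`, `"temp"`.
#' @param dyad_id,participant,interval_index identifying keys.
#' @return an object of class `signal_interval`.
#' @export
signal_interval <- function(samples, sampling_rate, channel,
                            dyad_id = NA_integer_, participant = NA_integer_,
                            interval_index = NA_integer_) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!channel %in% c("ecg", "eda", "resp", "temp"))
    stop("unknown channel: ", channel)
  if (any(!is.finite(samples)))
    stop("data error: non-finite samples in dyad ", dyad_id,
         " participant ", participant, " channel ", channel)
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 channel = channel, dyad_id = dyad_id,
                 participant = participant, interval_index = interval_index),
            class = "signal_interval")
}

#' Segment a continuous recording into intervals
#'
#' Splits one dyad's tidy long recording (columns `participant`, `channel`,
#' `time_s`, `value`) into the protocol's intervals; samples outside the given
#' boundaries (questionnaire breaks, trailing data) are discarded.
#'
#' @param raw data frame with columns `participant`, `channel`, `time_s`,
#'   `value` (and optionally `dyad_id`).
#' @param boundaries data frame with columns `interval_index`, `start_s`,
#'   `end_s`; intervals must be non-overlapping and ordered in time.
#' @param sampling_rate sampling rate of the recording in Hz.
#' @return list of [signal_interval()] objects, one per
#'   participant-channel-interval.
#' @export
segment_recording <- function(raw, boundaries, sampling_rate) {
  need <- c("participant", "channel", "time_s", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) stop("data error: missing columns ", paste(miss, collapse = ", "))
  b <- boundaries[order(boundaries$start_s), ]
  if (any(b$end_s <= b$start_s)) stop("invalid boundaries: end before start")
  if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)] - 1e-9))
    stop("invalid boundaries: intervals overlap")
  span <- range(raw$time_s)
  if (min(b$start_s) < span[1] - 1e-9 || max(b$end_s) > span[2] + 1/sampling_rate + 1e-9)
    stop("invalid boundaries: outside recording span")
  dyad_id <- if ("dyad_id" %in% names(raw)) raw$dyad_id[1] else NA_integer_
  out <- list()
  for (p in sort(unique(raw$participant))) {
    for (ch in sort(unique(raw$channel))) {
      sub <- raw[raw$participant == p & raw$channel == ch, ]
      sub <- sub[order(sub$time_s), ]
      if (nrow(sub) == 0)
        stop("data error: missing channel ", ch, " for dyad ", dyad_id,
             " participant ", p)
      for (k in seq_len(nrow(b))) {
        sel <- sub$time_s >= b$start_s[k] - 1e-9 & sub$time_s < b$end_s[k] - 1e-9
        expected <- round((b$end_s[k] - b$start_s[k]) * sampling_rate)
        if (sum(sel) < expected)
          stop("data error: truncated interval ", b$interval_index[k],
               " for dyad ", dyad_id, " participant ", p, " channel ", ch)
        out[[length(out) + 1]] <- signal_interval(
          sub$value[sel][seq_len(expected)], sampling_rate, ch,
          dyad_id = dyad_id, participant = p,
          interval_index = b$interval_index[k])
      }
    }
  }
  out
}

#' Channel denoising filters
#'
#' Zero-phase Butterworth filtering with channel-appropriate defaults:
#' ECG high-pass 0.5 Hz, EDA low-pass 1 Hz, respiration band-pass 0.05-1 Hz,
#' temperature low-pass 0.1 Hz. Cutoffs are clipped to the Nyquist limit.
#'
#' @param interval a [signal_interval()].
#' @param cutoffs optional named list overriding the per-channel cutoffs, each
#'   element `c(low, high)` in Hz with `NA` for an absent edge.
#' @return the filtered `signal_interval`.
#' @export
filter_channel <- function(interval, cutoffs = NULL) {
  stopifnot(inherits(interval, "signal_interval"))
  fs <- interval$sampling_rate
  defaults <- list(ecg = c(0.5, NA), eda = c(NA, 1),
                   resp = c(0.05, 1), temp = c(NA, 0.1))
  co <- if (is.null(cutoffs) || is.null(cutoffs[[interval$channel]]))
    defaults[[interval$channel]] else cutoffs[[interval$channel]]
  nyq <- fs / 2
  lo <- co[1]; hi <- co[2]
  if (!is.na(hi)) hi <- min(hi, 0.99 * nyq)
  x <- interval$samples
  y <- if (is.na(lo) && is.na(hi)) x
  else if (is.na(lo)) {
    bf <- signal::butter(2, hi / nyq, type = "low")
    as.numeric(signal::filtfilt(bf, x))
  } else if (is.na(hi)) {
    bf <- signal::butter(2, lo / nyq, type = "high")
    as.numeric(signal::filtfilt(bf, x))
  } else {
    bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
  interval$samples <- y
  interval
}

# local maxima (strictly greater than both neighbors), as sample indices
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# amplitude-priority peak picking with a refractory period
pick_peaks <- function(x, fs, refractory_s, threshold) {
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= threshold]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(-x[cand], cand)]
  accepted <- integer(0)
  for (i in cand) {
    if (all(abs(i - accepted) > refractory_s * fs)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Detect ECG R-peaks
#'
#' Amplitude-priority local-maximum detection with an adaptive threshold
#' (midway between the signal median and maximum) and a 0.25 s refractory
#' period (about a 240 beats/min ceiling). Intervals whose inter-beat
#' intervals fall outside 0.3-2 s are flagged in the result's
#' `quality_flag` attribute.
#'
#' @param interval a [signal_interval()] with channel `"ecg"` and at least
#'   10 s of signal.
#' @param refractory_s minimum peak spacing in seconds.
#' @return an object of class `peak_train` with `times` (s from interval
#'   start, strictly increasing) and `channel`.
#' @export
detect_r_peaks <- function(interval, refractory_s = 0.25) {
  stopifnot(inherits(interval, "signal_interval"))
  if (interval$channel != "ecg") stop("detect_r_peaks expects an ecg interval")
  fs <- interval$sampling_rate
  x <- interval$samples
  if (length(x) < 10 * fs) stop("quality error: need at least 10 s of ECG")
  thr <- median(x) + 0.5 * (max(x) - median(x))
  idx <- pick_peaks(x, fs, refractory_s, thr)
  if (length(idx) < 2)
    stop("quality error: fewer than 2 R-peaks detected (interval unusable for HRV)")
  times <- (idx - 1) / fs
  ibis <- diff(times)
  structure(list(channel = "ecg", times = times),
            class = "peak_train",
            quality_flag = any(ibis < 0.3 | ibis > 2))
}

#' Detect respiration peaks
#'
#' Breath-peak detection by the same amplitude-priority scheme as
#' [detect_r_peaks()] with a 1 s refractory period and a threshold at the
#' signal mean.
#'
#' @param interval a [signal_interval()] with channel `"resp"`.
#' @param refractory_s minimum peak spacing in seconds.
#' @return a `peak_train`.
#' @export
detect_respiration_peaks <- function(interval, refractory_s = 1.0) {
  stopifnot(inherits(interval, "signal_interval"))
  if (interval$channel != "resp") stop("detect_respiration_peaks expects a resp interval")
  fs <- interval$sampling_rate
  x <- interval$samples
  rng <- max(x) - min(x)
  if (rng <= 1e-12) stop("quality error: flat respiration signal")
  thr <- mean(x) + 0.25 * (max(x) - mean(x))
  idx <- pick_peaks(x, fs, refractory_s, thr)
  if (length(idx) < 2) stop("quality error: fewer than 2 breath peaks detected")
  structure(list(channel = "resp", times = (idx - 1) / fs),
            class = "peak_train", quality_flag = FALSE)
}

#' Detect skin conductance responses
#'
#' A candidate SCR is any local maximum of the (optionally smoothed) EDA
#' signal paired with the most recent preceding local minimum (its valley).
#' The pair is accepted when the peak value exceeds the valley value by at
#' least `min_amplitude` (default 0.05 microsiemens) and the peak occurs
#' within `max_rise_s` (default 5 s) of the valley. Zero accepted SCRs is a
#' valid result.
#'
#' @param interval a [signal_interval()] with channel `"eda"`.
#' @param min_amplitude minimum trough-to-peak rise in microsiemens.
#' @param max_rise_s maximum valley-to-peak latency in seconds.
#' @param smooth_s width of a moving-average pre-smoother in seconds
#'   (0 disables smoothing).
#' @return a `peak_train` with `times` (peak times), `valley_times` and
#'   `amplitudes`.
#' @export
detect_scrs <- function(interval, min_amplitude = 0.05, max_rise_s = 5,
                        smooth_s = 0.25) {
  stopifnot(inherits(interval, "signal_interval"))
  if (interval$channel != "eda") stop("detect_scrs expects an eda interval")
  fs <- interval$sampling_rate
  x <- interval$samples
  if (smooth_s > 0) {
    w <- max(1L, round(smooth_s * fs))
    if (w > 1) x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  }
  ok <- which(!is.na(x))
  peaks <- local_maxima(x)
  valleys <- local_minima(x)
  keep_p <- numeric(0); keep_v <- numeric(0); keep_a <- numeric(0)
  for (pk in peaks) {
    prev <- valleys[valleys < pk]
    if (length(prev) == 0) next
    vl <- max(prev)
    amp <- x[pk] - x[vl]
    lat <- (pk - vl) / fs
    if (amp >= min_amplitude && lat <= max_rise_s) {
      keep_p <- c(keep_p, (pk - 1) / fs)
      keep_v <- c(keep_v, (vl - 1) / fs)
      keep_a <- c(keep_a, amp)
    }
  }
  structure(list(channel = "eda", times = keep_p, valley_times = keep_v,
                 amplitudes = keep_a),
            class = "peak_train", quality_flag = FALSE)
}

#' Instantaneous event-rate series
#'
#' Converts an event train (R-peaks or breath peaks) into an evenly sampled
#' rate series: the value at time t is `60 / IBI` for the inter-event interval
#' containing t, extended by the first/last interval's value before the first
#' and after the last event (piecewise-constant convention).
#'
#' @param peaks a `peak_train` with at least 2 events.
#' @param out_rate output grid rate in Hz (default 4).
#' @param duration duration of the interval in seconds.
#' @param kind `"heart"` or `"respiration"` (annotation only).
#' @return an object of class `rate_series` with `values` (events/min),
#'   `sampling_rate` and `kind`.
#' @export
instantaneous_rate <- function(peaks, out_rate = 4, duration, kind = "heart") {
  stopifnot(inherits(peaks, "peak_train"))
  tt <- peaks$times
  if (length(tt) < 2) stop("quality error: need at least 2 events for a rate series")
  n <- round(duration * out_rate)
  grid <- (seq_len(n) - 1) / out_rate
  rate_per_ibi <- 60 / diff(tt)
  # interval containing t: index i with tt[i] <= t < tt[i+1]
  idx <- findInterval(grid, tt)
  idx[idx < 1] <- 1
  idx[idx > length(rate_per_ibi)] <- length(rate_per_ibi)
  structure(list(kind = kind, sampling_rate = out_rate,
                 values = rate_per_ibi[idx]),
            class = "rate_series")
}
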