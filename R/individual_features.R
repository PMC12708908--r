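#' Names of the 20 per-participant features
#'
#' Nine ECG/heart-rate-variability features, two respiration features, six
#' electrodermal features and three skin-temperature features, in stable
#' order.
#' @return character vector of length 20.
#' @export
individual_feature_names <- function() {
  c("mean_hr", "min_hr", "max_hr", "sdnn", "rmssd", "pnn50",
    "lf_power", "hf_power", "lf_hf_ratio",
    "mean_rr", "sd_rr",
    "mean_eda", "final_eda", "delta_eda", "n_scr", "mean_scr_amp", "sd_scr_amp",
    "mean_temp", "final_temp", "delta_temp")
}

# Lomb-Scargle periodogram power at frequencies f (Hz) for samples x at
# times t (s); returned in units of x^2 per independent frequency, so that
# (2/n) * sum over the natural frequency grid approximates variance.
lomb_power <- function(t, x, f) {
  x <- x - mean(x)
  n <- length(x)
  vapply(f, function(fr) {
    w <- 2 * pi * fr
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * ((sum(x * ct))^2 / sum(ct^2) + (sum(x * st))^2 / sum(st^2))
  }, numeric(1))
}

# band power (x^2 units) from the Lomb-Scargle spectrum over [lo, hi] Hz
ls_band_power <- function(t, x, lo, hi) {
  span <- diff(range(t))
  if (span <= 0) return(0)
  df <- 1 / span
  if (df > hi) return(0)
  f <- seq(df, hi, by = df)
  f <- f[f >= lo - 1e-12 & f <= hi + 1e-12]
  if (length(f) == 0) return(0)
  (2 / length(x)) * sum(lomb_power(t, x, f))
}

#' Heart-rate-variability features from inter-beat intervals
#'
#' Computes the nine ECG features: mean/min/max heart rate (statistics of the
#' per-beat `60000 / IBI` values), SDNN (standard deviation of the IBIs),
#' RMSSD (root-mean-square of successive IBI differences), pNN50 (percentage
#' of successive differences greater than 50 ms), low-frequency
#' (0.04-0.15 Hz) and high-frequency (0.15-0.40 Hz) power of the IBI
#' tachogram via a Lomb-Scargle spectrum on the unevenly sampled beat times,
#' and the LF/HF ratio (missing when HF power is zero).
#'
#' @param ibis_ms inter-beat intervals in milliseconds (>= 2, all positive).
#' @param lf,hf frequency band edges in Hz.
#' @return named numeric vector of the nine ECG features.
#' @export
hrv_features <- function(ibis_ms, lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  if (length(ibis_ms) < 2) stop("need at least 2 inter-beat intervals")
  if (any(ibis_ms <= 0)) stop("data error: non-positive inter-beat interval")
  hr <- 60000 / ibis_ms
  d <- diff(ibis_ms)
  t_beat <- cumsum(ibis_ms) / 1000
  lfp <- ls_band_power(t_beat, ibis_ms, lf[1], lf[2])
  hfp <- ls_band_power(t_beat, ibis_ms, hf[1], hf[2])
  ratio <- if (hfp > 0) lfp / hfp else NA_real_
  c(mean_hr = mean(hr), min_hr = min(hr), max_hr = max(hr),
    sdnn = safe_sd(ibis_ms),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    lf_power = lfp, hf_power = hfp, lf_hf_ratio = ratio)
}

#' Respiration-rate features
#'
#' Mean and standard deviation of the instantaneous respiration-rate series
#' over the interval (the evenly sampled `rate_series`, so both statistics
#' are time-weighted).
#'
#' @param rate a `rate_series` from [instantaneous_rate()], or a `peak_train`
#'   of breath peaks (then `duration` is required and the series is built at
#'   4 Hz).
#' @param duration interval duration in seconds, needed when `rate` is a
#'   `peak_train`.
#' @return named numeric vector `c(mean_rr, sd_rr)`; both `NA` when fewer
#'   than 2 breaths are available.
#' @export
respiration_features <- function(rate, duration = NULL) {
  if (inherits(rate, "peak_train")) {
    if (length(rate$times) < 2)
      return(c(mean_rr = NA_real_, sd_rr = NA_real_))
    rate <- instantaneous_rate(rate, 4, duration, kind = "respiration")
  }
  stopifnot(inherits(rate, "rate_series"))
  c(mean_rr = mean(rate$values), sd_rr = safe_sd(rate$values))
}

#' Electrodermal features
#'
#' Mean EDA over the interval's samples, final EDA (last sample), the
#' final-minus-initial difference, and the count, mean and sample standard
#' deviation of skin-conductance-response amplitudes (mean missing with 0
#' SCRs, SD missing with fewer than 2).
#'
#' @param interval a [signal_interval()] with channel `"eda"`.
#' @param scrs a `peak_train` from [detect_scrs()].
#' @return named numeric vector of the six EDA features.
#' @export
eda_features <- function(interval, scrs) {
  stopifnot(inherits(interval, "signal_interval"), interval$channel == "eda")
  x <- interval$samples
  amps <- scrs$amplitudes
  c(mean_eda = mean(x), final_eda = x[length(x)],
    delta_eda = x[length(x)] - x[1],
    n_scr = length(amps),
    mean_scr_amp = if (length(amps) >= 1) mean(amps) else NA_real_,
    sd_scr_amp = safe_sd(amps))
}

#' Skin-temperature features
#'
#' Mean temperature, final temperature, and the final-minus-initial
#' difference over the interval.
#'
#' @param interval a [signal_interval()] with channel `"temp"`.
#' @return named numeric vector of the three temperature features.
#' @export
temperature_features <- function(interval) {
  stopifnot(inherits(interval, "signal_interval"), interval$channel == "temp")
  x <- interval$samples
  c(mean_temp = mean(x), final_temp = x[length(x)],
    delta_temp = x[length(x)] - x[1])
}

#' All 20 individual features for one participant-interval
#'
#' Runs the detectors and the four feature groups on one participant's four
#' channels for a single interval. Quality errors in peak detection propagate
#' as missing values for the affected group rather than aborting the
#' extraction.
#'
#' @param channels list with elements `ecg`, `eda`, `resp`, `temp`
#'   (numeric sample vectors).
#' @param sampling_rate sampling rate in Hz.
#' @param duration interval duration in seconds.
#' @param rate_grid_hz output grid for instantaneous-rate series.
#' @return named numeric vector of the 20 features (missing as `NA`).
#' @export
individual_features_for_interval <- function(channels, sampling_rate, duration,
                                             rate_grid_hz = 4) {
  out <- stats::setNames(rep(NA_real_, 20), individual_feature_names())
  ecg_iv <- signal_interval(channels$ecg, sampling_rate, "ecg")
  hr <- tryCatch({
    pk <- detect_r_peaks(ecg_iv)
    hrv_features(diff(pk$times) * 1000)
  }, error = function(e) NULL)
  if (!is.null(hr)) out[names(hr)] <- hr
  resp_iv <- signal_interval(channels$resp, sampling_rate, "resp")
  rr <- tryCatch({
    pk <- detect_respiration_peaks(resp_iv)
    respiration_features(instantaneous_rate(pk, rate_grid_hz, duration,
                                            kind = "respiration"))
  }, error = function(e) NULL)
  if (!is.null(rr)) out[names(rr)] <- rr
  eda_iv <- signal_interval(channels$eda, sampling_rate, "eda")
  ed <- eda_features(eda_iv, detect_scrs(eda_iv))
  out[names(ed)] <- ed
  tp <- temperature_features(signal_interval(channels$temp, sampling_rate, "temp"))
  out[names(tp)] <- tp
  out
}
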